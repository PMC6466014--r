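# Job-posting exclusion phrases, one per line.
# Posts containing any of these on word boundaries are dropped before
# food-term matching.
hiring
job opening
apply now
careers
job alert
now recruiting
we are recruiting
join our team
click to apply
job posting
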