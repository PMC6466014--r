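term,calories_per_100g,healthy,fastfood
apple,52,1,0
banana,89,1,0
orange,47,1,0
strawberry,33,1,0
blueberry,57,1,0
grape,69,1,0
watermelon,30,1,0
spinach,23,1,0
kale,49,1,0
broccoli,34,1,0
carrot,41,1,0
cucumber,15,1,0
tomato,18,1,0
avocado,160,1,0
quinoa,120,1,0
lentils,116,1,0
chickpeas,164,1,0
almonds,579,1,0
walnuts,654,1,0
salmon,208,1,0
tuna,132,1,0
chicken,165,1,0
turkey,135,1,0
tofu,76,1,0
yogurt,59,1,0
oatmeal,68,1,0
hummus,166,1,0
green salad,20,1,0
big mac,257,0,1
whopper,231,0,1
mcnuggets,296,0,1
french fries,312,0,1
fried chicken,246,0,1
taco bell,206,0,1
burger king,233,0,1
mcdonalds,259,0,1
kfc,243,0,1
wendys,228,0,1
chalupa,251,0,1
doritos locos,217,0,1
baconator,318,0,1
mcflurry,221,0,1
pizza,266,0,0
burger,295,0,0
cheeseburger,303,0,0
hot dog,290,0,0
pasta,131,0,0
lasagna,135,0,0
burrito,206,0,0
taco,226,0,0
sushi,143,0,0
ramen,436,0,0
sandwich,250,0,0
bagel,250,0,0
pancakes,227,0,0
waffles,291,0,0
donut,452,0,0
cake,257,0,0
brownie,466,0,0
cookie,488,0,0
ice cream,207,0,0
apple pie,237,0,0
chocolate,546,0,0
steak,271,0,0
bacon,541,0,0
cheese,402,0,0
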