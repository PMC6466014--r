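#' Load census-tract polygons from GeoJSON
#'
#' Reads a FeatureCollection of Polygon / MultiPolygon features.  The
#' tract identifier is taken from the feature property named by
#' `id_property` (default `GEOID`).  Coordinates are `[lon, lat]` in
#' planar WGS84 degrees; tracts are small enough that planar geometry is
#' adequate.
#'
#' @param path GeoJSON file path.
#' @param id_property name of the feature property holding the tract id.
#' @return an object of class `tract_set`: list with `tract_id`
#'   (character), `geoms` (per tract, a list of polygon parts, each part a
#'   list of closed rings as n x 2 matrices, ring 1 exterior), and `bbox`
#'   (matrix with columns xmin, xmax, ymin, ymax).
#' @export
load_tracts <- function(path, id_property = "GEOID") {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path,
                                 call. = FALSE)
  feats <- gj$features
  ids <- vapply(feats, function(f) {
    id <- f$properties[[id_property]]
    if (is.null(id)) NA_character_ else as.character(id)
  }, character(1))
  if (anyNA(ids)) {
    stop("feature(s) missing id property '", id_property, "'", call. = FALSE)
  }
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    coords <- g$coordinates
    parts <- switch(g$type,
      Polygon = list(coords),
      MultiPolygon = coords,
      stop("unsupported geometry type: ", g$type, call. = FALSE))
    lapply(parts, function(rings) lapply(rings, ring_matrix))
  })
  new_tract_set(ids, geoms)
}

ring_matrix <- function(ring) {
  m <- matrix(unlist(ring, use.names = FALSE), ncol = 2, byrow = TRUE)
  check_ring(m)
  m
}

check_ring <- function(m) {
  if (nrow(m) < 4L) {
    stop("degenerate ring: fewer than 4 vertices including closure",
         call. = FALSE)
  }
  if (m[1, 1] != m[nrow(m), 1] || m[1, 2] != m[nrow(m), 2]) {
    stop("ring not closed: first vertex must equal last", call. = FALSE)
  }
  invisible(m)
}

#' Construct a tract set from ids and ring geometries
#'
#' @param tract_id character vector of unique ids.
#' @param geoms list (one element per tract) of polygon parts; each part a
#'   list of closed rings (n x 2 matrices of lon, lat).
#' @return a `tract_set`.
#' @export
new_tract_set <- function(tract_id, geoms) {
  tract_id <- as.character(tract_id)
  if (anyDuplicated(tract_id)) {
    stop("duplicate tract_id in tract set", call. = FALSE)
  }
  stopifnot(length(tract_id) == length(geoms))
  for (g in geoms) for (part in g) for (r in part) check_ring(r)
  bbox <- t(vapply(geoms, function(g) {
    xy <- do.call(rbind, unlist(g, recursive = FALSE))
    c(xmin = min(xy[, 1]), xmax = max(xy[, 1]),
      ymin = min(xy[, 2]), ymax = max(xy[, 2]))
  }, numeric(4)))
  structure(list(tract_id = tract_id, geoms = geoms, bbox = bbox),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d tracts, bbox [%g, %g] x [%g, %g]\n",
              length(x$tract_id), min(x$bbox[, 1]), max(x$bbox[, 2]),
              min(x$bbox[, 3]), max(x$bbox[, 4])))
  invisible(x)
}

# Even-odd containment for one closed ring; boundary points count inside.
# Returns 2L on the boundary, 1L if the crossing ray count is odd, 0L else.
point_ring_state <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  x <- ring[, 1]; y <- ring[, 2]
  inside <- FALSE
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    # on-segment test: collinear and within the segment's bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (abs(cross) < 1e-12 &&
        px >= min(x1, x2) - 1e-12 && px <= max(x1, x2) + 1e-12 &&
        py >= min(y1, y2) - 1e-12 && py <= max(y1, y2) + 1e-12) {
      return(2L)
    }
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
  }
  if (inside) 1L else 0L
}

#' Point-in-tract containment test
#'
#' Even-odd (ray casting) rule in planar lon/lat space.  A point exactly
#' on any boundary edge counts as inside.  A multi-part tract contains a
#' point if any part does; within a part, rings are combined even-odd, so
#' a point inside a hole is outside (unless it lies on the hole's edge).
#'
#' @param lon,lat point coordinates (degrees).
#' @param geom one tract geometry: a list of parts, each part a list of
#'   closed rings (n x 2 matrices).
#' @return logical scalar.
#' @export
point_in_tract <- function(lon, lat, geom) {
  for (part in geom) {
    crossings <- 0L
    on_edge <- FALSE
    for (ring in part) {
      st <- point_ring_state(lon, lat, ring)
      if (st == 2L) { on_edge <- TRUE; break }
      crossings <- crossings + st
    }
    if (on_edge || crossings %% 2L == 1L) return(TRUE)
  }
  FALSE
}

#' Assign food-post records to census tracts
#'
#' Annotates each record with the id of the containing tract, or
#' `NA` if no tract contains the point.  When more than one tract
#' contains a point (shared boundaries), the lexicographically smallest
#' tract id wins, making assignment deterministic.
#'
#' `method = "grid"` (default) prefilters candidates with a uniform grid
#' over tract bounding boxes before running exact even-odd tests;
#' `method = "brute"` tests every tract for every point and is kept as
#' the oracle the accelerated path is checked against.
#'
#' @param records data.frame with `lon` and `lat` columns (e.g. from
#'   [process_stream()]).
#' @param tracts a `tract_set`.
#' @param method `"grid"` or `"brute"`.
#' @return list with `records` (input plus a `tract_id` column; unassigned
#'   rows get `NA`) and `unassigned` (count).
#' @export
assign_tracts <- function(records, tracts, method = c("grid", "brute")) {
  method <- match.arg(method)
  if (!inherits(tracts, "tract_set") || !length(tracts$tract_id)) {
    stop("empty or invalid tract collection", call. = FALSE)
  }
  n <- nrow(records)
  ids <- tracts$tract_id
  out <- rep(NA_character_, n)
  if (n) {
    cand_fun <- if (method == "grid") {
      grid <- build_bbox_grid(tracts)
      function(px, py) grid_candidates(grid, px, py)
    } else {
      function(px, py) seq_along(ids)
    }
    bb <- tracts$bbox
    geoms <- tracts$geoms
    for (i in seq_len(n)) {
      px <- records$lon[i]; py <- records$lat[i]
      cand <- cand_fun(px, py)
      cand <- cand[bb[cand, 1] <= px & bb[cand, 2] >= px &
                   bb[cand, 3] <= py & bb[cand, 4] >= py]
      hit <- cand[vapply(cand, function(k) point_in_tract(px, py, geoms[[k]]),
                         logical(1))]
      if (length(hit)) out[i] <- min(ids[hit])
    }
  }
  records$tract_id <- out
  list(records = records, unassigned = sum(is.na(out)))
}

# Uniform grid over the union bbox; cell size = median tract bbox extent.
build_bbox_grid <- function(tracts) {
  bb <- tracts$bbox
  x0 <- min(bb[, 1]); x1 <- max(bb[, 2])
  y0 <- min(bb[, 3]); y1 <- max(bb[, 4])
  cell <- max(stats::median(bb[, 2] - bb[, 1]),
              stats::median(bb[, 4] - bb[, 3]), 1e-9)
  nx <- max(1L, ceiling((x1 - x0) / cell))
  ny <- max(1L, ceiling((y1 - y0) / cell))
  cells <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(bb))) {
    ix <- clamp_idx(floor((bb[k, 1] - x0) / cell), nx):
          clamp_idx(floor((bb[k, 2] - x0) / cell), nx)
    iy <- clamp_idx(floor((bb[k, 3] - y0) / cell), ny):
          clamp_idx(floor((bb[k, 4] - y0) / cell), ny)
    for (i in ix) for (j in iy) {
      key <- paste0(i, ",", j)
      cells[[key]] <- c(cells[[key]], k)
    }
  }
  list(x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny, cells = cells)
}

clamp_idx <- function(i, n) min(max(as.integer(i), 0L), n - 1L)

grid_candidates <- function(grid, px, py) {
  if (px < grid$x0 - grid$cell || py < grid$y0 - grid$cell) return(integer(0))
  i <- clamp_idx(floor((px - grid$x0) / grid$cell), grid$nx)
  j <- clamp_idx(floor((py - grid$y0) / grid$cell), grid$ny)
  out <- grid$cells[[paste0(i, ",", j)]]
  if (is.null(out)) integer(0) else out
}
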