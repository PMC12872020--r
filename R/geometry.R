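# Point-in-polygon with inclusive boundary, on unprojected WGS84 lon/lat.
#
# Even-odd ray casting plus an explicit on-segment test so that points lying
# exactly on an edge or vertex count as inside, matching the selection
# convention used for bounding boxes.

# TRUE if point (px,py) lies on segment (x1,y1)-(x2,y2), within tolerance
.onSegment <- function(px, py, x1, y1, x2, y2, tol = 1e-12) {
  cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
  scale <- max(abs(c(x1, x2, y1, y2, px, py)), 1)
  if (abs(cross) > tol * scale * scale) return(FALSE)
  px >= min(x1, x2) - tol && px <= max(x1, x2) + tol &&
    py >= min(y1, y2) - tol && py <= max(y1, y2) + tol
}

# polygon: two-column matrix (lon, lat); ring need not be closed
.pointInPolygon <- function(px, py, polygon) {
  n <- nrow(polygon)
  if (n >= 2 && all(polygon[1, ] == polygon[n, ])) {
    polygon <- polygon[-n, , drop = FALSE]
    n <- n - 1
  }
  if (n < 3) stop("polygon needs at least 3 distinct vertices", call. = FALSE)
  xs <- polygon[, 1]; ys <- polygon[, 2]
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    if (is.na(x) || is.na(y)) return(FALSE)
    inside <- FALSE
    j <- n
    for (k in seq_len(n)) {
      if (.onSegment(x, y, xs[j], ys[j], xs[k], ys[k])) return(TRUE)
      if ((ys[k] > y) != (ys[j] > y)) {
        xint <- xs[j] + (y - ys[j]) / (ys[k] - ys[j]) * (xs[k] - xs[j])
        if (x < xint) inside <- !inside
      }
      j <- k
    }
    inside
  }, logical(1))
}

# region spec -> two-column polygon matrix (lon, lat).
# Accepts: numeric length-4 c(minlon,minlat,maxlon,maxlat); a string
# "minlon,minlat,maxlon,maxlat"; a two-column matrix; a GeoJSON file path.
.asRegionPolygon <- function(region) {
  if (is.character(region) && length(region) == 1) {
    if (file.exists(region)) {
      region <- .readGeoJSONPolygon(region)
    } else {
      parts <- suppressWarnings(as.numeric(strsplit(region, ",")[[1]]))
      if (length(parts) != 4 || anyNA(parts))
        stop("box string must be 'minlon,minlat,maxlon,maxlat'", call. = FALSE)
      region <- parts
    }
  }
  if (is.numeric(region) && is.null(dim(region)) && length(region) == 4) {
    if (region[1] > region[3] || region[2] > region[4])
      stop("invalid bounding box: min exceeds max", call. = FALSE)
    region <- cbind(
      lon = c(region[1], region[3], region[3], region[1]),
      lat = c(region[2], region[2], region[4], region[4]))
  }
  region <- as.matrix(region)
  if (ncol(region) != 2 || anyNA(region))
    stop("region must be a bounding box or a two-column (lon, lat) polygon",
         call. = FALSE)
  storage.mode(region) <- "double"
  region
}

.readGeoJSONPolygon <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- switch(gj$type %||% "",
                 Polygon = gj,
                 Feature = gj$geometry,
                 FeatureCollection = gj$features$geometry,
                 stop("GeoJSON must contain a Polygon", call. = FALSE))
  if (is.data.frame(geom)) {  # FeatureCollection simplification
    coords <- geom$coordinates[[1]]
  } else {
    coords <- geom$coordinates
  }
  if (is.list(coords)) coords <- coords[[1]]
  if (length(dim(coords)) == 3) coords <- coords[1, , ]
  m <- matrix(as.numeric(coords), ncol = 2)
  colnames(m) <- c("lon", "lat")
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
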