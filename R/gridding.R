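# Grid binning of trip endpoints, high-demand zone selection and inter-zone
# distances. Cells are half-open squares [x, x+L) x [y, y+L) indexed (row, col)
# from the grid's south-west corner.

#' Define a square analysis grid
#'
#' @param cell_side cell side in metres (default 100, i.e. 100 m x 100 m
#'   zones).
#' @param n_cols,n_rows grid dimensions in cells.
#' @param origin for lon/lat grids, the lon/lat (degrees) of the south-west
#'   corner; for planar grids, the planar coordinates (metres) of that corner.
#' @param reference_latitude latitude (degrees) about which longitude is
#'   scaled in the equirectangular projection; ignored in planar mode.
#' @param mode `"lonlat"` (trip endpoints are longitude/latitude) or
#'   `"planar"` (endpoints already in metres).
#' @return a `grid_spec` list.
#' @export
grid_spec <- function(cell_side = 100, n_cols, n_rows,
                      origin = c(0, 0), reference_latitude = 40.7,
                      mode = c("lonlat", "planar")) {
  mode <- match.arg(mode)
  if (cell_side <= 0) stop_invalid("cell_side must be > 0")
  if (n_cols < 1 || n_rows < 1) stop_invalid("grid must have >= 1 cell")
  structure(list(cell_side = cell_side, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), origin = origin,
                 reference_latitude = reference_latitude, mode = mode),
            class = "grid_spec")
}

#' Project lon/lat points to the grid's planar frame
#'
#' Equirectangular projection about the grid's reference latitude:
#' `x = 111320 * cos(lat_ref) * (lon - lon0)`, `y = 111320 * (lat - lat0)`,
#' both in metres. In planar mode the points are only translated by the grid
#' origin.
#'
#' @param points two-column matrix (or data frame) of lon/lat degrees, or
#'   planar metres in planar mode.
#' @param grid a `grid_spec`.
#' @return a two-column matrix of planar metres; rows with non-finite input
#'   become `NA` (skipped and counted by downstream operations).
#' @export
project_point <- function(points, grid) {
  p <- as.matrix(points)
  if (ncol(p) != 2L) stop_invalid("points must have two columns")
  bad <- !is.finite(p[, 1]) | !is.finite(p[, 2])
  if (grid$mode == "planar") {
    xy <- cbind(x = p[, 1] - grid$origin[1], y = p[, 2] - grid$origin[2])
  } else {
    mx <- METRES_PER_DEG * cos(grid$reference_latitude * pi / 180)
    xy <- cbind(x = mx * (p[, 1] - grid$origin[1]),
                y = METRES_PER_DEG * (p[, 2] - grid$origin[2]))
  }
  xy[bad, ] <- NA_real_
  xy
}

#' Assign planar points to grid cells
#'
#' @param xy two-column matrix of planar metres in the grid frame.
#' @param grid a `grid_spec`.
#' @return data frame with integer `row`, `col` (0-based, from the south-west)
#'   and logical `in_bounds`; out-of-bounds or non-finite points have
#'   `in_bounds = FALSE` and `NA` indices.
#' @export
assign_zone <- function(xy, grid) {
  xy <- as.matrix(xy)
  col <- floor(xy[, 1] / grid$cell_side)
  row <- floor(xy[, 2] / grid$cell_side)
  inb <- is.finite(col) & is.finite(row) &
    col >= 0 & col < grid$n_cols & row >= 0 & row < grid$n_rows
  col[!inb] <- NA_real_
  row[!inb] <- NA_real_
  data.frame(row = as.integer(row), col = as.integer(col), in_bounds = inb)
}

# internal: per-trip cell assignment; a trip is in-bounds only if both
# endpoints are.
trip_cells <- function(trips, grid) {
  if (attr_mode(trips) == "lonlat") {
    pu <- cbind(trips$pickup_longitude, trips$pickup_latitude)
    do <- cbind(trips$dropoff_longitude, trips$dropoff_latitude)
  } else {
    pu <- cbind(trips$pickup_x, trips$pickup_y)
    do <- cbind(trips$dropoff_x, trips$dropoff_y)
  }
  a <- assign_zone(project_point(pu, grid), grid)
  b <- assign_zone(project_point(do, grid), grid)
  keep <- a$in_bounds & b$in_bounds
  list(origin = a, dest = b, keep = keep)
}

attr_mode <- function(trips) {
  m <- attr(trips, "mode")
  if (!is.null(m)) return(m)
  if ("pickup_longitude" %in% names(trips)) "lonlat" else "planar"
}

#' Count trip departures and arrivals per grid cell
#'
#' Trips with either endpoint outside the grid (or non-finite) are excluded
#' from both surfaces and counted in `n_excluded`.
#'
#' @param trips a `trip_table`.
#' @param grid a `grid_spec`.
#' @return list with `origins` and `destinations` (integer `n_rows x n_cols`
#'   matrices), `n_in_bounds` and `n_excluded`.
#' @export
count_endpoints <- function(trips, grid) {
  tc <- trip_cells(trips, grid)
  nr <- grid$n_rows; nc <- grid$n_cols
  idx <- function(z) z$row[tc$keep] * nc + z$col[tc$keep] + 1L
  origins <- matrix(tabulate(idx(tc$origin), nbins = nr * nc),
                    nrow = nr, byrow = TRUE)
  destinations <- matrix(tabulate(idx(tc$dest), nbins = nr * nc),
                         nrow = nr, byrow = TRUE)
  list(origins = origins, destinations = destinations,
       n_in_bounds = sum(tc$keep), n_excluded = sum(!tc$keep))
}

#' Select high-demand zones
#'
#' A cell is a high-demand zone when at least `M` trips depart from it AND at
#' least `M` trips arrive at it.
#'
#' @param counts the result of [count_endpoints()].
#' @param grid the `grid_spec` the counts were computed on.
#' @param M demand threshold (default 1000).
#' @return a `zone_set` data frame: `zone_id` (1..N, row-major from the
#'   south-west), `row`, `col`, centroid `x`, `y` metres (plus `lon`, `lat`
#'   in lon/lat mode), `departures`, `arrivals`.
#' @export
select_high_demand <- function(counts, grid, M = 1000) {
  if (M < 1) stop_invalid("M must be >= 1")
  keep <- counts$origins >= M & counts$destinations >= M
  if (!any(keep)) {
    stop_invalid(paste0(
      "no zone meets the high-demand threshold M = %d ",
      "(max departures %d, max arrivals %d)"),
      M, max(counts$origins), max(counts$destinations))
  }
  w <- which(t(keep)) - 1L  # row-major order
  nc <- grid$n_cols
  row <- w %/% nc
  col <- w %% nc
  zs <- data.frame(
    zone_id = seq_along(w),
    row = as.integer(row), col = as.integer(col),
    x = (col + 0.5) * grid$cell_side,
    y = (row + 0.5) * grid$cell_side,
    departures = counts$origins[cbind(row + 1L, col + 1L)],
    arrivals = counts$destinations[cbind(row + 1L, col + 1L)]
  )
  if (grid$mode == "lonlat") {
    mx <- METRES_PER_DEG * cos(grid$reference_latitude * pi / 180)
    zs$lon <- grid$origin[1] + zs$x / mx
    zs$lat <- grid$origin[2] + zs$y / METRES_PER_DEG
  }
  attr(zs, "M") <- M
  attr(zs, "grid") <- grid
  class(zs) <- c("zone_set", "data.frame")
  zs
}

#' Restrict trips to a set of high-demand zones
#'
#' Keeps trips whose endpoints both fall in selected zones, annotating each
#' retained trip with its origin and destination `zone_id`.
#'
#' @param trips a `trip_table`.
#' @param zoneset a `zone_set` from [select_high_demand()].
#' @return list with `trips` (annotated subset), `fraction` retained (of the
#'   in-bounds trips) and `n_in_bounds`.
#' @export
restrict_trips <- function(trips, zoneset) {
  if (nrow(zoneset) == 0L) stop_invalid("zoneset is empty")
  grid <- attr(zoneset, "grid")
  tc <- trip_cells(trips, grid)
  nc <- grid$n_cols
  lut <- rep(NA_integer_, grid$n_rows * nc)
  lut[zoneset$row * nc + zoneset$col + 1L] <- zoneset$zone_id
  oid <- did <- rep(NA_integer_, nrow(trips))
  oid[tc$keep] <- lut[tc$origin$row[tc$keep] * nc + tc$origin$col[tc$keep] + 1L]
  did[tc$keep] <- lut[tc$dest$row[tc$keep] * nc + tc$dest$col[tc$keep] + 1L]
  sel <- !is.na(oid) & !is.na(did)
  out <- trips[sel, , drop = FALSE]
  out$origin_zone <- oid[sel]
  out$dest_zone <- did[sel]
  attr(out, "mode") <- attr_mode(trips)
  class(out) <- c("trip_table", "data.frame")
  n_in <- sum(tc$keep)
  list(trips = out, fraction = if (n_in > 0) nrow(out) / n_in else NA_real_,
       n_in_bounds = n_in)
}

#' Inter-zone distance matrix
#'
#' Great-circle (haversine, Earth radius 6371.0088 km) distances between zone
#' centroids when lon/lat coordinates are available, Euclidean distances in
#' planar mode.
#'
#' @param zones a `zone_set` or `zone_layout` (any data frame with either
#'   `lon`/`lat` or planar `x`/`y` metre columns).
#' @return symmetric N x N matrix of distances in km with zero diagonal.
#' @export
zone_distances <- function(zones) {
  if (all(c("lon", "lat") %in% names(zones))) {
    n <- nrow(zones)
    p <- cbind(zones$lon, zones$lat)
    D <- geosphere::distm(p, p, fun = function(a, b)
      geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)) / 1000
    dimnames(D) <- NULL
  } else {
    D <- as.matrix(stats::dist(cbind(zones$x, zones$y))) / 1000
    dimnames(D) <- NULL
  }
  diag(D) <- 0
  D
}

#' Geographic displacement of each trip
#'
#' Distance in km between pickup and dropoff points (haversine in lon/lat
#' mode, Euclidean in planar mode).
#'
#' @param trips a `trip_table`.
#' @return numeric vector of km.
#' @export
trip_distances <- function(trips) {
  if (attr_mode(trips) == "lonlat") {
    haversine_km(cbind(trips$pickup_longitude, trips$pickup_latitude),
                 cbind(trips$dropoff_longitude, trips$dropoff_latitude))
  } else {
    sqrt((trips$pickup_x - trips$dropoff_x)^2 +
         (trips$pickup_y - trips$dropoff_y)^2) / 1000
  }
}
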