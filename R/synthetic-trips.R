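# Synthetic trip-table generation: zone layouts, heavy-tailed attractiveness
# weights, and trips drawn from the local/long-range distance kernel. The
# generator reproduces the statistical structure the downstream analysis
# assumes, so the full pipeline is testable without any external trip data.

#' Create a synthetic zone layout
#'
#' Places `n_zones` zone centres inside a rectangle. Zones stand in for the
#' high-demand grid cells of a real city: each is the centre of a square cell
#' of side `cell_side` metres.
#'
#' @param kind layout geometry: `"lattice"` (zones at the centres of a regular
#'   grid of cells, filled row-major from the south-west), `"uniform-random"`
#'   (uniform over the rectangle) or `"clustered"` (Gaussian clusters around
#'   uniformly placed centres, emulating demand hot-spots).
#' @param n_zones number of zones (>= 2).
#' @param extent rectangle dimensions in km, length-2 `c(width, height)` (a
#'   single value is recycled to a square).
#' @param seed optional integer seed; fixed seed gives a bit-reproducible
#'   layout.
#' @param cell_side zone cell side in metres (default 100).
#' @return a `zone_layout` data frame with columns `zone_id`, `x`, `y`
#'   (planar metres from the south-west corner) and attributes `cell_side`,
#'   `extent_m`, `mode = "planar"`.
#' @export
#' @examples
#' make_zone_layout("lattice", 4, extent = 0.2)
make_zone_layout <- function(kind = c("uniform-random", "lattice", "clustered"),
                             n_zones, extent, seed = NULL, cell_side = 100) {
  kind <- match.arg(kind)
  if (length(extent) == 1L) extent <- c(extent, extent)
  extent_m <- extent * 1000
  if (any(!is.finite(extent_m)) || any(extent_m <= 0)) {
    stop_invalid("extent must be positive (km)")
  }
  if (!is.finite(n_zones) || n_zones < 2) stop_invalid("n_zones must be >= 2")
  n_zones <- as.integer(n_zones)
  if (cell_side <= 0) stop_invalid("cell_side must be > 0")
  if (!is.null(seed)) set.seed(seed)

  if (kind == "lattice") {
    n_cols <- max(1L, floor(extent_m[1] / cell_side))
    n_rows <- max(1L, floor(extent_m[2] / cell_side))
    if (n_cols * n_rows < n_zones) {
      stop_invalid("lattice of %d x %d cells cannot host %d zones",
                   n_rows, n_cols, n_zones)
    }
    cells <- seq_len(n_zones) - 1L
    col <- cells %% n_cols
    row <- cells %/% n_cols
    x <- (col + 0.5) * cell_side
    y <- (row + 0.5) * cell_side
  } else if (kind == "uniform-random") {
    x <- stats::runif(n_zones, 0, extent_m[1])
    y <- stats::runif(n_zones, 0, extent_m[2])
  } else { # clustered
    n_clusters <- max(2L, ceiling(n_zones / 100))
    cx <- stats::runif(n_clusters, 0, extent_m[1])
    cy <- stats::runif(n_clusters, 0, extent_m[2])
    assign <- sample.int(n_clusters, n_zones, replace = TRUE)
    sd <- 0.08 * min(extent_m)
    x <- pmin(pmax(stats::rnorm(n_zones, cx[assign], sd), 0), extent_m[1])
    y <- pmin(pmax(stats::rnorm(n_zones, cy[assign], sd), 0), extent_m[2])
  }

  layout <- data.frame(zone_id = seq_len(n_zones), x = x, y = y)
  if (anyDuplicated(layout[, c("x", "y")])) {
    # jitter exact duplicates minimally so positions stay unique
    dup <- duplicated(layout[, c("x", "y")])
    layout$x[dup] <- layout$x[dup] + stats::runif(sum(dup), 0, 1e-6)
  }
  attr(layout, "cell_side") <- cell_side
  attr(layout, "extent_m") <- extent_m
  attr(layout, "mode") <- "planar"
  class(layout) <- c("zone_layout", "data.frame")
  layout
}

#' Wrap a planar layout onto longitude/latitude coordinates
#'
#' Inverts the equirectangular projection about a reference latitude so that
#' synthetic planar layouts can exercise the lon/lat gridding path end to end.
#'
#' @param layout a `zone_layout` in planar mode.
#' @param origin_lonlat lon/lat (degrees) of the layout's south-west corner.
#' @param reference_latitude latitude (degrees) used to scale longitude.
#' @return the layout with added `lon`, `lat` columns and `mode = "lonlat"`.
#' @export
layout_to_lonlat <- function(layout, origin_lonlat = c(-74.05, 40.55),
                             reference_latitude = 40.7) {
  stopifnot(inherits(layout, "zone_layout"))
  layout$lon <- origin_lonlat[1] +
    layout$x / (METRES_PER_DEG * cos(reference_latitude * pi / 180))
  layout$lat <- origin_lonlat[2] + layout$y / METRES_PER_DEG
  attr(layout, "mode") <- "lonlat"
  attr(layout, "origin_lonlat") <- origin_lonlat
  attr(layout, "reference_latitude") <- reference_latitude
  layout
}

#' Sample from the heavy-tailed degree models
#'
#' Draws `n` values at or above `k_min` from one of the two candidate degree
#' distributions used throughout the analysis:
#'
#' * `"stretched_exponential"`: density
#'   \eqn{p(k) = \beta\lambda k^{\beta-1} e^{-\lambda(k^\beta - k_{min}^\beta)}},
#'   sampled exactly by inverse CDF,
#'   \eqn{k = (k_{min}^\beta - \log(1-u)/\lambda)^{1/\beta}}.
#' * `"powerlaw_cutoff"`: density
#'   \eqn{p(k) \propto k^{-\gamma} e^{-\lambda k}} on \eqn{[k_{min},\infty)},
#'   sampled by rejection against a shifted exponential proposal
#'   \eqn{k_{min} + Exp(\lambda)} with acceptance probability
#'   \eqn{(k_{min}/k)^\gamma} (valid for \eqn{\gamma > 0}). A warning is
#'   emitted when the empirical acceptance rate falls below `1e-3`.
#'
#' @param model `"stretched_exponential"` or `"powerlaw_cutoff"`.
#' @param params named list: SE needs `beta > 0` and `lambda > 0`; the cutoff
#'   model needs `gamma > 0` and `lambda > 0`.
#' @param k_min lower support bound (> 0).
#' @param n number of draws (>= 0).
#' @param seed optional integer seed.
#' @return numeric vector of `n` values, all `>= k_min`.
#' @export
#' @examples
#' k <- sample_degree_values("stretched_exponential",
#'                           list(beta = 1, lambda = 0.01), k_min = 100,
#'                           n = 1000, seed = 1)
#' mean(k)  # ~ k_min + 1/lambda for beta = 1
sample_degree_values <- function(model = c("stretched_exponential", "powerlaw_cutoff"),
                                 params, k_min, n, seed = NULL) {
  model <- match.arg(model)
  if (!is.finite(n) || n < 0) stop_invalid("n must be >= 0")
  if (!is.finite(k_min) || k_min <= 0) stop_invalid("k_min must be > 0")
  lambda <- params$lambda
  if (is.null(lambda) || lambda <= 0) stop_invalid("params$lambda must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (n == 0L) return(numeric(0))

  if (model == "stretched_exponential") {
    beta <- params$beta
    if (is.null(beta) || beta <= 0) stop_invalid("params$beta must be > 0")
    u <- stats::runif(n)
    return((k_min^beta - log1p(-u) / lambda)^(1 / beta))
  }

  gamma_ <- params$gamma
  if (is.null(gamma_) || gamma_ <= 0) stop_invalid("params$gamma must be > 0")
  out <- numeric(0)
  proposed <- 0
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 1000L)
    cand <- k_min + stats::rexp(m, rate = lambda)
    keep <- stats::runif(m) < (k_min / cand)^gamma_
    out <- c(out, cand[keep])
    proposed <- proposed + m
    if (proposed > 1000 && length(out) / proposed < 1e-3) {
      warning(sprintf(
        "powerlaw_cutoff rejection acceptance rate %.2g is below 1e-3; sampling will be slow",
        length(out) / proposed))
      proposed <- -Inf # warn once
    }
  }
  out[seq_len(n)]
}

#' Generate a synthetic trip table
#'
#' Draws `n_trips` independent trips: the origin zone is sampled proportional
#' to `weights` (the zone attractiveness, standing in for the out-degree),
#' and the destination from the origin's row of the model transition matrix
#' built from the layout distances with the piecewise kernel (constant within
#' `R` km, truncated-Levy \eqn{(R/d) e^{-\beta(d-R)}} beyond). Emitted
#' coordinates are the zone centre plus, if `jitter = TRUE`, an independent
#' uniform offset within the half-open cell square, mimicking GPS endpoints
#' scattered inside grid cells.
#'
#' @param layout a `zone_layout` (planar, or lon/lat via [layout_to_lonlat()]).
#' @param weights non-negative origin weights, length `nrow(layout)`; `NULL`
#'   for uniform.
#' @param kernel_R kernel breakpoint in km.
#' @param kernel_beta kernel decay rate in 1/km (>= 0).
#' @param n_trips number of trips (>= 0).
#' @param seed optional integer seed; fixed seed gives a byte-identical table.
#' @param jitter scatter endpoints uniformly within their cell (default TRUE).
#' @return a `trip_table` data frame with TLC-like columns
#'   (`pickup_datetime`, `dropoff_datetime`, endpoint coordinates — `lon`/`lat`
#'   when the layout carries them, else planar `x`/`y` metres) plus the true
#'   `origin_zone` and `dest_zone` indices for validation.
#' @export
generate_trips <- function(layout, weights = NULL, kernel_R = 1.8,
                           kernel_beta = 0.15, n_trips, seed = NULL,
                           jitter = TRUE) {
  stopifnot(inherits(layout, "zone_layout"))
  n_zones <- nrow(layout)
  if (is.null(weights)) weights <- rep(1, n_zones)
  if (length(weights) != n_zones || any(weights < 0) || !any(weights > 0)) {
    stop_invalid("weights must be non-negative, length nrow(layout), not all zero")
  }
  if (!is.finite(n_trips) || n_trips < 0) stop_invalid("n_trips must be >= 0")
  if (kernel_R <= 0 || kernel_beta < 0) stop_invalid("invalid kernel parameters")
  if (!is.null(seed)) set.seed(seed)
  n_trips <- as.integer(n_trips)

  D <- zone_distances(layout)
  W <- model_transition_matrix(D, kernel_R, kernel_beta)

  if (n_trips == 0L) {
    origin <- dest <- integer(0)
  } else {
    origin <- sample.int(n_zones, n_trips, replace = TRUE,
                         prob = weights / sum(weights))
    dest <- sample_destinations(W, origin)
  }

  cell <- attr(layout, "cell_side")
  ox <- layout$x[origin]; oy <- layout$y[origin]
  dx <- layout$x[dest];   dy <- layout$y[dest]
  if (jitter && n_trips > 0L) {
    ox <- ox + stats::runif(n_trips, -cell / 2, cell / 2)
    oy <- oy + stats::runif(n_trips, -cell / 2, cell / 2)
    dx <- dx + stats::runif(n_trips, -cell / 2, cell / 2)
    dy <- dy + stats::runif(n_trips, -cell / 2, cell / 2)
  }

  # synthetic sequential timestamps; the analysis itself never uses time
  t0 <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")
  pickup <- t0 + seq_len(n_trips) * 60
  trips <- data.frame(
    pickup_datetime = format(pickup, "%Y-%m-%d %H:%M:%S"),
    dropoff_datetime = format(pickup + 600, "%Y-%m-%d %H:%M:%S"),
    stringsAsFactors = FALSE
  )
  if (identical(attr(layout, "mode"), "lonlat")) {
    ref <- attr(layout, "reference_latitude")
    org <- attr(layout, "origin_lonlat")
    mx <- METRES_PER_DEG * cos(ref * pi / 180)
    trips$pickup_longitude <- org[1] + ox / mx
    trips$pickup_latitude <- org[2] + oy / METRES_PER_DEG
    trips$dropoff_longitude <- org[1] + dx / mx
    trips$dropoff_latitude <- org[2] + dy / METRES_PER_DEG
  } else {
    trips$pickup_x <- ox
    trips$pickup_y <- oy
    trips$dropoff_x <- dx
    trips$dropoff_y <- dy
  }
  trips$origin_zone <- origin
  trips$dest_zone <- dest
  attr(trips, "mode") <- attr(layout, "mode")
  class(trips) <- c("trip_table", "data.frame")
  trips
}

#' Write / read a trip table as TLC-like CSV
#'
#' Coordinates are written with six decimals, matching the precision of the
#' public taxi-record dialect.
#'
#' @param trips a `trip_table`.
#' @param path CSV file path.
#' @return `write_trips` returns `path` invisibly; `read_trips` returns a
#'   `trip_table`.
#' @export
write_trips <- function(trips, path) {
  out <- as.data.frame(trips)
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("origin_zone", "dest_zone")
  out[num] <- lapply(out[num], function(v) sprintf("%.6f", v))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trips
#' @export
read_trips <- function(path) {
  trips <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(trips, "mode") <- if ("pickup_longitude" %in% names(trips)) "lonlat" else "planar"
  class(trips) <- c("trip_table", "data.frame")
  trips
}
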