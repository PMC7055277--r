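# Origin-destination matrix construction and displacement statistics.

#' Build the origin-destination matrix
#'
#' Counts trips between zones into a sparse N x N integer matrix `T` whose
#' entry `T[i, j]` is the number of trips from zone `i` to zone `j` (the
#' diagonal holds self-loop trips). In-degrees are column sums (total
#' arrivals), out-degrees row sums (total departures); their common total is
#' the number of trips, an identity asserted on every build.
#'
#' @param trips a `trip_table` carrying `origin_zone` and `dest_zone` columns
#'   (from [generate_trips()] or [restrict_trips()]).
#' @param n_zones number of zones N; defaults to the largest id seen.
#' @return an `od_matrix` list: `T` (sparse dgCMatrix), `k_in`, `k_out`,
#'   `total`.
#' @export
build_od <- function(trips, n_zones = NULL) {
  o <- trips$origin_zone
  d <- trips$dest_zone
  if (is.null(o) || is.null(d)) {
    stop("trips lack zone annotations; run restrict_trips() first")
  }
  if (anyNA(o) || anyNA(d)) stop("NA zone ids in trip table")
  if (is.null(n_zones)) n_zones <- max(o, d, 0L)
  if (length(o) && (max(o, d) > n_zones || min(o, d) < 1L)) {
    stop("trip references a zone outside 1..n_zones")
  }
  T_ <- Matrix::sparseMatrix(i = o, j = d, x = rep(1, length(o)),
                             dims = c(n_zones, n_zones))
  k_out <- Matrix::rowSums(T_)
  k_in <- Matrix::colSums(T_)
  total <- sum(k_out)
  stopifnot(isTRUE(all.equal(sum(k_in), total)),
            isTRUE(all.equal(sum(T_), total)))
  structure(list(T = T_, k_in = k_in, k_out = k_out, total = total),
            class = "od_matrix")
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("od_matrix: %d zones, %d trips, %d non-null links\n",
              nrow(x$T), as.integer(x$total), Matrix::nnzero(x$T)))
  invisible(x)
}

#' Displacement statistics
#'
#' Uniform-bin frequencies of trip displacements, their mean and maximum, and
#' the fraction of trips falling in each of a set of half-open distance
#' intervals `[a, b)`. The default intervals separate local trips
#' (`0 <= d < 1.8` km), long-range trips (`1.8 <= d < 20` km) and the far
#' tail (`d >= 20` km).
#'
#' @param d numeric vector of displacements in km (>= 0), or a `trip_table`
#'   (distances computed via [trip_distances()]).
#' @param bin_width uniform bin width in km (default 0.5, i.e. 500 m).
#' @param intervals increasing breakpoints in km defining half-open intervals;
#'   default `c(0, 1.8, 20, Inf)`.
#' @return a `displacement_stats` list: `freq` data frame (`bin_left`,
#'   `bin_right`, `count`), `mean_km`, `max_km`, `fractions` (named, summing
#'   to 1) and `n`.
#' @export
displacement_stats <- function(d, bin_width = 0.5,
                               intervals = c(0, 1.8, 20, Inf)) {
  if (inherits(d, "trip_table")) d <- trip_distances(d)
  d <- as.numeric(d)
  if (length(d) == 0L) stop("no displacements to analyse")
  if (any(!is.finite(d)) || any(d < 0)) stop("displacements must be finite and >= 0")
  breaks <- seq(0, max(d, bin_width) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(d, breaks, left.open = FALSE),
                     nbins = length(breaks) - 1L)
  labels <- sprintf("[%g, %g)", utils::head(intervals, -1), intervals[-1])
  frac <- tabulate(findInterval(d, intervals, left.open = FALSE),
                   nbins = length(intervals) - 1L) / length(d)
  names(frac) <- labels
  structure(list(
    freq = data.frame(bin_left = utils::head(breaks, -1),
                      bin_right = breaks[-1], count = counts),
    mean_km = mean(d), max_km = max(d), fractions = frac, n = length(d)),
    class = "displacement_stats")
}

#' @export
print.displacement_stats <- function(x, ...) {
  cat(sprintf("displacements: n = %d, mean = %.4g km, max = %.4g km\n",
              x$n, x$mean_km, x$max_km))
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %s km: %.2f%%\n", names(x$fractions)[i],
                100 * x$fractions[i]))
  }
  invisible(x)
}
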