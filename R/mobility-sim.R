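# The local/long-range mobility model and its Monte Carlo simulator.
# Transition weights are constant up to a breakpoint R and decay as a
# truncated Levy kernel (R/d) * exp(-beta (d - R)) beyond; trips start from
# zones drawn proportional to their out-degree.

#' Piecewise kernel weight
#'
#' \deqn{\Omega(d) = 1 \ \mathrm{for}\ 0 \le d \le R, \qquad
#'       \Omega(d) = (R/d)\, e^{-\beta (d - R)} \ \mathrm{for}\ d > R.}
#' Continuous at `d = R`, strictly decreasing beyond, in `(0, 1]` everywhere.
#'
#' @param d distance(s) in km (>= 0).
#' @param R breakpoint in km (> 0).
#' @param beta decay rate in 1/km (>= 0); `beta = 0` leaves the pure `R/d`
#'   factor, `beta -> Inf` suppresses long-range moves entirely.
#' @return numeric vector of weights.
#' @export
#' @examples
#' omega_weight(c(1, 1.8, 3.6), R = 1.8, beta = 0.15)
omega_weight <- function(d, R, beta) {
  if (any(d < 0) || R <= 0 || beta < 0) stop_invalid("need d >= 0, R > 0, beta >= 0")
  ifelse(d <= R, 1, (R / d) * exp(-beta * (d - R)))
}

#' Model transition matrix from a distance matrix
#'
#' Row-normalised kernel weights:
#' `w[i, j] = Omega(d[i, j]) / sum_l Omega(d[i, l])`. The diagonal is
#' included (`d = 0` gives weight 1), so self-loop trips are allowed.
#'
#' @param D distance matrix in km (zero diagonal).
#' @param R breakpoint in km.
#' @param beta decay rate in 1/km.
#' @return dense row-stochastic matrix.
#' @export
model_transition_matrix <- function(D, R, beta) {
  if (any(diag(D) != 0)) stop_invalid("D must have a zero diagonal")
  Om <- omega_weight(D, R, beta)
  Om / rowSums(Om)
}

#' Monte Carlo trip simulation from a model transition matrix
#'
#' Draws `n` independent trips: origin zone proportional to `origin_weights`
#' (typically the empirical out-degrees), destination from the origin's row
#' of `w_model` using per-row cumulative tables built once. Draws are
#' reproducible given a seed: origins are drawn first, then destinations row
#' by row in increasing origin index.
#'
#' @param w_model row-stochastic model matrix.
#' @param origin_weights non-negative weights, not all zero.
#' @param n number of trips (>= 0).
#' @param seed optional integer seed.
#' @param D optional distance matrix; when supplied, per-trip displacements
#'   are returned too.
#' @return data frame `origin`, `dest` (and `d_km` when `D` is given).
#' @export
simulate_trips <- function(w_model, origin_weights, n, seed = NULL, D = NULL) {
  check_row_stochastic(w_model)
  if (any(origin_weights < 0) || !any(origin_weights > 0)) {
    stop_invalid("origin_weights must be non-negative and not all zero")
  }
  if (!is.finite(n) || n < 0) stop_invalid("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  n_zones <- nrow(w_model)
  if (n == 0L) {
    out <- data.frame(origin = integer(0), dest = integer(0))
    if (!is.null(D)) out$d_km <- numeric(0)
    return(out)
  }
  pw <- cumsum(origin_weights / sum(origin_weights))
  pw[n_zones] <- 1
  origin <- findInterval(stats::runif(n), pw, left.open = TRUE) + 1L
  dest <- sample_destinations(as.matrix(w_model), origin)
  out <- data.frame(origin = origin, dest = dest)
  if (!is.null(D)) out$d_km <- D[cbind(origin, dest)]
  out
}

#' Displacement density over logarithmically spaced bins
#'
#' Normalised probability density of displacements over log-spaced bins; by
#' default 50 bins spanning 100 m to 40 km, the window in which zone-level
#' displacements are resolved (self-loops, at distance 0, fall outside it).
#' The density integrates to 1 over the retained window.
#'
#' @param d_km displacements in km.
#' @param window length-2 window in km (default `c(0.1, 40)`).
#' @param n_bins number of bins (default 50).
#' @return data frame `bin_left_km`, `bin_right_km`, `count`, `density`, with
#'   attribute `n_in_window`.
#' @export
displacement_density <- function(d_km, window = c(0.1, 40), n_bins = 50) {
  d <- d_km[is.finite(d_km)]
  if (!length(d)) stop("no displacements")
  breaks <- 10^seq(log10(window[1]), log10(window[2]), length.out = n_bins + 1)
  inw <- d >= window[1] & d <= window[2]
  cnt <- tabulate(findInterval(d[inw], breaks, rightmost.closed = TRUE),
                  nbins = n_bins)
  widths <- diff(breaks)
  dens <- if (sum(cnt) > 0) cnt / (sum(cnt) * widths) else rep(0, n_bins)
  out <- data.frame(bin_left_km = utils::head(breaks, -1),
                    bin_right_km = breaks[-1], count = cnt, density = dens)
  attr(out, "n_in_window") <- sum(inw)
  out
}

#' Compare two displacement samples on a common binned CDF
#'
#' Reports the Kolmogorov-Smirnov distance between the binned CDFs and the
#' total-variation distance between the binned probability masses. Metrics
#' are reported, not thresholded: the model/data comparison is diagnostic.
#'
#' @param d_a,d_b displacement vectors in km.
#' @param window,n_bins as in [displacement_density()].
#' @return list `ks`, `tv`, `n_a`, `n_b`.
#' @export
compare_displacements <- function(d_a, d_b, window = c(0.1, 40), n_bins = 50) {
  da <- displacement_density(d_a, window, n_bins)
  db <- displacement_density(d_b, window, n_bins)
  pa <- da$count / max(1, sum(da$count))
  pb <- db$count / max(1, sum(db$count))
  list(ks = max(abs(cumsum(pa) - cumsum(pb))),
       tv = sum(abs(pa - pb)) / 2,
       n_a = attr(da, "n_in_window"), n_b = attr(db, "n_in_window"))
}
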