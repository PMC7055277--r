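# Internal numerical helpers shared across modules.

# Metres per degree of latitude for the equirectangular projection; the same
# constant converts longitude after scaling by cos(reference latitude).
METRES_PER_DEG <- 111320

# Earth radius (km) fixed for reproducibility across platforms.
EARTH_RADIUS_KM <- 6371.0088

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Upper incomplete gamma function
#'
#' Computes \eqn{\Gamma(s, x) = \int_x^\infty t^{s-1} e^{-t} dt} for real
#' `s` (including zero and negative values, where the integral still
#' converges for `x > 0`) via the recurrence
#' \eqn{\Gamma(s, x) = (\Gamma(s+1, x) - x^s e^{-x}) / s}. The `s = 0` case is
#' the exponential integral \eqn{E_1(x)}; values of `s` within `1e-8` of a
#' non-positive integer are snapped to it to avoid catastrophic cancellation
#' in the recurrence.
#'
#' Needed to normalise the power law with exponential cutoff on a truncated
#' support, where the first argument `1 - gamma` is typically near zero.
#'
#' @param s real first argument (any sign).
#' @param x positive truncation point.
#' @return the value of \eqn{\Gamma(s, x)}.
#' @export
#' @examples
#' upper_inc_gamma(2, 1)            # == gamma(2) * pgamma(1, 2, lower = FALSE)
#' upper_inc_gamma(0, 0.5)          # == E1(0.5)
upper_inc_gamma <- function(s, x) {
  stopifnot(length(s) == 1L, length(x) == 1L, is.finite(s), is.finite(x))
  if (x <= 0 && s <= 0) stop_invalid("upper_inc_gamma: x must be > 0 when s <= 0")
  # snap near non-positive integers (the recurrence divides by s)
  if (s <= 1e-8 && abs(s - round(s)) < 1e-8) s <- round(s)
  if (s > 0) {
    return(gamma(s) * stats::pgamma(x, shape = s, lower.tail = FALSE))
  }
  if (s == 0) {
    return(pracma::expint(x))
  }
  (upper_inc_gamma(s + 1, x) - x^s * exp(-x)) / s
}

# Haversine great-circle distance in km between two lon/lat matrices (degrees).
haversine_km <- function(p1, p2) {
  p1 <- matrix(as.numeric(p1), ncol = 2)
  p2 <- matrix(as.numeric(p2), ncol = 2)
  to <- pi / 180
  dlat <- (p2[, 2] - p1[, 2]) * to
  dlon <- (p2[, 1] - p1[, 1]) * to
  a <- sin(dlat / 2)^2 + cos(p1[, 2] * to) * cos(p2[, 2] * to) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

# Draw one destination index per element of `origins` using per-row cumulative
# tables of the row-stochastic matrix W. Draw order is defined as: rows
# processed in increasing origin index, trips within a row in their original
# order, one uniform deviate per trip.
sample_destinations <- function(W, origins) {
  n <- length(origins)
  dest <- integer(n)
  if (n == 0L) return(dest)
  u <- stats::runif(n)
  idx_by_origin <- split(seq_len(n), origins)
  for (key in names(idx_by_origin)) {
    i <- as.integer(key)
    idx <- idx_by_origin[[key]]
    cum <- cumsum(W[i, ])
    cum[length(cum)] <- 1  # guard against rounding
    dest[idx] <- findInterval(u[idx], cum, left.open = TRUE) + 1L
  }
  dest
}

# argmax mode of a Gaussian KDE (Silverman's rule by default) on a 512-point
# grid. The grid spans the central 0.5-99.5% quantile range of the data:
# per-pair kernel inversions have extremely heavy tails (the divisor d - R
# can be arbitrarily small), and a grid stretched over those tails cannot
# resolve the bulk peak. The mode itself is unaffected by trimming far tails.
kde_argmax <- function(values, bw = "nrd0") {
  qs <- stats::quantile(values, c(0.005, 0.995), names = FALSE)
  v <- values[values >= qs[1] & values <= qs[2]]
  if (length(v) < 10 || qs[1] == qs[2]) v <- values
  d <- stats::density(v, bw = bw, n = 512, from = min(v), to = max(v))
  d$x[which.max(d$y)]
}
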