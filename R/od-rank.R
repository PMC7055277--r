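# Spectral analysis of the transition matrix: eigenvalue spectrum, stationary
# distribution ("OD rank"), mean-field PageRank approximation and its
# closed-form optimal mixing parameter. No teleportation/damping is added:
# disconnected inputs fail loudly instead of being patched.

check_row_stochastic <- function(W, tol = 1e-8) {
  rs <- if (inherits(W, "Matrix")) Matrix::rowSums(W) else rowSums(W)
  if (any(abs(rs - 1) > tol) || any(W < -tol)) {
    stop("W is not row-stochastic", call. = FALSE)
  }
  invisible(rs)
}

#' Eigenvalue spectrum of a transition matrix
#'
#' Full complex spectrum (dense solver), the multiplicity of the unit
#' eigenvalue (tolerance 1e-8 on `|lambda - 1|`), and a strong-connectivity
#' flag cross-checked by component analysis of the non-null pattern. For a
#' row-stochastic matrix all eigenvalue moduli are at most 1 and the unit
#' eigenvalue is simple exactly when the network is a single strongly
#' connected (and aperiodic) piece.
#'
#' @param W row-stochastic matrix (sparse or dense), N <= 1e4 for the dense
#'   solver.
#' @return an `od_spectrum` list: `values` (complex, length N, decreasing
#'   modulus), `unit_multiplicity`, `strongly_connected`.
#' @export
od_spectrum <- function(W) {
  check_row_stochastic(W)
  Wd <- as.matrix(W)
  ev <- eigen(Wd, only.values = TRUE)$values
  ev <- ev[order(-Mod(ev))]
  mult <- sum(Mod(ev - 1) < 1e-8)
  g <- igraph::graph_from_adjacency_matrix(Wd > 0, mode = "directed")
  scc <- igraph::components(g, mode = "strong")$no
  structure(list(values = ev, unit_multiplicity = mult,
                 strongly_connected = scc == 1L),
            class = "od_spectrum")
}

#' @export
print.od_spectrum <- function(x, ...) {
  cat(sprintf("od_spectrum: N = %d, max |lambda| = %.10f, unit multiplicity = %d, %s\n",
              length(x$values), max(Mod(x$values)), x$unit_multiplicity,
              if (x$strongly_connected) "strongly connected" else "NOT strongly connected"))
  invisible(x)
}

#' Stationary distribution of the transition matrix (OD rank)
#'
#' Left unit eigenvector of `W`, normalised to a probability vector: the
#' long-run visit probability of a random walker following the empirical
#' transition probabilities, used to rank zones. Requires a simple unit
#' eigenvalue (checked via strong connectivity of the non-null pattern).
#'
#' @param W row-stochastic matrix.
#' @param method `"power"` (default; power iteration on `p W`) or `"eigen"`
#'   (dense left eigensolver cross-check).
#' @param tol convergence tolerance on successive iterates (default 1e-12);
#'   the returned vector satisfies `max|pW - p| < 1e-10`.
#' @param max_iter maximum number of sweeps (default 1e5).
#' @return numeric probability vector of length N.
#' @export
stationary_dist <- function(W, method = c("power", "eigen"), tol = 1e-12,
                            max_iter = 1e5) {
  method <- match.arg(method)
  check_row_stochastic(W)
  g <- igraph::graph_from_adjacency_matrix(as.matrix(W) > 0, mode = "directed")
  if (igraph::components(g, mode = "strong")$no != 1L) {
    stop("unit eigenvalue is degenerate: the network is not strongly connected",
         call. = FALSE)
  }
  n <- nrow(W)
  if (method == "eigen") {
    e <- eigen(t(as.matrix(W)))
    k <- which.min(Mod(e$values - 1))
    p <- Re(e$vectors[, k])
    p <- abs(p) / sum(abs(p))
  } else {
    p <- rep(1 / n, n)
    converged <- FALSE
    delta <- Inf
    for (it in seq_len(max_iter)) {
      p_new <- as.numeric(p %*% W)
      p_new <- p_new / sum(p_new)
      delta <- max(abs(p_new - p))
      p <- p_new
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      stop(sprintf("power iteration did not converge in %d sweeps (last delta %.3g)",
                   max_iter, delta), call. = FALSE)
    }
  }
  resid <- max(abs(as.numeric(p %*% W) - p))
  if (resid > 1e-10) {
    stop(sprintf("stationary residual %.3g exceeds 1e-10", resid), call. = FALSE)
  }
  p
}

#' Mean-field PageRank approximation of the OD rank
#'
#' `P_i(q) = q / N + (1 - q) * k_in_i / total`: a mixture of a uniform term
#' and in-degree popularity. Sums to 1 exactly for any `q` in `[0, 1]`.
#'
#' @param k_in in-degree vector.
#' @param total total trip count (`sum(k_in)`).
#' @param q mixing parameter in `[0, 1]`.
#' @return numeric vector, same length as `k_in`.
#' @export
meanfield_rank <- function(k_in, total = sum(k_in), q) {
  if (!is.finite(q) || q < 0 || q > 1) stop_invalid("q must be in [0, 1]")
  if (abs(sum(k_in) - total) > 1e-6 * max(1, total)) {
    stop_invalid("sum(k_in) must equal total")
  }
  q / length(k_in) + (1 - q) * k_in / total
}

#' Closed-form optimal mean-field mixing parameter
#'
#' Minimises the quadratic error
#' \eqn{S(q) = \sum_\ell (P^\infty_\ell - P^\infty_\ell(q))^2} between the
#' true stationary vector and its mean-field approximation; the minimiser has
#' the closed form
#' \deqn{q^* = \frac{\sum p_\ell^2 - \sum P^\infty_\ell p_\ell}{\sum p_\ell^2 - 1/N},
#'   \quad p_\ell = k^{(in)}_\ell / \mathcal{T}.}
#'
#' @param p_inf stationary vector (length N, sums to 1).
#' @param k_in in-degree vector.
#' @param total total trips (`sum(k_in)`).
#' @return list with `q_star` and the achieved error `S_qstar`.
#' @export
optimal_q <- function(p_inf, k_in, total = sum(k_in)) {
  p <- k_in / total
  n <- length(p)
  denom <- sum(p^2) - 1 / n
  if (abs(denom) < 1e-15) {
    stop("in-degree distribution is uniform: optimal q is degenerate (0/0)",
         call. = FALSE)
  }
  q_star <- (sum(p^2) - sum(p_inf * p)) / denom
  S <- function(q) sum((p_inf - meanfield_rank(k_in, total, q))^2)
  list(q_star = q_star,
       S_qstar = sum((p_inf - (q_star / n + (1 - q_star) * p))^2),
       S = S)
}

#' Simulate a random walk driven by a transition matrix
#'
#' Sequential Markov chain draws with per-row cumulative tables; used to
#' cross-check the stationary distribution against long-run occupation
#' frequencies.
#'
#' @param W row-stochastic matrix.
#' @param n_steps number of steps.
#' @param start starting state (default 1).
#' @param seed optional integer seed.
#' @return integer vector of visited states, length `n_steps`.
#' @export
simulate_walk <- function(W, n_steps, start = 1L, seed = NULL) {
  check_row_stochastic(W)
  if (!is.null(seed)) set.seed(seed)
  Wd <- as.matrix(W)
  n <- nrow(Wd)
  cum <- t(apply(Wd, 1, cumsum))
  cum[, n] <- 1
  u <- stats::runif(n_steps)
  s <- integer(n_steps)
  cur <- as.integer(start)
  for (t in seq_len(n_steps)) {
    cur <- findInterval(u[t], cum[cur, ], left.open = TRUE) + 1L
    s[t] <- cur
  }
  s
}
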