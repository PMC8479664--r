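# Scaled-Poisson readout model: for a latent cell-type-specific count Z with
# mean lambda and precision t, t*Z ~ Poisson(t*lambda). Mean is lambda and
# variance lambda/t, so t < 1 is overdispersion and t > 1 underdispersion
# relative to Poisson. Counts are non-negative reals (effective counts), so
# the Poisson log-pmf is evaluated through its log-gamma continuation; the
# resulting quasi-likelihood is used unnormalized throughout (only relative
# values matter for the block-coordinate updates and for BIC comparisons made
# under the same convention).

.t_min_default <- 1e-3
.t_max_default <- 1e3

#' Scaled-Poisson quasi-log-likelihood
#'
#' Evaluates `ll(z; lambda, t) = t*z*log(t*lambda) - t*lambda - lgamma(t*z + 1)`,
#' the Poisson log-pmf of `t*Z` at `t*z` with continuous (log-gamma) extension.
#' At `t = 1` and integer `z` this is exactly the Poisson log-pmf. The
#' convention for vanishing means: `lambda = 0` with `z = 0` gives 0,
#' `lambda = 0` with `z > 0` gives `-Inf`.
#'
#' @param z observed (possibly real-valued) count, >= 0. Vectorized.
#' @param mean the mean `lambda`, >= 0.
#' @param precision the readout precision `t`; must lie in `[t_min, t_max]`.
#' @param t_min,t_max admissible precision bounds.
#' @return numeric vector of quasi-log-likelihood values.
#' @examples
#' scaled_poisson_loglik(0, 1, 1)        # -1
#' scaled_poisson_loglik(2, 2, 1)        # log(2) - 2
#' scaled_poisson_loglik(1, 1, 2)        # log(2) - 2 as well
#' @export
scaled_poisson_loglik <- function(z, mean, precision,
                                  t_min = .t_min_default,
                                  t_max = .t_max_default) {
  if (any(z < 0, na.rm = TRUE) || any(mean < 0, na.rm = TRUE))
    stop_domain("z and mean must be non-negative")
  if (any(precision < t_min) || any(precision > t_max))
    stop_domain("precision outside [%g, %g]", t_min, t_max)
  n <- max(length(z), length(mean), length(precision))
  z <- rep_len(z, n); mean <- rep_len(mean, n); precision <- rep_len(precision, n)
  ll <- numeric(n)
  zero_mean <- mean == 0
  ll[zero_mean & z > 0] <- -Inf
  # zero_mean & z == 0 stays 0
  ok <- !zero_mean
  zz <- z[ok]; mm <- mean[ok]; tt <- precision[ok]
  main <- -tt * mm - lgamma(tt * zz + 1)
  pos <- zz > 0
  main[pos] <- main[pos] + (tt * zz * log(tt * mm))[pos]
  ll[ok] <- main
  ll
}

# same formula, no argument checking, for hot loops (matrix inputs fine;
# assumes mean > 0 wherever z > 0, and mean == 0 entries paired with z == 0)
sp_ll_fast <- function(z, mean, precision) {
  tl <- precision * mean
  out <- -tl - lgamma(precision * z + 1)
  pos <- z > 0
  out[pos] <- out[pos] + (precision * z)[pos] * log(tl[pos])
  out[mean == 0 & z == 0] <- 0
  out
}

#' Expected cell-type allocation of an observed count
#'
#' Splits one observed bulk count `y` across `k` cell types in proportion to
#' `x_row * w` (profile times composition). This is the model's conditional
#' expectation of the latent type-specific counts given their observed total,
#' exact under Poisson readout and a proportional approximation otherwise.
#' Components sum to `y` exactly. When `sum(x_row * w) == 0` and `y > 0`, the
#' count is allocated proportionally to `w` alone (zero-denominator fallback),
#' keeping conservation exact for counts the current profile cannot explain.
#'
#' @param y observed count, scalar >= 0.
#' @param x_row length-k non-negative profile values for this gene.
#' @param w length-k composition (simplex) vector.
#' @return length-k non-negative vector summing to `y`.
#' @examples
#' expected_allocation(8, c(1, 3), c(0.5, 0.5))  # 2 and 6
#' @export
expected_allocation <- function(y, x_row, w) {
  if (length(x_row) != length(w))
    stop_domain("x_row and w differ in length")
  if (y < 0 || any(x_row < 0) || any(w < 0))
    stop_domain("negative input to expected_allocation")
  s <- x_row * w
  tot <- sum(s)
  if (tot > 0)
    return(y * s / tot)
  if (y == 0)
    return(numeric(length(w)))
  y * w / sum(w)
}

#' Joint quasi-log-likelihood of the two-block model
#'
#' Sums the scaled-Poisson quasi-log-likelihood over all (gene, cell type,
#' unit) triples of the single-cell block (means `X * W0 * G0`) and the bulk
#' block (means `X * W1 * G1`), evaluated at the given latent allocations.
#'
#' @param sc single-cell [count_matrix()] (used for dimension checks).
#' @param bulk bulk [count_matrix()].
#' @param params list with `X` (m x k), `T` (m x k), `W0` (k x n_sc),
#'   `G0` (n_sc), `W1` (k x n_bulk), `G1` (n_bulk).
#' @param sc_allocation m x k x n_sc array partitioning each single-cell count.
#' @param bulk_allocation m x k x n_bulk array partitioning each bulk count.
#' @return scalar quasi-log-likelihood.
#' @export
joint_loglik <- function(sc, bulk, params, sc_allocation, bulk_allocation) {
  X <- params$X; Tm <- params$T
  m <- nrow(X); k <- ncol(X)
  block <- function(counts, W, G, alloc) {
    n <- ncol(counts$values)
    if (!all(dim(alloc) == c(m, k, n)) || nrow(W) != k || length(G) != n)
      stop_domain("dimension mismatch in joint_loglik")
    tot <- 0
    for (j in seq_len(n)) {
      lam <- X * rep(W[, j] * G[j], each = m)
      tot <- tot + sum(sp_ll_fast(alloc[, , j], lam, Tm))
    }
    tot
  }
  block(sc, params$W0, params$G0, sc_allocation) +
    block(bulk, params$W1, params$G1, bulk_allocation)
}

# --- M-step building blocks -------------------------------------------------

# Profile update: X_il = sum_j Zhat_ilj / sum_j W_lj G_j over all pooled units
# (the precision cancels in the stationarity condition). Zero totals give 0.
# zsum: m x k summed allocations; wg: length-k summed W_lj * G_j.
m_step_expression <- function(zsum, wg) {
  X <- sweep(zsum, 2L, wg, "/")
  X[, wg == 0] <- 0
  X[zsum == 0] <- 0
  X
}

# Composition + scale update for one unit: the free maximizer in
# u_l = w_l * G is u_l = sum_i T_il Zhat_il / sum_i T_il X_il; the simplex
# constraint is restored by normalizing, with the unit scale G absorbing the
# total. All-zero allocations yield a uniform composition (flagged).
m_step_composition <- function(alloc, X, Tm) {
  num <- colSums(Tm * alloc)
  den <- colSums(Tm * X)
  u <- ifelse(den > 0, num / den, 0)
  s <- sum(u)
  if (s <= 0)
    return(list(w = rep(1 / ncol(X), ncol(X)), scale = 0, degenerate = TRUE))
  list(w = u / s, scale = s, degenerate = FALSE)
}

# Precision update by moment matching of the scaled-Poisson variance
# Var(Z) = lambda / t:  t_il = clamp(sum_j lambda_ilj / sum_j (z - lambda)^2).
# Entries with no information (no unit with positive mean) keep their prior
# value; zero empirical variance clamps at t_max.
# lam_sum, resid_sq: m x k sums over units; t_prev: m x k current values.
m_step_precision <- function(lam_sum, resid_sq, t_prev,
                             t_min = .t_min_default, t_max = .t_max_default) {
  t_new <- lam_sum / resid_sq
  t_new[lam_sum == 0] <- t_prev[lam_sum == 0]
  t_new[lam_sum > 0 & resid_sq == 0] <- t_max
  pmin(pmax(t_new, t_min), t_max)
}
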