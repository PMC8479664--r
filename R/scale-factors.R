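#' Trimmed common-profile scale-factor estimation
#'
#' For a set of pure (single-component) samples, estimates a relative scale
#' factor `G[j]` per sample by fitting a common scaled-Poisson subprofile
#' `(x, t)` on the best-fitting fraction `alpha` of genes per sample: for
#' genes `i` in the retained set `Omega[j]` of sample `j`,
#' `t[i] * Z[i,j] ~ Poisson(t[i] * x[i] * G[j])`. Trimming makes the scale
#' estimate robust to genes perturbed in a subset of samples, which would
#' otherwise drag the common profile and the scales with them.
#'
#' The fit alternates: (1) update the common profile `(x, t)` over retained
#' entries (closed-form mean, moment-matched precision accepted per gene only
#' when it improves the objective); (2) update each `G[j]` over its retained
#' genes; (3) re-select `Omega[j]` as the `round(alpha * m)` genes with the
#' highest per-gene quasi-log-likelihood contribution in sample `j` (ties
#' broken by gene index). Re-selection can only increase the trimmed
#' objective, so the trace is monotone; oscillating trim sets (cycle over the
#' last 4 selections) terminate at the best objective seen. The scale gauge is
#' fixed by constraining the geometric mean of `G` to 1.
#'
#' @param counts a [count_matrix()] or genes x samples matrix (m >= 2 genes).
#' @param alpha retained gene fraction per sample, in (0, 1]; default 0.5.
#' @param tol relative tolerance on the trimmed objective.
#' @param max_iter maximum alternation count.
#' @param t_bounds admissible precision range.
#' @return An object of class `scale_fit`: list with `G` (named, geometric
#'   mean 1; `NA` for all-zero samples, which are reported and excluded),
#'   `common_x`, `common_t`, `trim_sets` (list of retained gene index sets,
#'   each of size `round(alpha * m)`), `loglik_trace`, `converged`, `n_iter`,
#'   `alpha`.
#' @examples
#' y1 <- rpois(200, 20)
#' cm <- count_matrix(cbind(s1 = y1, s2 = 3 * y1),
#'                    gene_ids = sprintf("g%d", 1:200), kind = "single_cell")
#' estimate_scale_factors(cm)$G  # ratio 3, geometric mean 1
#' @export
estimate_scale_factors <- function(counts, alpha = 0.5, tol = 1e-8,
                                   max_iter = 200L,
                                   t_bounds = c(.t_min_default, .t_max_default)) {
  cm <- as_count_values(counts, kind = "single_cell")
  Y_all <- cm$values
  m <- nrow(Y_all)
  if (m < 2L)
    stop_validation("need at least 2 genes")
  if (!(alpha > 0 && alpha <= 1))
    stop_validation("alpha must lie in (0, 1]")
  h <- round(alpha * m)
  if (h < 1L)
    stop_validation("alpha * m < 1: no genes would be retained")

  usable <- colSums(Y_all) > 0
  if (!all(usable))
    warning(sprintf("excluding %d all-zero sample(s): %s", sum(!usable),
                    paste(colnames(Y_all)[!usable], collapse = ", ")),
            call. = FALSE)
  Y <- Y_all[, usable, drop = FALSE]
  n <- ncol(Y)
  if (n < 1L)
    stop_validation("no usable samples")
  t_min <- t_bounds[1L]; t_max <- t_bounds[2L]

  contrib <- function(x, tt, G) {
    # per-gene, per-sample quasi-log-likelihood under the common profile
    lam <- x %o% G
    sp_ll_fast(Y, lam, tt)
  }
  select_trim <- function(C) {
    # top-h genes per sample; ties broken by gene index for determinism
    matrix(apply(C, 2L, function(col)
      sort.int(order(-col, seq_along(col))[seq_len(h)])), nrow = h)
  }

  # init: scales from column totals (gauge-fixed), one full-profile fit, then
  # an initial trim selection
  G <- colSums(Y)
  G <- G / exp(mean(log(G)))
  x <- rowSums(Y) / sum(G)
  lam <- x %o% G
  tt <- m_step_precision(matrix(rowSums(lam), ncol = 1L),
                         matrix(rowSums((Y - lam)^2), ncol = 1L),
                         matrix(1, m, 1L), t_min, t_max)[, 1L]
  R <- select_trim(contrib(x, tt, G))           # m_trim x n matrix of indices

  mask_of <- function(R) {
    M <- matrix(FALSE, m, n)
    for (j in seq_len(n)) M[R[, j], j] <- TRUE
    M
  }

  trace <- numeric(0)
  seen_sets <- character(0)
  best <- list(obj = -Inf)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M <- mask_of(R)

    # (1) common profile over retained entries
    x_num <- rowSums(Y * M)
    x_den <- as.numeric(M %*% G)
    x <- ifelse(x_den > 0, x_num / x_den, 0)
    lam <- x %o% G
    lam_sum <- rowSums(lam * M)
    resid <- rowSums(((Y - lam)^2) * M)
    t_cand <- m_step_precision(matrix(lam_sum, ncol = 1L),
                               matrix(resid, ncol = 1L),
                               matrix(tt, ncol = 1L), t_min, t_max)[, 1L]
    masked_rowsums <- function(C) { C[!M] <- 0; rowSums(C) }  # -Inf * 0 safe
    C_old <- masked_rowsums(contrib(x, tt, G))
    C_new <- masked_rowsums(contrib(x, t_cand, G))
    tt <- ifelse(C_new >= C_old, t_cand, tt)

    # (2) per-sample scales over retained genes, then gauge fix
    num <- colSums(Y * M * tt)   # sum over retained genes of t_i z_ij
    den <- colSums(M * (tt * x))
    G_new <- ifelse(den > 0, num / den, G)
    G_new[G_new <= 0] <- G[G_new <= 0]
    G <- G_new
    gauge <- exp(mean(log(G)))
    G <- G / gauge
    x <- x * gauge

    # (3) trim re-selection and the trimmed objective
    C <- contrib(x, tt, G)
    R <- select_trim(C)
    M <- mask_of(R)
    obj <- sum(C[M])

    if (obj > best$obj)
      best <- list(obj = obj, x = x, t = tt, G = G, R = R)

    if (length(trace) > 0L) {
      prev <- trace[length(trace)]
      if (obj < prev) { converged <- TRUE; break }
      trace <- c(trace, obj)
      if (obj - prev <= tol * abs(prev)) { converged <- TRUE; break }
    } else trace <- c(trace, obj)

    key <- paste(R, collapse = ",")
    if (key %in% seen_sets) { converged <- TRUE; break }  # trim-set cycle
    seen_sets <- c(utils::tail(seen_sets, 3L), key)
  }
  if (!converged)
    warning("scale-factor estimation did not converge within max_iter",
            call. = FALSE)

  G_out <- rep(NA_real_, ncol(Y_all))
  names(G_out) <- colnames(Y_all)
  G_out[usable] <- best$G
  trims <- lapply(seq_len(n), function(j) best$R[, j])
  names(trims) <- colnames(Y)
  structure(list(G = G_out, common_x = best$x, common_t = best$t,
                 trim_sets = trims, loglik_trace = trace,
                 converged = converged, n_iter = it, alpha = alpha),
            class = "scale_fit")
}

#' @export
print.scale_fit <- function(x, digits = 4L, ...) {
  cat(sprintf("<scale_fit: %d sample(s), alpha = %g, %s in %d iteration(s)>\n",
              length(x$G), x$alpha,
              if (x$converged) "converged" else "not converged", x$n_iter))
  print(signif(x$G, digits))
  invisible(x)
}

#' @export
coef.scale_fit <- function(object, ...) object$G
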