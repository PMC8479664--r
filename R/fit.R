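#' Decompose a bulk RNA-seq sample against a single-cell reference
#'
#' Fits the joint scaled-Poisson model on one bulk sample (possibly with
#' several replicates sharing expression profiles but not composition) and a
#' labelled single-cell reference. The model assumes latent cell-type-specific
#' counts `Z` with `T[i,l] * Z[i,l,j] ~ Poisson(T[i,l] * X[i,l] * W[l,j] * G[j])`
#' summing to the observed counts, where `X` is the mean expression profile,
#' `T` the per-gene per-type readout precision, `W` the simplex-constrained
#' composition and `G` a per-unit scale factor. Profiles `(X, T)` are shared
#' between the reference and bulk blocks, so the bulk adapts the profiles
#' while the reference anchors them.
#'
#' Fitting is block-coordinate: an expectation step splits every observed
#' count across cell types in proportion to `X * w` (exact under Poisson
#' readout), then closed-form maximization steps update the profile, the
#' precisions (moment matching, accepted only when the objective improves),
#' and the per-unit composition and scale. The `X <-> G` scale ambiguity is
#' resolved by constraining the geometric mean of the reference scale factors
#' to 1 after every update. Iteration stops when the relative change of the
#' joint quasi-log-likelihood falls below `tol`, when the objective stalls
#' (the expectation step is a proportional approximation, so near convergence
#' it can stop improving; the previous iterate is then kept), or at
#' `max_iter`.
#'
#' @param bulk bulk counts for one sample: a [count_matrix()], a numeric
#'   vector, or a genes x replicates matrix with dimnames.
#' @param reference single-cell reference counts, a [count_matrix()] or a
#'   matrix with dimnames.
#' @param labels a [cell_labels()] assigning each reference cell to a type;
#'   when `NULL`, labels are derived by model-based clustering of the
#'   reference ([cluster_profiles()]).
#' @param free_reference when `TRUE` the reference compositions are not pinned
#'   one-hot at their labels but re-estimated (initialized one-hot).
#' @param profiles optional list with fixed `X` and `T` matrices (m x k); when
#'   supplied only compositions and scales are estimated.
#' @param tol relative quasi-log-likelihood convergence tolerance.
#' @param max_iter maximum number of block-coordinate iterations.
#' @param t_bounds admissible precision range `c(t_min, t_max)`.
#' @param verbose print per-iteration objective values.
#' @return An object of class `poisdecon` with components `composition`
#'   (k x replicates, columns on the simplex), `scale` (per replicate), `X`,
#'   `T` (fitted profiles), `allocations` (genes x types x replicates expected
#'   cell-type contributions, summing to the observed counts per gene),
#'   `reference_scales`, `reference_composition`, `loglik_trace`, `converged`,
#'   `n_iter`, `n_fallback`.
#' @seealso [poisdecon_cohort()] for many samples, [write_decomposition()].
#' @examples
#' sim <- simulate_cohort("baseline", seed = 1, m = 120, cells_per_type = 25,
#'                        bulk_depth = 5e4)
#' fit <- poisdecon(sim$bulk$counts, sim$reference$counts, sim$reference$labels,
#'                  tol = 1e-6)
#' coef(fit)
#' @export
poisdecon <- function(bulk, reference, labels = NULL,
                      free_reference = FALSE, profiles = NULL,
                      tol = 1e-8, max_iter = 1000L,
                      t_bounds = c(.t_min_default, .t_max_default),
                      verbose = FALSE) {
  cl <- match.call()
  bulk <- as_count_values(bulk, kind = "bulk")
  reference <- as_count_values(reference, kind = "single_cell")
  if (is.null(labels)) {
    message("no labels supplied; deriving cell types by model-based clustering of the reference")
    labels <- cluster_profiles(reference)$labels
  }
  al <- align_labels(reference, labels)
  reference <- al$counts; labels <- al$labels

  shared <- reference$gene_ids[reference$gene_ids %in% bulk$gene_ids]
  if (length(shared) == 0L)
    stop_validation("bulk and reference share no gene ids")
  n_drop <- (length(reference$gene_ids) - length(shared)) +
    (length(bulk$gene_ids) - length(shared))
  if (n_drop > 0L)
    message(sprintf("gene universes reconciled by id intersection: %d gene(s) dropped, %d retained",
                    n_drop, length(shared)))
  Y0 <- reference$values[shared, , drop = FALSE]
  Y1 <- bulk$values[shared, , drop = FALSE]

  nonzero_cells <- colSums(Y0) > 0
  if (!all(nonzero_cells)) {
    warning(sprintf("dropping %d reference cell(s) with zero total count",
                    sum(!nonzero_cells)), call. = FALSE)
    Y0 <- Y0[, nonzero_cells, drop = FALSE]
    labels <- cell_labels(labels$unit_ids[nonzero_cells],
                          labels$labels[nonzero_cells])
  }
  if (ncol(Y0) == 0L)
    stop_validation("no usable reference cells")
  if (any(colSums(Y1) == 0))
    stop_validation("bulk replicate with zero total count")

  type_names <- labels$type_names
  k <- length(type_names)
  lab <- match(labels$labels, type_names)
  if (!is.null(profiles)) {
    if (ncol(profiles$X) != k || ncol(profiles$T) != k)
      stop_validation("profiles have %d cell types but labels define %d",
                      ncol(profiles$X), k)
    if (nrow(profiles$X) != length(shared))
      stop_validation("profiles row count does not match the shared gene set")
  }

  opts <- list(tol = tol, max_iter = as.integer(max_iter), t_bounds = t_bounds,
               free_reference = isTRUE(free_reference), seed = NULL)
  eng <- if (isTRUE(free_reference))
    fit_engine_general(Y0, lab, k, Y1, profiles, opts, verbose,
                       update_ref_composition = TRUE)
  else
    fit_engine_fixed(Y0, lab, k, Y1, profiles, opts, verbose)

  dimnames(eng$W1) <- list(type_names, colnames(Y1))
  dimnames(eng$X) <- dimnames(eng$T) <- list(shared, type_names)
  dimnames(eng$alloc) <- list(shared, type_names, colnames(Y1))
  structure(list(
    composition = eng$W1,
    scale = stats::setNames(eng$G1, colnames(Y1)),
    X = eng$X, T = eng$T,
    allocations = eng$alloc,
    reference_scales = stats::setNames(eng$G0, labels$unit_ids),
    reference_composition = eng$W0,
    loglik_trace = eng$trace,
    converged = eng$converged, stalled = eng$stalled,
    n_iter = eng$n_iter, n_fallback = eng$n_fallback,
    gene_ids = shared, type_names = type_names,
    labels = labels, options = opts, call = cl),
    class = "poisdecon")
}

# Expectation step for a block of columns: split y[, r] proportionally to
# X * w_r per gene; rows the profile cannot explain (all-zero X * w) fall back
# to allocation proportional to w so conservation stays exact.
allocate_block <- function(Y, X, W) {
  m <- nrow(Y); k <- ncol(X); R <- ncol(Y)
  alloc <- array(0, dim = c(m, k, R))
  fallback <- logical(m)
  for (r in seq_len(R)) {
    num <- X * rep(W[, r], each = m)
    rs <- .rowSums(num, m, k)
    pos <- rs > 0
    a <- num * (Y[, r] / ifelse(pos, rs, 1))
    a[!pos, ] <- 0
    fb <- !pos & Y[, r] > 0
    if (any(fb)) {
      a[fb, ] <- Y[fb, r] %o% (W[, r] / sum(W[, r]))
      fallback <- fallback | fb
    }
    alloc[, , r] <- a
  }
  list(alloc = alloc, fallback = fallback)
}

# Fast engine for the default case: reference compositions pinned one-hot at
# the labels, so the reference allocation is fixed and only per-type
# sufficient statistics of the reference are touched inside the loop.
fit_engine_fixed <- function(Y0, lab, k, Y1, profiles, opts, verbose) {
  m <- nrow(Y0); J <- ncol(Y0); R <- ncol(Y1)
  t_min <- opts$t_bounds[1L]; t_max <- opts$t_bounds[2L]
  fixed_prof <- !is.null(profiles)

  Ind <- matrix(0, J, k); Ind[cbind(seq_len(J), lab)] <- 1
  Zsum0 <- Y0 %*% Ind                  # m x k summed reference counts per type
  S2_0 <- (Y0 * Y0) %*% Ind
  pos0 <- Zsum0 > 0

  # init: scales from column totals (reference gauge-fixed), profile from
  # per-type scale-normalized reference means, unit precisions, uniform w
  G0 <- colSums(Y0)
  G0 <- G0 / exp(mean(log(G0)))
  typeG0 <- as.numeric(crossprod(Ind, G0))
  X <- if (fixed_prof) profiles$X else m_step_expression(Zsum0, typeG0)
  Tm <- if (fixed_prof) profiles$T else matrix(1, m, k)
  W1 <- matrix(1 / k, k, R)
  xw <- colSums(X) / k
  G1 <- colSums(Y1) / max(sum(xw), .Machine$double.xmin)

  # per-(gene,type) reference lgamma sums at precision Tc
  lgam_ref <- function(Tc) lgamma(Tc[, lab, drop = FALSE] * Y0 + 1) %*% Ind

  # quasi-log-likelihood contributions per (gene, type), split so the
  # reference lgamma sums (the expensive part) can be reused; entries the
  # model assigns zero mean but positive allocated count (transient
  # zero-denominator fallback) are excluded, see vignette
  contrib <- function(Tc, X, G0stats, lam1, alloc, Lg) {
    ref <- -Tc * (X * G0stats$typeG0) - Lg
    ref[pos0] <- ref[pos0] +
      (Tc * (Zsum0 * log(Tc * X) + G0stats$ZlogG0))[pos0]
    bulk <- matrix(0, m, k)
    for (r in seq_len(R)) {
      lam <- lam1[, , r]; a <- alloc[, , r]
      term <- -Tc * lam - lgamma(Tc * a + 1)
      p <- a > 0 & lam > 0
      term[p] <- term[p] + (Tc * a * log(Tc * lam))[p]
      term[a > 0 & lam == 0] <- 0  # unexplained counts carry no information
      bulk <- bulk + term
    }
    ref + bulk
  }

  g0_stats <- function(G0) list(
    typeG0 = as.numeric(crossprod(Ind, G0)),
    G2_0 = as.numeric(crossprod(Ind, G0 * G0)),
    YG0 = Y0 %*% (Ind * G0),
    ZlogG0 = Y0 %*% (Ind * log(G0)))

  st <- g0_stats(G0)
  Lg <- lgam_ref(Tm)
  trace <- numeric(0)
  converged <- FALSE; stalled <- FALSE
  n_fallback <- 0L
  snap <- NULL

  # Inner composition equilibration: alternate the (cheap) expectation step
  # with the per-replicate composition/scale update until the composition is
  # stationary under the current profiles. Letting the composition settle
  # before the profile and precision blocks move keeps the profile block from
  # absorbing composition misfit early on (the reference anchors the profiles
  # while the composition finds its optimum under them).
  equilibrate_w <- function(X, Tm, W1, G1, inner_max = 200L, w_tol = 1e-12) {
    for (ii in seq_len(inner_max)) {
      ab <- allocate_block(Y1, X, W1)
      W_old <- W1
      for (r in seq_len(R)) {
        cs <- m_step_composition(ab$alloc[, , r], X, Tm)
        if (!cs$degenerate) {
          W1[, r] <- cs$w
          G1[r] <- cs$scale
        }
      }
      if (max(abs(W1 - W_old)) < w_tol) break
    }
    ab <- allocate_block(Y1, X, W1)
    list(W1 = W1, G1 = G1, alloc = ab$alloc, fallback = ab$fallback)
  }

  for (it in seq_len(opts$max_iter)) {
    # E-step + composition/scale to stationarity (reference allocation is
    # fixed one-hot and does not enter)
    eq <- equilibrate_w(X, Tm, W1, G1)
    W1 <- eq$W1; G1 <- eq$G1; alloc <- eq$alloc
    n_fallback <- sum(eq$fallback)

    # M-step: profile
    if (!fixed_prof) {
      zsum <- Zsum0 + apply(alloc, c(1L, 2L), sum)
      wg <- st$typeG0 + as.numeric(W1 %*% G1)
      X <- m_step_expression(zsum, wg)
    }

    lam1 <- array(0, dim = c(m, k, R))
    for (r in seq_len(R))
      lam1[, , r] <- X * rep(W1[, r] * G1[r], each = m)

    # M-step: precision. Moment matching is not itself an ascent step of the
    # unnormalized quasi-likelihood (near-zero empirical variance drives it to
    # the clamp), so each (gene, type) update is accepted only when its
    # objective contribution does not decrease.
    if (!fixed_prof) {
      lam_sum <- X * st$typeG0
      resid <- S2_0 - 2 * X * st$YG0 + X * X * st$G2_0
      for (r in seq_len(R)) {
        lam_sum <- lam_sum + lam1[, , r]
        resid <- resid + (alloc[, , r] - lam1[, , r])^2
      }
      resid <- pmax(resid, 0)
      Tc <- m_step_precision(lam_sum, resid, Tm, t_min, t_max)
      Lg_c <- lgam_ref(Tc)
      C_old <- contrib(Tm, X, st, lam1, alloc, Lg)
      C_new <- contrib(Tc, X, st, lam1, alloc, Lg_c)
      take <- C_new >= C_old
      Tm[take] <- Tc[take]
      Lg[take] <- Lg_c[take]
    }

    # M-step: per-replicate composition + scale (joint closed form), then
    # reference scales and the gauge fix
    for (r in seq_len(R)) {
      cs <- m_step_composition(alloc[, , r], X, Tm)
      if (!cs$degenerate) {
        W1[, r] <- cs$w
        G1[r] <- cs$scale
      }
    }
    den_type <- colSums(Tm * X)
    G0_num <- colSums(Y0 * Tm[, lab, drop = FALSE])
    G0_new <- G0_num / den_type[lab]
    G0_new[!is.finite(G0_new) | G0_new <= 0] <- G0[!is.finite(G0_new) | G0_new <= 0]
    G0 <- G0_new
    if (!fixed_prof) {   # gauge fix needs the X compensation, so only when X is free
      gauge <- exp(mean(log(G0)))
      G0 <- G0 / gauge
      G1 <- G1 / gauge
      X <- X * gauge
    }

    st <- g0_stats(G0)
    for (r in seq_len(R))
      lam1[, , r] <- X * rep(W1[, r] * G1[r], each = m)
    ll <- sum(contrib(Tm, X, st, lam1, alloc, Lg))
    if (verbose)
      message(sprintf("iter %d: loglik %.6f", it, ll))

    if (it > 1L) {
      prev <- trace[length(trace)]
      if (ll < prev) {          # objective stalled at the approximation floor
        restore <- snap
        X <- restore$X; Tm <- restore$Tm; W1 <- restore$W1
        G1 <- restore$G1; G0 <- restore$G0; alloc <- restore$alloc
        n_fallback <- restore$n_fallback
        converged <- TRUE; stalled <- TRUE
        break
      }
      trace <- c(trace, ll)
      if (ll - prev <= opts$tol * abs(prev)) {
        converged <- TRUE
        break
      }
    } else {
      trace <- c(trace, ll)
    }
    snap <- list(X = X, Tm = Tm, W1 = W1, G1 = G1, G0 = G0, alloc = alloc,
                 n_fallback = n_fallback)
  }
  if (!converged)
    warning("decomposition did not converge within max_iter", call. = FALSE)

  W0 <- t(Ind)
  list(X = X, T = Tm, W1 = W1, G1 = G1, G0 = G0, W0 = W0, alloc = alloc,
       trace = trace, converged = converged, stalled = stalled,
       n_iter = length(trace), n_fallback = n_fallback)
}

# General engine: every unit (reference cell or bulk replicate) carries its
# own composition column; used for free reference compositions and as an
# internal cross-check of the fast path. Designed for small problems.
fit_engine_general <- function(Y0, lab, k, Y1, profiles, opts, verbose,
                               update_ref_composition = FALSE) {
  m <- nrow(Y0); J <- ncol(Y0); R <- ncol(Y1)
  t_min <- opts$t_bounds[1L]; t_max <- opts$t_bounds[2L]
  fixed_prof <- !is.null(profiles)
  Y <- cbind(Y0, Y1)
  n <- J + R
  is_bulk <- c(rep(FALSE, J), rep(TRUE, R))

  W <- matrix(0, k, n)
  W[cbind(lab, seq_len(J))] <- 1
  W[, J + seq_len(R)] <- 1 / k
  G <- colSums(Y)
  gauge <- exp(mean(log(G[seq_len(J)])))
  G <- G / gauge
  Ind <- matrix(0, J, k); Ind[cbind(seq_len(J), lab)] <- 1
  X <- if (fixed_prof) profiles$X
       else m_step_expression(Y0 %*% Ind, as.numeric(crossprod(Ind, G[seq_len(J)])))
  Tm <- if (fixed_prof) profiles$T else matrix(1, m, k)

  loglik_at <- function(alloc, lam) {
    tot <- 0
    for (j in seq_len(n)) {
      a <- alloc[, , j]; lm <- lam[, , j]
      term <- -Tm * lm - lgamma(Tm * a + 1)
      p <- a > 0 & lm > 0
      term[p] <- term[p] + (Tm * a * log(Tm * lm))[p]
      term[a > 0 & lm == 0] <- 0
      tot <- tot + sum(term)
    }
    tot
  }

  trace <- numeric(0); converged <- FALSE; stalled <- FALSE
  n_fallback <- 0L; snap <- NULL; alloc <- NULL

  # E-step plus per-unit composition/scale updates to stationarity under the
  # current profiles (see the fixed engine for rationale); reference columns
  # with pinned one-hot compositions allocate to their own type and only
  # their scale is free
  equilibrate_w <- function(X, Tm, W, G, inner_max = 200L, w_tol = 1e-12) {
    for (ii in seq_len(inner_max)) {
      ab <- allocate_block(Y, X, W)
      W_old <- W
      for (j in seq_len(n)) {
        cs <- m_step_composition(ab$alloc[, , j], X, Tm)
        if (cs$degenerate) next
        if (is_bulk[j] || update_ref_composition) {
          W[, j] <- cs$w
          G[j] <- cs$scale
        } else {
          G[j] <- cs$scale
        }
      }
      if (max(abs(W - W_old)) < w_tol) break
    }
    ab <- allocate_block(Y, X, W)
    list(W = W, G = G, alloc = ab$alloc, fallback = ab$fallback)
  }

  for (it in seq_len(opts$max_iter)) {
    eq <- equilibrate_w(X, Tm, W, G)
    W <- eq$W; G <- eq$G; alloc <- eq$alloc
    n_fallback <- sum(eq$fallback)

    if (!fixed_prof) {
      zsum <- apply(alloc, c(1L, 2L), sum)
      wg <- as.numeric(W %*% G)
      X <- m_step_expression(zsum, wg)
    }

    lam <- array(0, dim = c(m, k, n))
    for (j in seq_len(n))
      lam[, , j] <- X * rep(W[, j] * G[j], each = m)

    if (!fixed_prof) {
      lam_sum <- apply(lam, c(1L, 2L), sum)
      resid <- apply((alloc - lam)^2, c(1L, 2L), sum)
      Tc <- m_step_precision(lam_sum, pmax(resid, 0), Tm, t_min, t_max)
      contrib_mat <- function(Tx) {
        C <- matrix(0, m, k)
        for (j in seq_len(n)) {
          a <- alloc[, , j]; lm <- lam[, , j]
          term <- -Tx * lm - lgamma(Tx * a + 1)
          p <- a > 0 & lm > 0
          term[p] <- term[p] + (Tx * a * log(Tx * lm))[p]
          term[a > 0 & lm == 0] <- 0
          C <- C + term
        }
        C
      }
      take <- contrib_mat(Tc) >= contrib_mat(Tm)   # accept-if-improves guard
      Tm[take] <- Tc[take]
    }

    for (j in seq_len(n)) {
      cs <- m_step_composition(alloc[, , j], X, Tm)
      if (cs$degenerate) next
      if (is_bulk[j] || update_ref_composition) {
        W[, j] <- cs$w
        G[j] <- cs$scale
      } else {
        G[j] <- cs$scale  # composition pinned, scale free
      }
    }
    if (!fixed_prof) {
      gauge <- exp(mean(log(G[seq_len(J)])))
      G <- G / gauge
      X <- X * gauge
    }

    for (j in seq_len(n))
      lam[, , j] <- X * rep(W[, j] * G[j], each = m)
    ll <- loglik_at(alloc, lam)
    if (verbose) message(sprintf("iter %d: loglik %.6f", it, ll))

    if (it > 1L) {
      prev <- trace[length(trace)]
      if (ll < prev) {
        X <- snap$X; Tm <- snap$Tm; W <- snap$W; G <- snap$G
        alloc <- snap$alloc; n_fallback <- snap$n_fallback
        converged <- TRUE; stalled <- TRUE
        break
      }
      trace <- c(trace, ll)
      if (ll - prev <= opts$tol * abs(prev)) { converged <- TRUE; break }
    } else trace <- c(trace, ll)
    snap <- list(X = X, Tm = Tm, W = W, G = G, alloc = alloc,
                 n_fallback = n_fallback)
  }
  if (!converged)
    warning("decomposition did not converge within max_iter", call. = FALSE)

  list(X = X, T = Tm, W1 = W[, J + seq_len(R), drop = FALSE],
       G1 = G[J + seq_len(R)], G0 = G[seq_len(J)],
       W0 = W[, seq_len(J), drop = FALSE],
       alloc = alloc[, , J + seq_len(R), drop = FALSE],
       trace = trace, converged = converged, stalled = stalled,
       n_iter = length(trace), n_fallback = n_fallback)
}

#' Decompose a cohort of bulk samples
#'
#' Runs [poisdecon()] independently on each bulk sample (optionally grouping
#' columns into replicate sets sharing one fit). Fits are independent, so
#' results do not depend on execution order; a failure in one sample is
#' recorded and does not abort the rest.
#'
#' @inheritParams poisdecon
#' @param bulk a [count_matrix()] (or matrix) of all bulk columns.
#' @param replicate_map character/factor of length `ncol(bulk)` assigning each
#'   column to a sample; columns sharing a value are fitted jointly as
#'   replicates. Default: every column is its own sample.
#' @param ... further arguments passed to [poisdecon()].
#' @return An object of class `poisdecon_cohort`: list with `fits` (named list
#'   of `poisdecon` objects) and `failures` (named character of error
#'   messages, empty when all samples succeeded).
#' @export
poisdecon_cohort <- function(bulk, reference, labels = NULL,
                             replicate_map = NULL, ...) {
  bulk <- as_count_values(bulk, kind = "bulk")
  if (is.null(replicate_map))
    replicate_map <- bulk$unit_ids
  replicate_map <- as.character(replicate_map)
  if (length(replicate_map) != length(bulk$unit_ids))
    stop_validation("replicate_map must assign every bulk column")
  samples <- unique(replicate_map)
  fits <- stats::setNames(vector("list", length(samples)), samples)
  failures <- character(0)
  for (s in samples) {
    cols <- which(replicate_map == s)
    sub <- count_matrix(bulk$values[, cols, drop = FALSE],
                        gene_ids = bulk$gene_ids,
                        unit_ids = bulk$unit_ids[cols], kind = "bulk")
    res <- tryCatch(poisdecon(sub, reference, labels, ...),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[s] <- conditionMessage(res)
      warning(sprintf("sample %s failed: %s", s, conditionMessage(res)),
              call. = FALSE)
    } else {
      fits[[s]] <- res
    }
  }
  structure(list(fits = fits, failures = failures, samples = samples),
            class = "poisdecon_cohort")
}

#' @export
print.poisdecon_cohort <- function(x, ...) {
  ok <- sum(!vapply(x$fits, is.null, logical(1L)))
  cat(sprintf("<poisdecon_cohort: %d sample(s), %d fitted, %d failed>\n",
              length(x$samples), ok, length(x$failures)))
  if (length(x$failures))
    cat("failures:", paste(names(x$failures), collapse = ", "), "\n")
  invisible(x)
}

#' Extract cohort compositions
#'
#' @param object a `poisdecon_cohort`.
#' @param ... unused.
#' @return cell types x replicates matrix of fitted compositions pooled over
#'   all successfully fitted samples.
#' @export
coef.poisdecon_cohort <- function(object, ...) {
  mats <- lapply(Filter(Negate(is.null), object$fits), coef)
  do.call(cbind, mats)
}
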