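# Generative direction of the scaled-Poisson model: latent type-specific
# counts with mean lambda and variance lambda / t, summed to the observation.
# All randomness is funnelled through with_local_seed() so simulations are
# reproducible from a single integer seed and never clobber the caller's RNG.

with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

#' Draw scaled-Poisson counts
#'
#' Samples counts with mean `lambda` and variance `lambda / t`. At `t = 1`
#' this is Poisson; overdispersed draws (`t < 1`) use a gamma-Poisson mixture
#' with gamma shape `lambda * t / (1 - t)` and mean `lambda`, which matches
#' the first two scaled-Poisson moments exactly; underdispersed draws
#' (`t > 1`) use `round(Poisson(t * lambda) / t)`, moment-matched up to the
#' rounding.
#'
#' @param n number of draws.
#' @param lambda mean(s), recycled.
#' @param t precision(s), recycled.
#' @return numeric vector of n non-negative counts.
#' @export
rscaled_pois <- function(n, lambda, t = 1) {
  lambda <- rep_len(lambda, n)
  t <- rep_len(t, n)
  out <- numeric(n)
  pos <- lambda > 0
  if (!any(pos)) return(out)
  eq <- pos & t == 1
  lo <- pos & t < 1
  hi <- pos & t > 1
  if (any(eq)) out[eq] <- stats::rpois(sum(eq), lambda[eq])
  if (any(lo)) out[lo] <- stats::rnbinom(sum(lo),
                                         size = lambda[lo] * t[lo] / (1 - t[lo]),
                                         mu = lambda[lo])
  if (any(hi)) out[hi] <- round(stats::rpois(sum(hi), t[hi] * lambda[hi]) / t[hi])
  out
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

build_profile <- function(m, k, profile_spec) {
  spec <- utils::modifyList(list(kind = "lognormal", gene_sdlog = 1.2,
                                 type_sdlog = 1, markers_per_type = 0L,
                                 marker_mean = 20, background_mean = 0.1),
                            profile_spec %||% list())
  if (identical(spec$kind, "markers")) {
    mk <- spec$markers_per_type
    if (k * mk > m)
      stop_validation("marker blocks exceed gene count")
    X <- matrix(spec$background_mean, m, k)
    for (l in seq_len(k))
      X[((l - 1L) * mk + 1L):(l * mk), l] <- spec$marker_mean
    return(X)
  }
  base <- stats::rlnorm(m, meanlog = 0, sdlog = spec$gene_sdlog)
  fold <- matrix(stats::rlnorm(m * k, meanlog = 0, sdlog = spec$type_sdlog), m, k)
  base * fold
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a labelled single-cell reference
#'
#' Draws a cell-type expression profile matrix `X` (log-normal gene effects
#' with log-normal per-type folds, or disjoint marker blocks), per-cell scale
#' factors `G` log-normal around the target depth, and counts with mean
#' `X[i, type(j)] * G[j]` and variance `mean / t` via [rscaled_pois()].
#'
#' @param m number of genes.
#' @param k number of cell types.
#' @param cells_per_type reference cells per type.
#' @param depth_mean expected per-cell total count; profile columns are
#'   normalized so cells average this depth. `NULL` keeps the profile in
#'   absolute per-cell count units (used with marker specs).
#' @param depth_sdlog log-sd of the per-cell depth variation.
#' @param dispersion_t scaled-Poisson precision of the readout.
#' @param profile_spec list controlling `X`: either
#'   `list(kind = "lognormal", gene_sdlog =, type_sdlog =)` or
#'   `list(kind = "markers", markers_per_type =, marker_mean =, background_mean =)`.
#' @param type_names optional cell-type names (default `cancer`, `fibroblast`,
#'   `immune`, then `type4`, ...).
#' @param seed integer seed; identical seeds give identical outputs.
#' @return list with `counts` (a single-cell [count_matrix()]), `labels`
#'   (a [cell_labels()]), and `truth` (list with `params` = list(X, T, W, G)
#'   and the generator `design`).
#' @export
simulate_reference <- function(m = 500L, k = 3L, cells_per_type = 100L,
                               depth_mean = 2000, depth_sdlog = 0.3,
                               dispersion_t = 1, profile_spec = NULL,
                               type_names = NULL, seed = 1L) {
  stopifnot(m >= 1, k >= 1, cells_per_type >= 1)
  if (dispersion_t < .t_min_default || dispersion_t > .t_max_default)
    stop_domain("dispersion_t outside admissible precision range")
  with_local_seed(seed, {
    if (is.null(type_names)) {
      type_names <- c("cancer", "fibroblast", "immune",
                      sprintf("type%d", seq_len(max(0L, k - 3L)) + 3L))[seq_len(k)]
    }
    X <- build_profile(m, k, profile_spec)
    if (!is.null(depth_mean))
      X <- sweep(X, 2L, colSums(X), "/") * depth_mean
    J <- k * cells_per_type
    lab <- rep(seq_len(k), each = cells_per_type)
    G <- stats::rlnorm(J, meanlog = -depth_sdlog^2 / 2, sdlog = depth_sdlog)
    lam <- X[, lab, drop = FALSE] * rep(G, each = m)
    counts <- matrix(rscaled_pois(m * J, as.numeric(lam), dispersion_t), m, J)
    gene_ids <- sprintf("gene_%04d", seq_len(m))
    cell_ids <- sprintf("cell_%04d", seq_len(J))
    dimnames(counts) <- list(gene_ids, cell_ids)
    W <- matrix(0, k, J, dimnames = list(type_names, cell_ids))
    W[cbind(lab, seq_len(J))] <- 1
    list(counts = count_matrix(counts, kind = "single_cell"),
         labels = cell_labels(cell_ids, type_names[lab]),
         truth = list(params = list(X = `dimnames<-`(X, list(gene_ids, type_names)),
                                    T = matrix(dispersion_t, m, k,
                                               dimnames = list(gene_ids, type_names)),
                                    W = W, G = stats::setNames(G, cell_ids)),
                      design = list(m = m, k = k, cells_per_type = cells_per_type,
                                    depth_mean = depth_mean,
                                    depth_sdlog = depth_sdlog,
                                    dispersion_t = dispersion_t,
                                    profile_spec = profile_spec, seed = seed)))
  })
}

#' Simulate bulk mixtures from known profiles
#'
#' Optionally perturbs a stated fraction of genes of selected cell-type
#' profiles per sample (log-normal fold noise) before mixing — this is the
#' ground truth the profile-adaptation analyses compare against — then draws
#' latent per-type counts with [rscaled_pois()] and sums them per gene, so
#' conservation between latent and observed counts is exact by construction.
#'
#' @param profiles genes x types matrix of mean expression (e.g.
#'   `truth$params$X` from [simulate_reference()]).
#' @param compositions types x samples matrix of simplex columns.
#' @param depth expected total count per bulk sample.
#' @param dispersion_t scaled-Poisson precision.
#' @param perturbation `NULL`, or `list(fraction =, sdlog =, types =)` naming
#'   the perturbed gene fraction, the log-normal fold sd, and which type
#'   columns to perturb (names or indices; default the first type).
#' @param seed integer seed.
#' @return list with `counts` (bulk [count_matrix()]) and `truth` (list with
#'   per-sample perturbed profiles `X_by_sample`, `W`, `G`, latent
#'   allocations `latent` (genes x types x samples), `perturbed_genes`, and
#'   the generator `design`).
#' @export
simulate_bulk <- function(profiles, compositions, depth = 1e6,
                          dispersion_t = 1, perturbation = NULL, seed = 1L) {
  X <- as.matrix(profiles)
  W <- as.matrix(compositions)
  m <- nrow(X); k <- ncol(X); n <- ncol(W)
  if (nrow(W) != k)
    stop_validation("compositions have %d rows but profiles %d types", nrow(W), k)
  if (any(W < 0) || any(abs(colSums(W) - 1) > 1e-9))
    stop_validation("composition columns must lie on the simplex")
  gene_ids <- rownames(X) %||% sprintf("gene_%04d", seq_len(m))
  type_names <- colnames(X) %||% sprintf("type%d", seq_len(k))
  sample_ids <- colnames(W) %||% sprintf("bulk_%02d", seq_len(n))
  with_local_seed(seed, {
    latent <- array(0, dim = c(m, k, n),
                    dimnames = list(gene_ids, type_names, sample_ids))
    X_by_sample <- vector("list", n)
    pert_genes <- vector("list", n)
    G <- numeric(n)
    for (s in seq_len(n)) {
      Xs <- X
      pg <- integer(0)
      if (!is.null(perturbation)) {
        pg <- sort(sample.int(m, size = round(perturbation$fraction * m)))
        ty <- perturbation$types %||% 1L
        if (is.character(ty)) ty <- match(ty, type_names)
        fold <- stats::rlnorm(length(pg), 0, perturbation$sdlog)
        Xs[pg, ty] <- Xs[pg, ty] * fold
      }
      mix <- as.numeric(Xs %*% W[, s])
      G[s] <- depth / sum(mix)
      lam <- Xs * rep(W[, s] * G[s], each = m)
      latent[, , s] <- matrix(rscaled_pois(m * k, as.numeric(lam), dispersion_t),
                              m, k)
      X_by_sample[[s]] <- Xs
      pert_genes[[s]] <- pg
    }
    y <- apply(latent, c(1L, 3L), sum)
    dimnames(y) <- list(gene_ids, sample_ids)
    list(counts = count_matrix(y, kind = "bulk"),
         truth = list(X_by_sample = stats::setNames(X_by_sample, sample_ids),
                      W = `dimnames<-`(W, list(type_names, sample_ids)),
                      G = stats::setNames(G, sample_ids),
                      latent = latent,
                      perturbed_genes = stats::setNames(pert_genes, sample_ids),
                      design = list(depth = depth, dispersion_t = dispersion_t,
                                    perturbation = perturbation, seed = seed)))
  })
}

#' Simulate a named benchmark scenario
#'
#' Bundles [simulate_reference()] and [simulate_bulk()] into the preset
#' families the test-suite and examples use:
#'
#' * `baseline` — 500 genes, 3 types, 100 cells/type at depth 2000, one bulk
#'   sample of depth 1e6 with a Dirichlet(2,2,2) composition, Poisson readout.
#' * `shifted-composition` — as baseline but 6 bulk samples in two groups
#'   whose mean cancer fractions are about 0.7 and 0.4.
#' * `perturbed-profiles` — baseline plus log-normal fold noise (sd 0.5) on
#'   10% of the cancer profile genes per bulk sample.
#' * `pure-samples` — one bulk sample per type with one-hot composition.
#' * `two-type-markers` — 2 types, 50 cells each, disjoint 50-gene marker
#'   blocks (mean 20) over a background of mean 0.1; for clustering tests.
#' * `one-type` — a single phenotype, for model-order null tests.
#'
#' @param scenario preset name (see above).
#' @param seed integer seed.
#' @param m,cells_per_type,bulk_depth optional size overrides (defaults are
#'   per scenario).
#' @return list with `reference` (counts, labels, truth), `bulk` (counts,
#'   truth), `scenario`, `seed`.
#' @export
simulate_cohort <- function(scenario = c("baseline", "shifted-composition",
                                         "perturbed-profiles", "pure-samples",
                                         "two-type-markers", "one-type"),
                            seed = 1L, m = NULL, cells_per_type = NULL,
                            bulk_depth = NULL) {
  if (!is.character(scenario) || !scenario[1L] %in%
      c("baseline", "shifted-composition", "perturbed-profiles",
        "pure-samples", "two-type-markers", "one-type"))
    stop_validation("unknown scenario '%s'; presets: baseline, shifted-composition, perturbed-profiles, pure-samples, two-type-markers, one-type",
                    as.character(scenario[1L]))
  scenario <- scenario[1L]
  seed <- as.integer(seed)
  markers <- scenario %in% c("two-type-markers", "one-type")
  k <- switch(scenario, "two-type-markers" = 2L, "one-type" = 1L, 3L)
  m <- m %||% if (markers) 200L else 500L
  cells_per_type <- cells_per_type %||% if (markers) 50L else 100L
  bulk_depth <- bulk_depth %||% 1e6

  ref <- simulate_reference(
    m = m, k = k, cells_per_type = cells_per_type,
    depth_mean = if (markers) NULL else 2000,
    profile_spec = if (markers)
      list(kind = "markers", markers_per_type = min(50L, m %/% max(k, 2L)),
           marker_mean = 20, background_mean = 0.1)
    else list(kind = "lognormal"),
    seed = seed)

  W <- with_local_seed(seed + 10000L, switch(scenario,
    "baseline" = matrix(rdirichlet1(rep(2, k))),
    # tumor-like composition: the profile-adaptation scenario emulates a
    # cancer-bearing sample with the cancer fraction typical of solid tumors
    "perturbed-profiles" = matrix(rdirichlet1(12 * c(0.55, 0.25, 0.20))),
    "shifted-composition" = {
      pri <- replicate(3L, rdirichlet1(15 * c(0.7, 0.2, 0.1)))
      int <- replicate(3L, rdirichlet1(15 * c(0.4, 0.35, 0.25)))
      cbind(pri, int)
    },
    "pure-samples" = diag(k),
    "two-type-markers" = matrix(c(0.5, 0.5)),
    "one-type" = matrix(1)))
  rownames(W) <- ref$labels$type_names
  colnames(W) <- if (scenario == "shifted-composition")
    sprintf("%s_%d", rep(c("primary", "interval"), each = 3L), rep(1:3, 2L))
  else sprintf("bulk_%02d", seq_len(ncol(W)))

  bulk <- simulate_bulk(
    profiles = ref$truth$params$X, compositions = W, depth = bulk_depth,
    perturbation = if (scenario == "perturbed-profiles")
      list(fraction = 0.1, sdlog = 0.5, types = "cancer") else NULL,
    seed = seed + 20000L)

  list(reference = ref, bulk = bulk, scenario = scenario, seed = seed)
}
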