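#' Bayesian information criterion under the package likelihood convention
#'
#' `-2 * loglik + n_params * log(n_obs)`. Used with the unnormalized
#' scaled-Poisson quasi-log-likelihood; comparisons are valid because every
#' candidate model is scored under the same convention.
#'
#' @param loglik model quasi-log-likelihood.
#' @param n_params number of free parameters.
#' @param n_obs number of observed entries (must be >= 1).
#' @return the BIC value (smaller is better).
#' @export
bic_score <- function(loglik, n_params, n_obs) {
  if (any(n_obs < 1))
    stop_domain("n_obs must be >= 1")
  -2 * loglik + n_params * log(n_obs)
}

# Cluster sufficient statistics are additive over members, so merges combine
# by summation; only the lgamma term of the quasi-log-likelihood needs the
# member columns because the refitted precision enters it nonlinearly.
cluster_stats <- function(Y, G, members) {
  g <- G[members]
  list(members = members,
       sz = rowSums(Y[, members, drop = FALSE]),
       sz2 = rowSums(Y[, members, drop = FALSE]^2),
       szG = as.numeric(Y[, members, drop = FALSE] %*% g),
       szlogG = as.numeric(Y[, members, drop = FALSE] %*% log(g)),
       sG = sum(g), sG2 = sum(g * g))
}

merge_stats <- function(a, b) {
  list(members = c(a$members, b$members),
       sz = a$sz + b$sz, sz2 = a$sz2 + b$sz2, szG = a$szG + b$szG,
       szlogG = a$szlogG + b$szlogG, sG = a$sG + b$sG, sG2 = a$sG2 + b$sG2)
}

# Refit one cluster's (x, t) profile by the closed forms and return its
# quasi-log-likelihood contribution. The contribution includes the lattice
# Jacobian term +log(t) per observed entry (the density of the scaled
# readout on a fixed measure): without it the free dispersion can flatten any
# misfit almost for free, making cluster configurations non-comparable and
# BIC degenerate; with it the moment-matched precision is (asymptotically)
# the per-gene maximizer, so refitting t on a merge is an honest refit.
cluster_ll <- function(st, Y, G, t_min, t_max) {
  x <- st$sz / st$sG
  lam_sum <- x * st$sG
  resid <- pmax(st$sz2 - 2 * x * st$szG + x * x * st$sG2, 0)
  tt <- lam_sum / resid
  tt[lam_sum > 0 & resid == 0] <- t_max
  tt[lam_sum == 0] <- 1
  tt <- pmin(pmax(tt, t_min), t_max)
  pos <- st$sz > 0
  ll_main <- -tt * lam_sum
  ll_main[pos] <- ll_main[pos] +
    (tt * (st$sz * log(tt * x) + st$szlogG))[pos]
  ll_main[pos] <- ll_main[pos] + (length(st$members) * log(tt))[pos]
  lg <- sum(lgamma(tt * Y[, st$members, drop = FALSE] + 1))
  sum(ll_main) - lg
}

#' Model-based agglomerative clustering of single-cell profiles
#'
#' Discovers constituent phenotypes in a single-cell count matrix by building
#' a binary-membership composition agglomeratively under the scaled-Poisson
#' model: every unit starts as its own component; at each step the pair whose
#' merge loses the least quasi-log-likelihood is merged, refitting the merged
#' component's mean and precision profile by the closed-form updates. The
#' number of components is selected by BIC over the merge path. Agglomeration
#' is deterministic given the input (ties broken lexicographically by node
#' id), which makes it stable against the multiple local optima an iterative
#' mixture fit would face.
#'
#' Per-unit scale factors are taken from `scales` or default to library-size
#' normalization. For inputs larger than `micro_threshold` units,
#' exact duplicates are collapsed and remaining units are pre-seeded into
#' micro-clusters by k-means on log-scale normalized profiles (a documented
#' approximation; below the threshold the exact pairwise rule is used
#' throughout).
#'
#' @param sc a [count_matrix()] (or matrix) of single-cell counts.
#' @param scales optional positive per-unit scale factors (e.g. from
#'   [estimate_scale_factors()] for a pure panel); default is library-size
#'   normalization (total counts, geometric mean 1).
#' @param t_bounds admissible precision range.
#' @param micro_threshold unit count above which pre-seeding kicks in.
#' @return An object of class `cluster_tree`: `merges` (data frame with
#'   columns `node_a`, `node_b`, `merged_node`, `loglik_after_merge`),
#'   `leaves` (list of unit-id vectors per initial node), `loglik_by_k`,
#'   `bic_by_k`, `chosen_k` (argmin BIC), and `labels`, a [cell_labels()] at
#'   the chosen cut (types named `C1`, `C2`, ... by first unit appearance).
#' @examples
#' sim <- simulate_cohort("two-type-markers", seed = 1, cells_per_type = 12)
#' tr <- cluster_profiles(sim$reference$counts)
#' tr$chosen_k
#' @export
cluster_profiles <- function(sc, scales = NULL,
                             t_bounds = c(.t_min_default, .t_max_default),
                             micro_threshold = 2000L) {
  cm <- as_count_values(sc, kind = "single_cell")
  Y <- cm$values
  m <- nrow(Y); n_units <- ncol(Y)
  t_min <- t_bounds[1L]; t_max <- t_bounds[2L]

  usable <- colSums(Y) > 0
  if (!all(usable)) {
    warning(sprintf("dropping %d all-zero unit(s) before clustering",
                    sum(!usable)), call. = FALSE)
    Y <- Y[, usable, drop = FALSE]
  }
  unit_ids <- colnames(Y)
  n <- ncol(Y)
  if (n == 0L)
    stop_validation("no usable units")

  if (is.null(scales)) {
    # library-size normalization: the trimmed common-profile estimator
    # presumes one shared profile across units, which is the very structure
    # clustering is meant to discover, so a profile-free default is used here;
    # callers can supply estimate_scale_factors() output for pure panels
    tot <- colSums(Y)
    scales <- tot / exp(mean(log(tot)))
  } else {
    scales <- scales[usable]
  }
  G <- as.numeric(scales)

  # initial nodes: one per unit, or micro-cluster seeds above the threshold
  seeds <- as.list(seq_len(n))
  if (n > micro_threshold) {
    key <- apply(Y, 2L, paste, collapse = ",")
    dup_groups <- split(seq_len(n), key)
    seeds <- unname(dup_groups)
    if (length(seeds) > micro_threshold) {
      reps <- vapply(seeds, `[[`, integer(1L), 1L)
      prof <- t(log1p(sweep(Y[, reps, drop = FALSE], 2L, G[reps], "/")))
      km <- with_local_seed(1L,
        stats::kmeans(prof, centers = micro_threshold, iter.max = 50L,
                      nstart = 1L))
      seeds <- unname(lapply(split(seq_along(reps), km$cluster),
                             function(ix) unlist(seeds[ix], use.names = FALSE)))
    }
    # deterministic seed order: by smallest member index
    seeds <- seeds[order(vapply(seeds, min, integer(1L)))]
  }
  n_leaves <- length(seeds)

  clusters <- lapply(seeds, function(mem) cluster_stats(Y, G, mem))
  lls <- vapply(clusters, cluster_ll, numeric(1L), Y, G, t_min, t_max)
  node_id <- seq_len(n_leaves)
  active <- rep(TRUE, n_leaves)
  total_ll <- sum(lls)

  n_params_at <- function(k) 2 * k * m + n
  n_obs <- n * m
  ks <- n_leaves
  ll_by_k <- stats::setNames(total_ll, n_leaves)
  bic_by_k <- stats::setNames(bic_score(total_ll, n_params_at(n_leaves), n_obs),
                              n_leaves)

  merges <- data.frame(node_a = integer(0), node_b = integer(0),
                       merged_node = integer(0),
                       loglik_after_merge = numeric(0))
  if (n_leaves > 1L) {
    slots <- seq_len(n_leaves)
    # pairwise merge gains (<= 0): gain[a,b] = ll(merged) - ll(a) - ll(b)
    gain <- matrix(NA_real_, n_leaves, n_leaves)
    pair_gain <- function(a, b)
      cluster_ll(merge_stats(clusters[[a]], clusters[[b]]), Y, G, t_min, t_max) -
        lls[a] - lls[b]
    for (a in seq_len(n_leaves - 1L))
      for (b in seq((a + 1L), n_leaves))
        gain[a, b] <- pair_gain(a, b)

    next_id <- n_leaves
    for (step in seq_len(n_leaves - 1L)) {
      act <- which(active)
      cand <- which(!is.na(gain), arr.ind = TRUE)
      g <- gain[cand]
      ida <- node_id[cand[, 1L]]; idb <- node_id[cand[, 2L]]
      lo <- pmin(ida, idb); hi <- pmax(ida, idb)
      pick <- order(-g, lo, hi)[1L]
      a <- cand[pick, 1L]; b <- cand[pick, 2L]
      merged <- merge_stats(clusters[[a]], clusters[[b]])
      new_ll <- cluster_ll(merged, Y, G, t_min, t_max)
      total_ll <- total_ll + (new_ll - lls[a] - lls[b])
      next_id <- next_id + 1L
      merges <- rbind(merges, data.frame(
        node_a = min(node_id[a], node_id[b]),
        node_b = max(node_id[a], node_id[b]),
        merged_node = next_id, loglik_after_merge = total_ll))
      clusters[[a]] <- merged
      lls[a] <- new_ll
      node_id[a] <- next_id
      active[b] <- FALSE
      gain[b, ] <- NA_real_; gain[, b] <- NA_real_
      for (o in which(active)) {
        if (o == a) next
        i <- min(o, a); j <- max(o, a)
        gain[i, j] <- pair_gain(i, j)
      }
      k_now <- n_leaves - step
      ll_by_k[as.character(k_now)] <- total_ll
      bic_by_k[as.character(k_now)] <- bic_score(total_ll, n_params_at(k_now),
                                                 n_obs)
    }
  }

  ks_all <- as.integer(names(bic_by_k))
  chosen_k <- ks_all[which.min(bic_by_k)]

  labels <- labels_at_cut(seeds, merges, n_leaves, chosen_k, unit_ids)

  structure(list(merges = merges,
                 leaves = lapply(seeds, function(mem) unit_ids[mem]),
                 loglik_by_k = ll_by_k, bic_by_k = bic_by_k,
                 chosen_k = chosen_k, labels = labels,
                 unit_ids = unit_ids, n_units = n),
            class = "cluster_tree")
}

# replay the merge history down to k clusters and emit labels in
# first-appearance order
labels_at_cut <- function(seeds, merges, n_leaves, k, unit_ids) {
  parent <- seq_len(n_leaves + nrow(merges))
  n_steps <- n_leaves - k
  for (s in seq_len(n_steps)) {
    parent[merges$node_a[s]] <- merges$merged_node[s]
    parent[merges$node_b[s]] <- merges$merged_node[s]
  }
  root_of <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  leaf_root <- vapply(seq_len(n_leaves), root_of, integer(1L))
  unit_root <- integer(length(unit_ids))
  for (s in seq_len(n_leaves))
    unit_root[seeds[[s]]] <- leaf_root[s]
  cluster_names <- stats::setNames(sprintf("C%d", seq_len(k)),
                                   unique(unit_root))
  cell_labels(unit_ids, unname(cluster_names[as.character(unit_root)]))
}

#' Cut a cluster tree at a given number of clusters
#'
#' @param tree a `cluster_tree`.
#' @param k desired number of clusters along the merge path.
#' @return a [cell_labels()].
#' @export
cluster_labels <- function(tree, k = tree$chosen_k) {
  stopifnot(inherits(tree, "cluster_tree"))
  if (!as.character(k) %in% names(tree$bic_by_k))
    stop_validation("k = %d is not on the merge path", k)
  seeds <- lapply(tree$leaves, function(ids) match(ids, tree$unit_ids))
  labels_at_cut(seeds, tree$merges, length(tree$leaves), k, tree$unit_ids)
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree: %d unit(s), %d initial node(s), chosen k = %d (BIC %.2f)>\n",
              x$n_units, length(x$leaves), x$chosen_k,
              x$bic_by_k[as.character(x$chosen_k)]))
  invisible(x)
}

#' Plot the BIC model-selection curve of a cluster tree
#'
#' @param x a `cluster_tree`.
#' @param max_k largest number of clusters to display.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cluster_tree <- function(x, max_k = min(15L, length(x$bic_by_k)), ...) {
  ks <- sort(as.integer(names(x$bic_by_k)))
  ks <- ks[ks <= max_k]
  graphics::plot(ks, x$bic_by_k[as.character(ks)], type = "b",
                 xlab = "number of components k", ylab = "BIC", ...)
  graphics::abline(v = x$chosen_k, lty = 2)
  invisible(x)
}
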