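test_that("a single cell type receives the whole composition and all counts", {
  ref <- simulate_reference(m = 50, k = 1, cells_per_type = 10, depth_mean = 400,
                            seed = 4)
  W <- matrix(1, dimnames = list(ref$labels$type_names, "b1"))
  bulk <- simulate_bulk(ref$truth$params$X, W, depth = 1e4, seed = 9)
  fit <- poisdecon(bulk$counts, ref$counts, ref$labels, tol = 1e-6)
  expect_equal(unname(coef(fit)[, 1]), 1)
  expect_equal(fit$allocations[, 1, 1], bulk$counts$values[, 1],
               ignore_attr = TRUE)
})

test_that("allocations conserve the bulk counts gene by gene", {
  mx <- small_mixture(seed = 8)
  fit <- poisdecon(mx$bulk$counts, mx$ref$counts, mx$ref$labels, tol = 1e-6)
  y <- mx$bulk$counts$values
  recon <- apply(fit$allocations, c(1, 3), sum)
  expect_lt(max(abs(recon - y) / pmax(1, y)), 1e-6)
  # a gene whose profile is concentrated on one type allocates there entirely
  X <- fit$X
  conc <- which(X[, 1] > 0 & X[, 2] == 0)
  if (length(conc) > 0)
    expect_true(all(fit$allocations[conc, 2, 1] == 0))
})

test_that("fitted composition matches a brute-force grid search with frozen profiles", {
  set.seed(42)
  m <- 3; k <- 2
  X <- matrix(c(50, 10, 5, 5, 30, 20), m, k)
  Tt <- matrix(1, m, k)
  y <- rpois(m, as.numeric(X %*% c(0.7, 0.3)) * 20)
  ref <- matrix(rpois(m * 4, 20), m, 4,
                dimnames = list(sprintf("g%d", 1:m), sprintf("c%d", 1:4)))
  labs <- cell_labels(sprintf("c%d", 1:4), c("A", "A", "B", "B"))
  bulk <- matrix(y, dimnames = list(sprintf("g%d", 1:m), "b1"))
  fit <- poisdecon(bulk, count_matrix(ref, kind = "single_cell"), labs,
                   profiles = list(X = X, T = Tt))
  obj_w <- function(w1) {
    w <- c(w1, 1 - w1)
    Gj <- sum(y) / sum(X %*% w)
    for (i in 1:200) {
      al <- t(sapply(1:m, function(i) expected_allocation(y[i], X[i, ], w)))
      Gn <- sum(Tt * al) / sum(Tt * sweep(X, 2, w, "*"))
      if (abs(Gn - Gj) < 1e-12 * Gj) { Gj <- Gn; break }
      Gj <- Gn
    }
    al <- t(sapply(1:m, function(i) expected_allocation(y[i], X[i, ], w)))
    sum(scaled_poisson_loglik(as.numeric(al),
                              pmax(as.numeric(sweep(X, 2, w * Gj, "*")), 1e-300),
                              as.numeric(Tt)))
  }
  grid <- seq(0, 1, by = 0.001)
  w_grid <- grid[which.max(vapply(grid, obj_w, numeric(1)))]
  expect_lt(abs(coef(fit)["A", 1] - w_grid), 0.01)
})

test_that("proportional allocation equals the exact conditional mean for Poisson", {
  # lattice enumeration oracle: Z1 + Z2 = y with independent Poisson components
  for (y in 0:6) for (l1 in c(0.3, 1, 2.5)) for (l2 in c(0.5, 1.7)) {
    zs <- 0:y
    wts <- dpois(zs, l1) * dpois(y - zs, l2)
    exact <- if (y == 0) 0 else sum(zs * wts) / sum(wts)
    approx <- expected_allocation(y, c(l1, l2), c(0.5, 0.5))[1]
    expect_lt(abs(exact - approx), 1e-9)
  }
})

test_that("replicates share profiles but carry their own compositions", {
  ref <- simulate_reference(m = 60, k = 3, cells_per_type = 12, depth_mean = 500,
                            seed = 21)
  W <- cbind(r1 = c(0.6, 0.3, 0.1), r2 = c(0.2, 0.5, 0.3))
  rownames(W) <- ref$labels$type_names
  bulk <- simulate_bulk(ref$truth$params$X, W, depth = 3e4, seed = 22)
  fit <- poisdecon(bulk$counts, ref$counts, ref$labels, tol = 1e-6)
  expect_identical(dim(coef(fit)), c(3L, 2L))
  expect_identical(dim(fit$X), c(60L, 3L))       # one shared profile
  expect_equal(unname(colSums(coef(fit))), c(1, 1), tolerance = 1e-9)
  expect_false(identical(coef(fit)[, 1], coef(fit)[, 2]))
})

test_that("cohort fits are independent of column order and record failures", {
  ref <- simulate_reference(m = 50, k = 2, cells_per_type = 10, depth_mean = 400,
                            type_names = c("A", "B"), seed = 31)
  W <- cbind(b1 = c(0.7, 0.3), b2 = c(0.4, 0.6), b3 = c(0.1, 0.9))
  rownames(W) <- c("A", "B")
  bulk <- simulate_bulk(ref$truth$params$X, W, depth = 2e4, seed = 32)
  co <- poisdecon_cohort(bulk$counts, ref$counts, ref$labels, tol = 1e-6)
  perm <- count_matrix(bulk$counts$values[, c(3, 1, 2)],
                       gene_ids = bulk$counts$gene_ids,
                       unit_ids = bulk$counts$unit_ids[c(3, 1, 2)], kind = "bulk")
  co_p <- poisdecon_cohort(perm, ref$counts, ref$labels, tol = 1e-6)
  for (s in c("b1", "b2", "b3"))
    expect_identical(coef(co$fits[[s]]), coef(co_p$fits[[s]]))

  # an all-zero sample fails alone without aborting the cohort
  bz <- bulk$counts$values; bz[, 2] <- 0
  bulk_bad <- count_matrix(bz, bulk$counts$gene_ids, bulk$counts$unit_ids, "bulk")
  co_bad <- suppressWarnings(
    poisdecon_cohort(bulk_bad, ref$counts, ref$labels, tol = 1e-6))
  expect_named(co_bad$failures, "b2")
  expect_s3_class(co_bad$fits$b1, "poisdecon")
  expect_s3_class(co_bad$fits$b3, "poisdecon")

  # replicate_map groups columns into one joint fit
  co_rep <- poisdecon_cohort(bulk$counts, ref$counts, ref$labels,
                             replicate_map = c("s", "s", "t"), tol = 1e-6)
  expect_identical(ncol(coef(co_rep$fits$s)), 2L)
  expect_identical(ncol(coef(co_rep$fits$t)), 1L)
})

test_that("uninformative overdispersed genes barely move the composition", {
  mx <- small_mixture(seed = 12, m = 100, cells_per_type = 20, depth = 5e4)
  fit0 <- poisdecon(mx$bulk$counts, mx$ref$counts, mx$ref$labels, tol = 1e-6)
  set.seed(99)
  mn <- 40
  xn <- rlnorm(mn, log(4), 1)
  Xn <- cbind(xn, xn)  # equal across types: zero discriminating power
  lab_idx <- match(mx$ref$labels$labels, mx$ref$labels$type_names)
  lamn <- Xn[, lab_idx] * rep(mx$ref$truth$params$G, each = mn)
  Yn <- matrix(rscaled_pois(length(lamn), as.numeric(lamn), 0.1), mn)
  bn <- rscaled_pois(mn, as.numeric(Xn %*% mx$w) * mx$bulk$truth$G, 0.1)
  ids <- c(mx$ref$counts$gene_ids, sprintf("noise_%02d", seq_len(mn)))
  sc2 <- count_matrix(rbind(mx$ref$counts$values, Yn), ids,
                      mx$ref$counts$unit_ids, "single_cell")
  b2 <- count_matrix(rbind(mx$bulk$counts$values, matrix(bn)), ids,
                     mx$bulk$counts$unit_ids, "bulk")
  fit1 <- poisdecon(b2, sc2, mx$ref$labels, tol = 1e-6)
  # noise genes are downweighted via their fitted precision...
  noise <- grepl("noise", rownames(fit1$T))
  expect_lt(median(fit1$T[noise, ]), 0.6)
  expect_equal(median(fit1$T[!noise, ]), 1, tolerance = 0.2)
  # ...so the composition moves less than the recovery tolerance
  expect_lt(sum(abs(coef(fit1)[, 1] - coef(fit0)[, 1])), 0.1)
})

test_that("free reference compositions stay near their one-hot anchors", {
  mx <- small_mixture(seed = 14, m = 60, cells_per_type = 10, depth = 2e4)
  fit <- suppressWarnings(
    poisdecon(mx$bulk$counts, mx$ref$counts, mx$ref$labels,
              free_reference = TRUE, tol = 1e-6, max_iter = 80))
  expect_true(all(abs(colSums(fit$reference_composition) - 1) < 1e-9))
  expect_gt(mean(apply(fit$reference_composition, 2, max)), 0.9)
})

test_that("the two fitting engines agree when reference compositions are pinned", {
  mx <- small_mixture(seed = 16, m = 40, cells_per_type = 8, depth = 1e4)
  lab <- match(mx$ref$labels$labels, mx$ref$labels$type_names)
  opts <- list(tol = 1e-8, max_iter = 150L, t_bounds = c(1e-3, 1e3))
  fast <- suppressWarnings(poisdecon:::fit_engine_fixed(
    mx$ref$counts$values, lab, 2, mx$bulk$counts$values, NULL, opts, FALSE))
  slow <- suppressWarnings(poisdecon:::fit_engine_general(
    mx$ref$counts$values, lab, 2, mx$bulk$counts$values, NULL, opts, FALSE,
    update_ref_composition = FALSE))
  expect_equal(fast$W1, slow$W1, tolerance = 5e-3)
  expect_equal(fast$G1, slow$G1, tolerance = 5e-3)
  expect_equal(fast$X, slow$X, tolerance = 2e-2, ignore_attr = TRUE)
})

test_that("modelling-object methods expose the fit coherently", {
  mx <- small_mixture(seed = 18, m = 40, cells_per_type = 8, depth = 1e4)
  fit <- poisdecon(mx$bulk$counts, mx$ref$counts, mx$ref$labels, tol = 1e-6)
  expect_output(print(fit), "Composition")
  expect_output(print(summary(fit)), "quasi-log-likelihood")
  expect_identical(dim(fitted(fit)), dim(mx$bulk$counts$values))
  r <- residuals(fit, type = "pearson")
  expect_identical(dim(r), dim(mx$bulk$counts$values))
  expect_lt(median(abs(r)), 3)
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_equal(as.numeric(ll), fit$loglik_trace[length(fit$loglik_trace)])
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2L)
  expect_identical(dim(sims[[1]]), dim(mx$bulk$counts$values))
  # simulated totals resemble the fitted totals
  expect_equal(sum(sims[[1]]), sum(fitted(fit)), tolerance = 0.05)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
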