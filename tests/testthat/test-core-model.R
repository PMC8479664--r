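test_that("scaled-Poisson quasi-log-likelihood matches its closed form", {
  expect_equal(scaled_poisson_loglik(0, 1, 1), -1)
  expect_equal(scaled_poisson_loglik(2, 2, 1), log(2) - 2)
  # hand-evaluated: t*z*log(t*mean) - t*mean - lgamma(t*z + 1) at (1, 1, 2)
  expect_equal(scaled_poisson_loglik(1, 1, 2), 2 * log(2) - 2 - lgamma(3))
  expect_equal(scaled_poisson_loglik(1, 1, 2), log(2) - 2)
  # at t = 1 and integer z it is exactly the Poisson log-pmf
  for (z in 0:6)
    expect_equal(scaled_poisson_loglik(z, 2.5, 1), dpois(z, 2.5, log = TRUE))
  # vanishing-mean conventions
  expect_identical(scaled_poisson_loglik(0, 0, 1), 0)
  expect_identical(scaled_poisson_loglik(3, 0, 1), -Inf)
  # domain errors
  expect_error(scaled_poisson_loglik(-1, 1, 1), class = "poisdecon_domain_error")
  expect_error(scaled_poisson_loglik(1, 1, 1e9), class = "poisdecon_domain_error")
})

test_that("expected allocation partitions counts and honours invariances", {
  expect_equal(expected_allocation(8, c(1, 3), c(0.5, 0.5)), c(2, 6))
  expect_equal(expected_allocation(17, 5, 1), 17)
  expect_equal(expected_allocation(0, c(2, 3), c(0.4, 0.6)), c(0, 0))
  # zero-denominator fallback: proportional to w, conservation exact
  expect_equal(expected_allocation(6, c(0, 0), c(0.25, 0.75)), c(1.5, 4.5))

  set.seed(31)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    x <- rexp(k); w <- rsimplex(k); y <- rexp(1) * 10
    a <- expected_allocation(y, x, w)
    expect_equal(sum(a), y, tolerance = 1e-12)
    # scale invariance in x and 1-homogeneity in y
    expect_equal(expected_allocation(y, 7.3 * x, w), a, tolerance = 1e-12)
    expect_equal(expected_allocation(2 * y, x, w), 2 * a, tolerance = 1e-12)
  }
})

test_that("joint quasi-log-likelihood agrees with elementwise summation", {
  # single unit, single gene, k = 1, y = 0, lambda = 1, t = 1 -> -1
  sc <- count_matrix(matrix(0, 1, 1, dimnames = list("g", "c")), kind = "single_cell")
  bulk <- count_matrix(matrix(0, 1, 1, dimnames = list("g", "b")), kind = "bulk")
  params <- list(X = matrix(1), T = matrix(1), W0 = matrix(1), G0 = 1,
                 W1 = matrix(1), G1 = 1)
  z0 <- array(0, c(1, 1, 1))
  expect_equal(joint_loglik(sc, bulk, params, z0, z0), -2)  # both blocks at -1

  # independent summation oracle on a random 2 x 2 x 2 instance
  set.seed(5)
  m <- 2; k <- 2
  X <- matrix(rexp(m * k) + 0.5, m, k)
  Tm <- matrix(runif(m * k, 0.5, 2), m, k)
  W0 <- cbind(c(1, 0), c(0, 1)); G0 <- c(1.2, 0.8)
  W1 <- cbind(rsimplex(2), rsimplex(2)); G1 <- c(2, 3)
  sc_al <- array(rexp(m * k * 2), c(m, k, 2))
  bk_al <- array(rexp(m * k * 2), c(m, k, 2))
  sc2 <- count_matrix(apply(sc_al, c(1, 3), sum),
                      gene_ids = c("g1", "g2"), unit_ids = c("c1", "c2"),
                      kind = "single_cell")
  bk2 <- count_matrix(apply(bk_al, c(1, 3), sum),
                      gene_ids = c("g1", "g2"), unit_ids = c("b1", "b2"),
                      kind = "bulk")
  pars <- list(X = X, T = Tm, W0 = W0, G0 = G0, W1 = W1, G1 = G1)
  brute <- 0
  for (i in 1:m) for (l in 1:k) for (j in 1:2) {
    brute <- brute + scaled_poisson_loglik(sc_al[i, l, j], X[i, l] * W0[l, j] * G0[j], Tm[i, l])
    brute <- brute + scaled_poisson_loglik(bk_al[i, l, j], X[i, l] * W1[l, j] * G1[j], Tm[i, l])
  }
  expect_equal(joint_loglik(sc2, bk2, pars, sc_al, bk_al), brute)

  # invariance under joint permutation of cell-type indices
  perm <- c(2, 1)
  pars_p <- list(X = X[, perm], T = Tm[, perm], W0 = W0[perm, ], G0 = G0,
                 W1 = W1[perm, ], G1 = G1)
  expect_equal(joint_loglik(sc2, bk2, pars_p, sc_al[, perm, , drop = FALSE],
                            bk_al[, perm, , drop = FALSE]),
               joint_loglik(sc2, bk2, pars, sc_al, bk_al))

  # gauge invariance: X -> cX, G -> G/c for all units simultaneously
  cc <- 3.7
  pars_g <- list(X = cc * X, T = Tm, W0 = W0, G0 = G0 / cc, W1 = W1, G1 = G1 / cc)
  expect_equal(joint_loglik(sc2, bk2, pars_g, sc_al, bk_al),
               joint_loglik(sc2, bk2, pars, sc_al, bk_al))
})

test_that("profile M-step is the weighted ratio and maximizes the objective", {
  # one unit, k = 1: Zhat = 10, W = 1, G = 2 -> X = 5
  expect_equal(poisdecon:::m_step_expression(matrix(10), 2), matrix(5))
  # two units, Zhat = {4, 6}, WG = {1, 1} -> X = 5
  expect_equal(poisdecon:::m_step_expression(matrix(4 + 6), 2), matrix(5))
  # zero totals give zero, not NaN
  expect_equal(poisdecon:::m_step_expression(matrix(0), 0), matrix(0))

  # golden-section / optimize() oracle on a random small instance
  set.seed(11)
  z <- rexp(4) * 5; wg <- runif(4, 0.5, 2); tt <- 1.3
  xhat <- sum(z) / sum(wg)
  f <- function(x) sum(scaled_poisson_loglik(z, x * wg, tt))
  opt <- optimize(f, interval = c(1e-6, 50), maximum = TRUE)$maximum
  expect_equal(xhat, opt, tolerance = 1e-4)
})

test_that("composition M-step lands on the simplex at the constrained optimum", {
  # k = 1 is always [1]
  r1 <- poisdecon:::m_step_composition(matrix(c(3, 1), 2, 1), matrix(c(2, 2), 2, 1),
                                       matrix(1, 2, 1))
  expect_equal(r1$w, 1)

  # equal profiles with allocation totals {30, 10} -> (0.75, 0.25)
  al <- cbind(c(20, 10), c(5, 5))
  X <- cbind(c(2, 3), c(2, 3)); Tm <- matrix(1, 2, 2)
  r2 <- poisdecon:::m_step_composition(al, X, Tm)
  expect_equal(r2$w, c(0.75, 0.25))

  # constrained numeric maximization oracle (profile the scale at each w)
  set.seed(13)
  X <- matrix(rexp(6) + 0.2, 3, 2); Tm <- matrix(runif(6, 0.5, 2), 3, 2)
  al <- matrix(rexp(6) * 4, 3, 2)
  r3 <- poisdecon:::m_step_composition(al, X, Tm)
  f <- function(w1) {
    w <- c(w1, 1 - w1)
    g <- sum(Tm * al) / sum(Tm * sweep(X, 2, w, "*"))  # optimal scale given w
    sum(scaled_poisson_loglik(as.numeric(al), as.numeric(sweep(X, 2, w * g, "*")),
                              as.numeric(Tm)))
  }
  opt <- optimize(f, c(1e-6, 1 - 1e-6), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(r3$w[1], opt, tolerance = 1e-4)
  expect_equal(sum(r3$w), 1, tolerance = 1e-12)

  # degenerate all-zero allocation flags and returns uniform
  r4 <- poisdecon:::m_step_composition(matrix(0, 3, 2), X, Tm)
  expect_true(r4$degenerate)
  expect_equal(r4$w, c(0.5, 0.5))
})

test_that("moment-matched precision recovers generating dispersions", {
  set.seed(17)
  n <- 2000; m <- 40
  for (t_true in c(0.25, 1)) {
    lam <- matrix(rep(rlnorm(m, log(30), 0.5), n), m, n)
    z <- matrix(rscaled_pois(m * n, as.numeric(lam), t_true), m, n)
    that <- poisdecon:::m_step_precision(matrix(rowSums(lam), ncol = 1),
                                         matrix(rowSums((z - lam)^2), ncol = 1),
                                         matrix(1, m, 1))[, 1]
    tol <- if (t_true < 1) 0.05 else 0.1
    expect_lt(abs(mean(that) - t_true), tol)
  }
  # zero empirical variance clamps at t_max; no information keeps the prior
  out <- poisdecon:::m_step_precision(matrix(c(5, 0)), matrix(c(0, 0)),
                                      matrix(c(1, 0.7)))
  expect_equal(out[1, 1], 1e3)
  expect_equal(out[2, 1], 0.7)
})

test_that("M-step blocks never decrease the joint objective at fixed allocation", {
  set.seed(23)
  for (rep in 1:10) {
    m <- sample(4:8, 1); k <- sample(2:3, 1); n <- sample(2:4, 1)
    X <- matrix(rexp(m * k) + 0.3, m, k)
    Tm <- matrix(runif(m * k, 0.5, 2), m, k)
    W <- sapply(seq_len(n), function(j) rsimplex(k))
    G <- runif(n, 0.5, 3)
    al <- array(rexp(m * k * n) * 3, c(m, k, n))
    obj <- function(X, Tm, W, G) {
      tot <- 0
      for (j in seq_len(n))
        tot <- tot + sum(scaled_poisson_loglik(
          as.numeric(al[, , j]),
          pmax(as.numeric(sweep(X, 2, W[, j] * G[j], "*")), 1e-300),
          as.numeric(Tm)))
      tot
    }
    base <- obj(X, Tm, W, G)
    X2 <- poisdecon:::m_step_expression(apply(al, c(1, 2), sum), as.numeric(W %*% G))
    expect_gte(obj(X2, Tm, W, G), base - 1e-8)
    base2 <- obj(X2, Tm, W, G)
    W2 <- W; G2 <- G
    for (j in seq_len(n)) {
      cs <- poisdecon:::m_step_composition(al[, , j], X2, Tm)
      W2[, j] <- cs$w; G2[j] <- cs$scale
    }
    expect_gte(obj(X2, Tm, W2, G2), base2 - 1e-8)
  }
})
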