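# Shared fixtures, all built in code at test time.

tiny_counts <- function(kind = "bulk") {
  v <- matrix(c(5, 0, 2,
                0, 3, 4), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("u1", "u2")))
  count_matrix(v, kind = kind)
}

# small two-type reference + one bulk mixture with known truth
small_mixture <- function(seed = 1, m = 80, cells_per_type = 15,
                          depth = 3e4, w = c(0.65, 0.35)) {
  ref <- simulate_reference(m = m, k = 2, cells_per_type = cells_per_type,
                            depth_mean = 500, type_names = c("A", "B"),
                            seed = seed)
  W <- matrix(w, dimnames = list(c("A", "B"), "b1"))
  bulk <- simulate_bulk(ref$truth$params$X, W, depth = depth, seed = seed + 77L)
  list(ref = ref, bulk = bulk, w = w)
}

# Dirichlet draw used by property loops
rsimplex <- function(k) {
  g <- rgamma(k, shape = 1)
  g / sum(g)
}
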