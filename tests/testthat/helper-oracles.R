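# Shared oracles and generators, independent of the code paths they check.

# O(|a| * |b|) double-loop sup-distance between the two ECDFs.
ks_oracle <- function(a, b) {
  best <- 0
  for (x in c(a, b)) {
    best <- max(best, abs(mean(a <= x) - mean(b <= x)))
  }
  best
}

# Random complete m-ary forest with random traits and degrees.
random_forest <- function(k, m, h, seed) {
  set.seed(seed)
  d <- forest_design(k, m, h)
  n <- forest_size(d)
  make_forest(d, trait = sample(0:1, n, replace = TRUE),
              degree = sample(1:6, n, replace = TRUE))
}

# Aggregate (value, prob) pairs keeping exact representative values.
agg_law <- function(values, probs) {
  idx <- split(seq_along(values), signif(values, 12))
  v <- vapply(idx, function(i) values[i[1L]], numeric(1))
  p <- vapply(idx, function(i) sum(probs[i]), numeric(1))
  ord <- order(v)
  list(values = unname(v[ord]), probs = unname(p[ord]))
}

# Classical i.i.d. bootstrap of k values: exact law of the mean by
# enumerating all k^k ordered with-replacement draws.
iid_bootstrap_law <- function(values) {
  k <- length(values)
  grid <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
  means <- rowMeans(matrix(values[grid], nrow(grid), k))
  agg_law(means, rep(1 / k^k, length(means)))
}

# Joint enumeration over all K^k (seed draw) combinations, taking the
# per-seed outcome lists as given: an independent route to the mean law
# that skips the convolution machinery.
joint_enumeration_law <- function(per_seed_supports, k, n) {
  draws <- unlist(per_seed_supports, use.names = FALSE)
  K <- length(draws)
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), k)))
  sums <- rowSums(matrix(draws[grid], nrow(grid), k))
  agg_law(sums / n, rep(1 / K^k, length(sums)))
}

expect_law_equal <- function(law_a, law_b, tol = 1e-12) {
  expect_equal(length(law_a$values), length(law_b$values))
  expect_equal(law_a$values, law_b$values, tolerance = tol)
  expect_equal(law_a$probs, law_b$probs, tolerance = tol)
}

# Temp paths (tempfile does not touch the R RNG stream).
withr_local_file <- function(name) tempfile(pattern = paste0(name, "-"))
withr_local_dir <- function() {
  d <- tempfile("clidir")
  dir.create(d)
  d
}

# Small deterministic graphs.
triangle_graph <- function(trait = c(1, 0, 1)) {
  population_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), trait = trait)
}

star_graph <- function(leaves = 3, trait = NULL) {
  if (is.null(trait)) trait <- rep(c(1, 0), length.out = leaves + 1)
  population_graph(cbind(1L, 1L + seq_len(leaves)), trait = trait)
}
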