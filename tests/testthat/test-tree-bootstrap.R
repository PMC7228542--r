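test_that("resampling preserves the design and the origin links", {
  f <- random_forest(k = 3, m = 2, h = 2, seed = 1)
  b <- tree_resample(f, rng_seed = 2)
  expect_s3_class(b, "bootstrap_forest")
  expect_identical(b$design, f$design)
  expect_equal(nrow(b$nodes), nrow(f$nodes))
  nd <- f$nodes
  bo <- b$nodes
  # roots map to roots
  expect_true(all(bo$origin[is.na(bo$parent)] %in% nd$node[is.na(nd$parent)]))
  # each non-root's origin is a child of its parent's origin
  nonroot <- which(!is.na(bo$parent))
  parent_origin <- bo$origin[bo$parent[nonroot]]
  expect_true(all(nd$parent[bo$origin[nonroot]] == parent_origin))
  # traits and degrees inherited from origins
  expect_equal(bo$trait, nd$trait[bo$origin])
  expect_equal(bo$degree, nd$degree[bo$origin])
})

test_that("a height-0 resample is i.i.d. seed resampling", {
  f <- fixture_forest("three_seeds_h0")
  set.seed(3)
  for (i in 1:10) {
    b <- tree_resample(f)
    expect_true(all(b$nodes$origin %in% 1:3))
  }
})

test_that("an m = 1 single chain resamples to itself", {
  f <- fixture_forest("chain_m1")
  b <- tree_resample(f, rng_seed = 9)
  expect_identical(b$nodes$origin, f$nodes$node)
  expect_identical(b$nodes$trait, f$nodes$trait)
})

test_that("child-pair resampling frequencies match the enumerated law", {
  # k=1, m=2, h=1, child traits (0, 1): pair sums 0,1,2 w.p. 1/4, 1/2, 1/4
  f <- fixture_forest("single_tree_h1")
  B <- 40000
  bs <- bootstrap_replicates(f, "sample_mean", B = B, rng_seed = 12)
  sums <- round(3 * bs$replicate_values - 1)  # root trait is 1
  freq <- tabulate(sums + 1L, nbins = 3) / B
  expected <- c(1 / 4, 1 / 2, 1 / 4)
  se <- sqrt(expected * (1 - expected) / B)
  expect_true(all(abs(freq - expected) < 3 * se))
})

test_that("replicate generation is deterministic given the seed", {
  f <- random_forest(2, 2, 2, seed = 4)
  a <- bootstrap_replicates(f, "vh", B = 500, rng_seed = 7)
  b <- bootstrap_replicates(f, "vh", B = 500, rng_seed = 7)
  expect_identical(a$replicate_values, b$replicate_values)
  expect_error(bootstrap_replicates(f, "hajek", B = 10), "arg")
})

test_that("constant-trait forests give constant replicates", {
  f <- make_forest(forest_design(2, 2, 1), trait = rep(1L, 6),
                   degree = rep(2, 6))
  bs <- bootstrap_replicates(f, "sample_mean", B = 200, rng_seed = 1)
  expect_true(all(bs$replicate_values == 1))
  expect_equal(bootstrap_variance(bs), 0)
})

test_that("exact enumeration reproduces the worked single-tree law", {
  ed <- exact_distribution(fixture_forest("single_tree_h1"))
  expect_equal(ed$per_tree_count, 4)
  expect_equal(ed$total_count, 4)
  expect_equal(ed$support, c(1 / 3, 2 / 3, 1))
  expect_equal(ed$probs, c(1 / 4, 1 / 2, 1 / 4))
  expect_equal(ed$mean, 2 / 3, tolerance = 1e-12)
  expect_equal(ed$variance, 1 / 18, tolerance = 1e-12)
  # per-seed sums are the 4 ordered child pairs plus the root
  expect_equal(sort(ed$per_seed_supports[[1]]), c(1, 2, 2, 3))
})

test_that("exact bootstrap mean equals the sample mean on random forests", {
  cases <- expand.grid(m = c(2, 3), h = 1:2, k = 1:3)
  cases <- cases[!(cases$m == 3 & cases$h == 2), ]
  for (i in seq_len(nrow(cases))) {
    f <- random_forest(cases$k[i], cases$m[i], cases$h[i], seed = 100 + i)
    ed <- exact_distribution(f)
    expect_equal(ed$mean, sample_mean(f)$value, tolerance = 1e-12)
    expect_equal(sum(ed$probs), 1, tolerance = 1e-12)
    expect_equal(ed$per_tree_count,
                 length(ed$per_seed_supports[[1]]))
  }
})

test_that("seed-only enumeration matches the multinomial closed form", {
  ed <- exact_distribution(fixture_forest("three_seeds_h0"))
  expect_equal(ed$per_tree_count, 1)
  expect_equal(ed$total_count, 3)
  expect_equal(sort(unique(unlist(ed$per_seed_supports))), c(0, 1))
  expect_equal(ed$variance, (2 / 9) / 3, tolerance = 1e-12)
})

test_that("the k-seed law is the k-fold convolution of the per-draw law", {
  for (spec in list(c(2, 2, 1), c(3, 1, 0), c(2, 3, 1))) {
    f <- random_forest(spec[1], spec[2], spec[3], seed = sum(spec))
    ed <- exact_distribution(f)
    oracle <- joint_enumeration_law(ed$per_seed_supports, spec[1],
                                    forest_size(f$design))
    expect_law_equal(list(values = ed$support, probs = ed$probs), oracle)
  }
})

test_that("exact enumeration supports the IPW relabelling, rejects VH", {
  f <- random_forest(2, 2, 1, seed = 8)
  ed <- exact_distribution(f, estimator = "ipw", total_degree = 30,
                           population_size = 10)
  expect_equal(ed$mean, ipw_estimate(f, 30, 10)$value, tolerance = 1e-12)
  expect_error(exact_distribution(f, estimator = "vh"), "Monte Carlo|ratio")
})

test_that("the enumeration guard trips on infeasible forests", {
  f <- random_forest(1, 2, 4, seed = 1)  # a = (2 f(3))^2 > 1e9
  expect_error(exact_distribution(f), "Monte Carlo")
})

test_that("Monte Carlo variance converges to the exact variance", {
  f <- fixture_forest("two_trees_h2")
  ed <- exact_distribution(f)
  bs <- bootstrap_replicates(f, "sample_mean", B = 20000, rng_seed = 21)
  se_mean <- sqrt(ed$variance / bs$B)
  expect_lt(abs(mean(bs$replicate_values) - ed$mean), 3 * se_mean)
  # bootstrap-of-bootstrap standard error for the variance
  v <- bs$replicate_values - mean(bs$replicate_values)
  se_var <- sqrt(stats::var(v^2) / bs$B)
  expect_lt(abs(bootstrap_variance(bs) - ed$variance), 3 * se_var)
})

test_that("bootstrap variance is the 1/B population form", {
  fake <- structure(list(replicate_values = c(0, 1), B = 2L),
                    class = "bootstrap_summary")
  expect_equal(bootstrap_variance(fake), 0.25)
  fake$replicate_values <- c(0, 0)
  expect_equal(bootstrap_variance(fake), 0)
  fake$replicate_values <- 1
  expect_error(bootstrap_variance(fake), "at least 2")
})

test_that("confidence intervals follow the documented conventions", {
  fake <- structure(list(replicate_values = as.numeric(1:100),
                         estimate = 50.5, B = 100L),
                    class = "bootstrap_summary")
  ci <- bootstrap_ci(fake, level = 0.9, method = "percentile")
  expect_equal(ci, c(5.95, 95.05))
  v <- bootstrap_variance(fake)
  ci_n <- bootstrap_ci(fake, level = 0.95, method = "normal")
  expect_equal(ci_n, 50.5 + c(-1, 1) * qnorm(0.975) * sqrt(v))
  const <- structure(list(replicate_values = rep(0.4, 50), estimate = 0.4,
                          B = 50L),
                     class = "bootstrap_summary")
  expect_equal(bootstrap_ci(const, 0.95, "percentile"), c(0.4, 0.4))
  expect_equal(bootstrap_ci(const, 0.95, "normal"), c(0.4, 0.4))
  expect_error(bootstrap_ci(fake, level = 1.2), "level")
})
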