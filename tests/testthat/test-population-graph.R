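test_that("SBM with p = r = 1 is the complete graph", {
  g <- make_sbm(sbm_params(1, 3, 1, 1), rng_seed = 1)
  expect_equal(g$num_vertices, 6L)
  expect_equal(graph_degrees(g), rep(5L, 6L))
})

test_that("SBM with r = 0 and one block pair is disconnected", {
  g <- make_sbm(sbm_params(1, 3, 1, 0), rng_seed = 1)
  expect_equal(sort(unique(graph_degrees(g))), 2L)  # two triangles
  expect_error(stationary_distribution(g), "disconnected")
  expect_error(make_sbm(sbm_params(1, 3, 1, 0), rng_seed = 1,
                        require_connected = TRUE, max_tries = 5),
               "connected")
})

test_that("SBM parameter validation rejects bad inputs", {
  expect_error(sbm_params(2, 0, 0.3, 0.2), "block_size")
  expect_error(sbm_params(2, 10, 1.3, 0.2), "probabilities")
  expect_error(sbm_params(2, 10, 0.3, -0.1), "probabilities")
})

test_that("realized SBM block-pair edge densities match p and r", {
  sp <- sbm_params(2, 50, 0.3, 0.2)
  n_seeds <- 200
  within <- numeric(n_seeds)
  between <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    g <- make_sbm(sp, rng_seed = s)
    em <- igraph::as_edgelist(g$igraph, names = FALSE)
    same <- g$block[em[, 1]] == g$block[em[, 2]]
    within[s] <- sum(same) / (4 * choose(50, 2))
    between[s] <- sum(!same) / (choose(200, 2) - 4 * choose(50, 2))
  }
  se_w <- sqrt(0.3 * 0.7 / (n_seeds * 4 * choose(50, 2)))
  se_b <- sqrt(0.2 * 0.8 / (n_seeds * (choose(200, 2) - 4 * choose(50, 2))))
  expect_lt(abs(mean(within) - 0.3), 3 * se_w)
  expect_lt(abs(mean(between) - 0.2), 3 * se_b)
})

test_that("trait assignment follows blocks, with overrides", {
  sp <- sbm_params(2, 5, 0.5, 0.5)
  g <- make_sbm(sp, rng_seed = 1)
  expect_equal(g$trait, as.integer(g$block <= 2))
  g2 <- make_sbm(sp, trait_rule = function(b) b %% 2, rng_seed = 1)
  expect_equal(g2$trait, g2$block %% 2L)
  custom <- rep(c(0L, 1L), 10)
  g3 <- make_sbm(sp, trait_rule = custom, rng_seed = 1)
  expect_equal(g3$trait, custom)
})

test_that("transition kernel has the degree-normalized form", {
  P <- transition_kernel(triangle_graph())
  expect_equal(diag(P), rep(0, 3), ignore_attr = TRUE)
  expect_equal(P[1, 2], 0.5)
  expect_true(all(P[upper.tri(P)] == 0.5))
  # path a-b-c
  gp <- population_graph(rbind(c(1, 2), c(2, 3)), trait = c(0, 1, 0))
  Pp <- transition_kernel(gp)
  expect_equal(Pp[2, ], c(0.5, 0, 0.5), ignore_attr = TRUE)
  expect_equal(Pp[1, ], c(0, 1, 0), ignore_attr = TRUE)
  expect_equal(Pp[3, ], c(0, 1, 0), ignore_attr = TRUE)
})

test_that("kernel is row-stochastic and reversible on random graphs", {
  for (s in 1:5) {
    g <- make_sbm(sbm_params(1, 6, 0.5, 0.5), rng_seed = s,
                  require_connected = TRUE)
    P <- transition_kernel(g)
    deg <- graph_degrees(g)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    M <- deg * P  # M[i, j] = deg_i * P_ij; reversibility <=> M symmetric
    expect_lt(max(abs(M - t(M))), 1e-12)
    A <- as.matrix(igraph::as_adjacency_matrix(g$igraph))
    expect_true(all((P > 0) == (A > 0)))
  }
})

test_that("isolated vertices are rejected by name", {
  g <- population_graph(rbind(c(1, 2)), trait = c(0, 1, 1), num_vertices = 3)
  expect_error(transition_kernel(g), "vertex.*3")
})

test_that("stationary distribution is degree-proportional and invariant", {
  expect_equal(stationary_distribution(triangle_graph()), rep(1 / 3, 3))
  expect_equal(stationary_distribution(star_graph(3)),
               c(1 / 2, 1 / 6, 1 / 6, 1 / 6))
  g <- make_sbm(sbm_params(1, 5, 0.6, 0.6), rng_seed = 3,
                require_connected = TRUE)
  pi <- stationary_distribution(g)
  P <- transition_kernel(g)
  expect_equal(sum(pi), 1, tolerance = 1e-12)
  expect_lt(max(abs(as.vector(pi %*% P) - pi)), 1e-12)
})

test_that("stationary distribution is uniform on regular graphs", {
  g <- make_sbm(sbm_params(1, 3, 1, 1), rng_seed = 1)  # complete K6
  expect_equal(stationary_distribution(g), rep(1 / 6, 6))
})

test_that("tilde_p follows the printed closed form", {
  expect_equal(tilde_p(sbm_params(2, 10, 0.3, 0.2)), 0.6)
  expect_equal(tilde_p(sbm_params(3, 10, 0.4, 0)), 1.0)
  expect_equal(tilde_p(sbm_params(2, 10, 0.25, 0.25)), 0.5)
  expect_error(tilde_p(sbm_params(2, 10, 0, 0)), "positive")
})

test_that("critical-threshold test uses strict inequalities", {
  expect_true(below_threshold(sbm_params(2, 10, 0.3, 0.2)))   # p~ = 0.6
  expect_false(below_threshold(sbm_params(2, 10, 0.2, 0.6)))  # p~ = 0.25 boundary
  expect_false(below_threshold(sbm_params(2, 10, 0.5, 0.1)))  # p~ = 5/6
})

test_that("population graph constructor enforces simplicity and traits", {
  expect_error(population_graph(rbind(c(1, 1)), trait = c(0, 1),
                                num_vertices = 2), "self-loop")
  expect_error(population_graph(rbind(c(1, 2)), trait = c(0, 2)), "0 or 1")
  expect_error(population_graph(rbind(c(1, 5)), trait = c(0, 1)), "vertex ids")
  # duplicate and reversed edges collapse
  g <- population_graph(rbind(c(1, 2), c(2, 1), c(1, 2)), trait = c(0, 1))
  expect_equal(igraph::ecount(g$igraph), 1)
})
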