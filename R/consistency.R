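#' Kolmogorov distance between two empirical distributions
#'
#' The sup-norm distance between the two empirical distribution functions
#' (right-continuous convention), evaluated over the pooled jump points --
#' where the maximum of two step functions must occur.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return scalar in `[0, 1]`
#' @export
kolmogorov_distance <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) {
    stop("both samples must be non-empty")
  }
  x <- sort(unique(c(sample_a, sample_b)))
  Fa <- stats::ecdf(sample_a)(x)
  Fb <- stats::ecdf(sample_b)(x)
  max(abs(Fa - Fb))
}

#' Build a design growth schedule
#'
#' A schedule is a sequence of forest designs with a common branching `m`
#' along which per-tree size `l` grows but slowly relative to the total
#' sample: `l` strictly increasing and `l/sqrt(n)` strictly decreasing,
#' the finite-sample surrogate of `l(n) = o(sqrt(n))` with `l -> infinity`
#' that bootstrap consistency requires.  The default rule sets the height
#' at stage `t` to `h = t` and the seed count to `k = l^2`, which gives
#' `l/sqrt(n) = l^{-1/2} -> 0`.
#'
#' @param m branching factor.
#' @param stages number of stages (>= 2) for the default rule.
#' @param rule `"k_eq_l_squared"` (default) or `"custom"`.
#' @param heights,seeds stage vectors for `rule = "custom"`.
#' @return a `"growth_schedule"` with a `stages` data frame
#'   (`stage, h, k, l, n`).
#' @export
make_schedule <- function(m, stages = 2L, rule = c("k_eq_l_squared", "custom"),
                          heights = NULL, seeds = NULL) {
  rule <- match.arg(rule)
  m <- as.integer(m)
  if (m < 1L) stop("branching m must be a positive integer")
  if (rule == "k_eq_l_squared") {
    stages <- as.integer(stages)
    if (stages < 2L) stop("a schedule needs at least 2 stages")
    heights <- seq_len(stages)
    l <- vapply(heights, function(h) tree_size(forest_design(1L, m, h)),
                integer(1))
    seeds <- l^2
  } else {
    if (is.null(heights) || is.null(seeds) ||
        length(heights) != length(seeds) || length(heights) < 2L) {
      stop("custom rule needs matching heights and seeds vectors, length >= 2")
    }
    heights <- as.integer(heights)
    seeds <- as.integer(seeds)
    l <- vapply(heights, function(h) tree_size(forest_design(1L, m, h)),
                integer(1))
  }
  n <- seeds * l
  ratio <- l / sqrt(n)
  if (any(diff(l) <= 0)) {
    stop("schedule invalid: per-tree size l must be strictly increasing")
  }
  if (any(diff(ratio) >= 0)) {
    stop("schedule invalid: l/sqrt(n) must be strictly decreasing ",
         "(the o(sqrt(n)) surrogate)")
  }
  structure(
    list(m = m, rule = rule,
         stages = data.frame(stage = seq_along(heights), h = heights,
                             k = seeds, l = l, n = n)),
    class = "growth_schedule"
  )
}

#' @export
print.growth_schedule <- function(x, ...) {
  cat("growth_schedule (m =", x$m, ", rule =", x$rule, "):\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

# The estimand each estimator is centred on.
estimator_target <- function(graph, estimator) {
  switch(estimator,
    sample_mean = degree_weighted_mean(graph),
    vh = ,
    ipw = population_mean(graph),
    stop("unknown estimator: ", estimator)
  )
}

apply_estimator <- function(forest, estimator, total_degree = NULL,
                            population_size = NULL) {
  switch(estimator,
    sample_mean = sample_mean(forest)$value,
    vh = vh_estimate(forest)$value,
    ipw = ipw_estimate(forest, total_degree, population_size)$value
  )
}

#' Monte Carlo sampling distribution of an RDS estimator
#'
#' Simulates `reps` independent respondent-driven samples from the graph
#' and returns the centred, root-n-scaled estimates
#' `sqrt(n) * (estimate - target)`, where the target is the
#' degree-weighted mean `mu` for the sample mean and the true mean `mu0`
#' for the IPW and Volz--Heckathorn estimators.
#'
#' @param graph a connected [population_graph()].
#' @param design a [forest_design()].
#' @param estimator `"sample_mean"`, `"vh"` or `"ipw"`.
#' @param reps number of simulated samples (>= 2).
#' @param rng_seed optional integer seed.
#' @param total_degree,population_size required for `"ipw"`.
#' @return numeric vector of length `reps`; its variance estimates the
#'   limiting `rho^2`.
#' @export
sampling_distribution <- function(graph, design, estimator = "sample_mean",
                                  reps, rng_seed = NULL,
                                  total_degree = NULL,
                                  population_size = NULL) {
  estimator <- match.arg(estimator, c("sample_mean", "vh", "ipw"))
  reps <- as.integer(reps)
  if (reps < 2L) stop("reps must be at least 2")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  target <- estimator_target(graph, estimator)
  n <- forest_size(design)
  vals <- vapply(seq_len(reps), function(r) {
    f <- simulate_forest(graph, design)
    apply_estimator(f, estimator, total_degree, population_size)
  }, numeric(1))
  sqrt(n) * (vals - target)
}

#' Run a bootstrap-consistency experiment
#'
#' For each stage of a growth schedule, estimates the true sampling law of
#' the centred, scaled estimator by Monte Carlo, then for each of `R`
#' freshly simulated samples runs the tree bootstrap (`B` replicates),
#' measures the Kolmogorov distance between the centred bootstrap law
#' `sqrt(n)(Xbar* - Xbar)` and the sampling law `sqrt(n)(Xbar - mu)`,
#' records whether the bootstrap confidence interval covers the estimand,
#' and tracks the scaled bootstrap variance `n * sigma_hat^2`.  Under a
#' below-threshold population and an admissible schedule the median
#' distance shrinks across stages and coverage approaches nominal.
#'
#' @param config a list with components:
#'   \describe{
#'     \item{graph}{a [population_graph()], or `sbm`, a list with `K`,
#'       `block_size`, `p`, `r`, optional `seed`, `require_connected`.}
#'     \item{schedule}{a [make_schedule()] result, or a list with `m`,
#'       `stages` and optional `rule`/`heights`/`seeds`.}
#'     \item{estimator}{`"sample_mean"` (default), `"vh"` or `"ipw"`.}
#'     \item{reps}{Monte Carlo size for the sampling law (default 2000).}
#'     \item{R}{samples per stage to bootstrap (default 200).}
#'     \item{B}{bootstrap replicates per sample (default 2000).}
#'     \item{level}{nominal CI level (default 0.95).}
#'     \item{method}{CI method, `"percentile"` (default) or `"normal"`.}
#'     \item{rng_seed}{integer seed for the whole run (default 1).}
#'   }
#' @return an `"experiment_result"`: a per-stage data frame with columns
#'   `stage, n, k, h, l, ks_median, coverage, scaled_var_median, rho2_hat`,
#'   plus the per-stage distance vectors and any threshold warning.
#' @export
run_consistency_experiment <- function(config) {
  cfg <- config
  estimator <- if (is.null(cfg$estimator)) "sample_mean" else cfg$estimator
  estimator <- match.arg(estimator, c("sample_mean", "vh", "ipw"))
  reps <- if (is.null(cfg$reps)) 2000L else as.integer(cfg$reps)
  R <- if (is.null(cfg$R)) 200L else as.integer(cfg$R)
  B <- if (is.null(cfg$B)) 2000L else as.integer(cfg$B)
  level <- if (is.null(cfg$level)) 0.95 else cfg$level
  method <- if (is.null(cfg$method)) "percentile" else cfg$method
  rng_seed <- if (is.null(cfg$rng_seed)) 1L else as.integer(cfg$rng_seed)

  warnings <- character(0)
  if (!is.null(cfg$graph)) {
    graph <- cfg$graph
    stopifnot(inherits(graph, "population_graph"))
  } else if (!is.null(cfg$sbm)) {
    sp <- sbm_params(cfg$sbm$K, cfg$sbm$block_size, cfg$sbm$p, cfg$sbm$r)
    if (!below_threshold(sp)) {
      warnings <- c(warnings, paste0(
        "SBM is not below the critical threshold (tilde_p = ",
        format(tilde_p(sp), digits = 4),
        "); the consistency guarantee does not apply"))
    }
    graph <- make_sbm(
      sp, rng_seed = if (is.null(cfg$sbm$seed)) rng_seed else cfg$sbm$seed,
      require_connected = !isFALSE(cfg$sbm$require_connected))
  } else {
    stop("config needs either a graph or an sbm block")
  }
  check_connected(graph, "the consistency experiment")

  sched <- cfg$schedule
  if (!inherits(sched, "growth_schedule")) {
    sched <- make_schedule(
      m = sched$m,
      stages = if (is.null(sched$stages)) 2L else sched$stages,
      rule = if (is.null(sched$rule)) "k_eq_l_squared" else sched$rule,
      heights = sched$heights, seeds = sched$seeds)
  }

  td <- sum(graph_degrees(graph))
  N <- graph$num_vertices
  target <- estimator_target(graph, estimator)

  set.seed(rng_seed)
  stage_rows <- vector("list", nrow(sched$stages))
  stage_distances <- vector("list", nrow(sched$stages))
  for (t in seq_len(nrow(sched$stages))) {
    srow <- sched$stages[t, ]
    design <- forest_design(srow$k, sched$m, srow$h)
    n <- forest_size(design)
    message(sprintf("stage %d: n = %d (k = %d, h = %d); sampling law (%d reps)",
                    srow$stage, n, srow$k, srow$h, reps))
    samp_law <- sampling_distribution(graph, design, estimator, reps,
                                      total_degree = td,
                                      population_size = N)
    ks <- numeric(R)
    cover <- logical(R)
    sc_var <- numeric(R)
    for (r in seq_len(R)) {
      f <- simulate_forest(graph, design)
      bs <- bootstrap_replicates(f, estimator, B,
                                 total_degree = td, population_size = N)
      centred <- sqrt(n) * (bs$replicate_values - bs$estimate)
      ks[r] <- kolmogorov_distance(centred, samp_law)
      ci <- bootstrap_ci(bs, level = level, method = method)
      cover[r] <- ci[1] <= target && target <= ci[2]
      sc_var[r] <- n * bs$variance
    }
    message(sprintf("stage %d: median KS %.4f, coverage %.3f",
                    srow$stage, stats::median(ks), mean(cover)))
    stage_rows[[t]] <- data.frame(
      stage = srow$stage, n = n, k = srow$k, h = srow$h, l = srow$l,
      ks_median = stats::median(ks), coverage = mean(cover),
      scaled_var_median = stats::median(sc_var),
      rho2_hat = stats::var(samp_law))
    stage_distances[[t]] <- ks
  }
  structure(
    list(stages = do.call(rbind, stage_rows),
         distances = stage_distances,
         estimator = estimator, level = level, method = method,
         R = R, B = B, reps = reps, rng_seed = rng_seed,
         warnings = warnings),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (", x$estimator, ", ", x$R, " samples x ", x$B,
      " replicates, sampling law ", x$reps, " reps):\n", sep = "")
  print(x$stages, row.names = FALSE)
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Write an experiment result as CSV
#' @param result an `"experiment_result"`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_experiment_csv <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  utils::write.csv(result$stages, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
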