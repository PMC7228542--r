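#' @title The tree bootstrap
#' @description
#' The tree bootstrap resamples a recruitment forest by drawing the `k`
#' bootstrap seeds uniformly with replacement from the original seeds and
#' then, recursively, drawing each resampled node's `m` recruits uniformly
#' with replacement from the recruits its origin had in the original
#' sample, down to the leaves.  Because every tree is a complete `m`-ary
#' tree, every replicate has exactly the original `n` nodes, and the
#' resampling preserves homophily by never mixing recruits across
#' branches.
#' @name tree-bootstrap
NULL

# B x n matrix of origin node indices, canonical slot order, one row per
# bootstrap replicate.  Vectorized across replicates wave by wave.
resample_origin_matrix <- function(forest, B, st = forest_structure(forest)) {
  d <- forest$design
  k <- d$num_seeds
  m <- d$branching
  h <- d$height
  slots <- st$slots
  n <- nrow(slots)
  O <- matrix(NA_integer_, B, n)
  rootslots <- st$roots
  O[, rootslots] <- st$roots[sample.int(k, B * k, replace = TRUE)]
  if (h >= 1L) {
    for (w in 1:h) {
      cs <- which(slots$wave == w)
      pm <- O[, slots$parent[cs], drop = FALSE]
      pick <- sample.int(m, B * length(cs), replace = TRUE)
      O[, cs] <- st$children[cbind(as.vector(pm), pick)]
    }
  }
  O
}

#' Draw one tree-bootstrap replicate
#'
#' @param forest a valid `"recruitment_forest"`
#' @param rng_seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `"bootstrap_forest"`: same design and canonical shape, with an
#'   `origin` column mapping each node to the source node it copies; trait
#'   and degree are inherited from the origin.
#' @export
tree_resample <- function(forest, rng_seed = NULL) {
  validate_forest(forest)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  origin <- as.vector(resample_origin_matrix(forest, 1L))
  nd <- forest$nodes
  boot <- new_forest(forest$design, nd$member[origin], nd$trait[origin],
                     nd$degree[origin])
  boot$nodes$origin <- origin
  class(boot) <- c("bootstrap_forest", class(boot))
  boot
}

#' Generate Monte Carlo bootstrap replicates of an estimator
#'
#' Draws `B` independent tree-bootstrap replicates and applies the chosen
#' estimator to each.  The replicate generation is vectorized across
#' replicates, so large `B` is cheap on small forests.
#'
#' @param forest a valid `"recruitment_forest"`
#' @param estimator one of `"sample_mean"`, `"vh"`, `"ipw"`.
#' @param B number of replicates (>= 1).
#' @param rng_seed optional integer seed.
#' @param total_degree,population_size required for `"ipw"`.
#' @return a `"bootstrap_summary"`: `replicate_values` (length `B`, in
#'   generation order), `variance` (the `1/B`-normalized bootstrap variance,
#'   `NA` when `B = 1`), `estimate` (the estimator on the original forest),
#'   plus bookkeeping fields; the interval is unset until [bootstrap_ci()].
#' @export
bootstrap_replicates <- function(forest, estimator = "sample_mean", B,
                                 rng_seed = NULL, total_degree = NULL,
                                 population_size = NULL) {
  validate_forest(forest)
  estimator <- match.arg(estimator, c("sample_mean", "vh", "ipw"))
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nd <- forest$nodes
  n <- nrow(nd)
  st <- forest_structure(forest)
  point <- switch(estimator,
    sample_mean = sample_mean(forest)$value,
    vh = vh_estimate(forest)$value,
    ipw = ipw_estimate(forest, total_degree, population_size)$value
  )
  # chunk so the B x n index matrix stays modest in memory
  chunk <- max(1L, as.integer(floor(5e6 / n)))
  vals <- numeric(B)
  done <- 0L
  while (done < B) {
    b <- min(chunk, B - done)
    O <- resample_origin_matrix(forest, b, st)
    tr <- matrix(nd$trait[O], b, n)
    vals[done + seq_len(b)] <- switch(estimator,
      sample_mean = rowMeans(tr),
      vh = {
        di <- matrix(1 / nd$degree[O], b, n)
        rowSums(tr * di) / rowSums(di)
      },
      ipw = {
        di <- matrix(1 / nd$degree[O], b, n)
        total_degree / (n * population_size) * rowSums(tr * di)
      }
    )
    done <- done + b
  }
  structure(
    list(replicate_values = vals, B = B, estimator = estimator,
         estimate = point,
         variance = if (B >= 2L) mean((vals - mean(vals))^2) else NA_real_,
         interval = NULL, method = NULL, level = NULL),
    class = "bootstrap_summary"
  )
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat("bootstrap_summary:", x$B, "replicates of", x$estimator,
      "; point", format(x$estimate, digits = 6),
      "; variance", format(x$variance, digits = 6), "\n")
  if (!is.null(x$interval)) {
    cat("  ", format(100 * x$level), "% ", x$method, " interval: [",
        format(x$interval[1], digits = 6), ", ",
        format(x$interval[2], digits = 6), "]\n", sep = "")
  }
  invisible(x)
}

#' Bootstrap variance of the replicate values
#'
#' The `1/B`-normalized (population-style) variance of the replicates, so
#' that as `B` grows it converges to the exact bootstrap variance without
#' a finite-`B` correction.
#'
#' @param summary a `"bootstrap_summary"` with `B >= 2`.
#' @return non-negative scalar
#' @export
bootstrap_variance <- function(summary) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  v <- summary$replicate_values
  if (length(v) < 2L) stop("bootstrap variance needs at least 2 replicates")
  mean((v - mean(v))^2)
}

#' Bootstrap confidence interval
#'
#' Percentile intervals take the empirical `alpha/2` and `1 - alpha/2`
#' quantiles of the replicate values using the linear-interpolation
#' quantile definition ([stats::quantile()] type 7), so they are
#' reproducible bit-for-bit given the seed.  Normal intervals are
#' `estimate +/- z * sqrt(bootstrap variance)`.
#'
#' @param summary a `"bootstrap_summary"`.
#' @param level confidence level in (0, 1).
#' @param method `"percentile"` (default) or `"normal"`.
#' @return numeric `c(lower, upper)`
#' @export
bootstrap_ci <- function(summary, level = 0.95,
                         method = c("percentile", "normal")) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || is.na(level) ||
      level <= 0 || level >= 1) {
    stop("level must be in (0, 1)")
  }
  alpha <- 1 - level
  v <- summary$replicate_values
  if (method == "percentile") {
    if (length(v) < 2L) stop("percentile interval needs at least 2 replicates")
    ci <- unname(stats::quantile(v, c(alpha / 2, 1 - alpha / 2), type = 7))
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    hw <- z * sqrt(bootstrap_variance(summary))
    ci <- c(summary$estimate - hw, summary$estimate + hw)
  }
  ci
}

# Number of order-distinguished resampled trees of one seed's tree:
# f(0) = 1, f(d) = (m f(d-1))^m.
resample_tree_count <- function(m, h) {
  f <- 1
  if (h >= 1L) for (d in 1:h) f <- (m * f)^m
  f
}

# All order-distinguished resampled-subtree value sums below `node`.
subtree_resample_sums <- function(node, children, values) {
  ch <- children[node, ]
  ch <- ch[!is.na(ch)]
  if (length(ch) == 0L) return(values[node])
  draws <- unlist(lapply(ch, subtree_resample_sums,
                         children = children, values = values),
                  use.names = FALSE)
  acc <- draws
  m <- length(ch)
  if (m >= 2L) for (j in 2:m) acc <- as.vector(outer(acc, draws, "+"))
  values[node] + acc
}

# Aggregate a discrete distribution by support value (keyed at 12
# significant digits; exact representative values are kept, not the keys).
dist_aggregate <- function(values, probs) {
  idx <- split(seq_along(values), signif(values, 12))
  v <- vapply(idx, function(i) values[i[1L]], numeric(1))
  p <- vapply(idx, function(i) sum(probs[i]), numeric(1))
  ord <- order(v)
  list(values = unname(v[ord]), probs = unname(p[ord]))
}

dist_convolve <- function(a, b) {
  dist_aggregate(as.vector(outer(a$values, b$values, "+")),
                 as.vector(outer(a$probs, b$probs)))
}

#' Exact enumeration of the tree-bootstrap distribution
#'
#' Enumerates, for each seed tree, every order-distinguished resampled
#' tree (there are `a = f(h)` of them, with `f(0) = 1` and
#' `f(d) = (m f(d-1))^m`), giving `K = a k` equally likely (tree, outcome)
#' pairs.  The bootstrap mean is the average of `k` i.i.d. draws from this
#' uniform law, so its exact distribution is the `k`-fold convolution of
#' the per-draw law.  Exact mean and variance follow; the exact mean
#' always equals the sample mean (the tree bootstrap is exactly unbiased
#' for it).
#'
#' @param forest a valid `"recruitment_forest"`.
#' @param estimator `"sample_mean"` (default) or `"ipw"` (via the `x_pi`
#'   per-node relabelling).  The Volz--Heckathorn ratio is not a per-node
#'   mean and cannot be enumerated this way; use Monte Carlo.
#' @param values optional explicit per-node numeric values overriding the
#'   estimator's relabelling.
#' @param total_degree,population_size required for `"ipw"`.
#' @param max_outcomes guard on `K = a k`; enumeration beyond it errors
#'   with advice to use Monte Carlo instead.
#' @return an `"exact_boot_dist"`: `per_seed_supports` (list of `k`
#'   length-`a` vectors of resampled-tree value sums), `per_tree_count`
#'   (`a`), `total_count` (`K`), `support`/`probs` for the bootstrap mean,
#'   and its exact `mean` and `variance`.
#' @export
exact_distribution <- function(forest, estimator = "sample_mean",
                               values = NULL, total_degree = NULL,
                               population_size = NULL, max_outcomes = 1e7) {
  validate_forest(forest)
  d <- forest$design
  k <- d$num_seeds
  m <- d$branching
  h <- d$height
  l <- tree_size(d)
  n <- k * l
  if (is.null(values)) {
    if (estimator == "vh") {
      stop("the Volz-Heckathorn ratio has no per-node linear form; ",
           "exact enumeration is unavailable - use bootstrap_replicates()")
    }
    values <- estimator_node_values(forest, estimator, total_degree,
                                    population_size)
  }
  a <- resample_tree_count(m, h)
  K <- a * k
  if (K > max_outcomes) {
    stop("exact enumeration would cover ", format(K, big.mark = ","),
         " outcomes (> ", format(max_outcomes, scientific = FALSE),
         "); use bootstrap_replicates() for Monte Carlo instead")
  }
  st <- forest_structure(forest)
  per_seed <- lapply(st$roots, subtree_resample_sums,
                     children = st$children, values = values)
  stopifnot(all(lengths(per_seed) == a))
  # per-draw law: uniform over all K (tree, outcome) pairs
  draw <- dist_aggregate(unlist(per_seed, use.names = FALSE),
                         rep(1 / K, K))
  tot <- draw
  if (k >= 2L) for (j in 2:k) tot <- dist_convolve(tot, draw)
  support <- tot$values / n
  probs <- tot$probs
  mu <- sum(support * probs)
  structure(
    list(per_seed_supports = per_seed, per_tree_count = a, total_count = K,
         support = support, probs = probs,
         mean = mu, variance = sum((support - mu)^2 * probs),
         estimator = estimator, design = d),
    class = "exact_boot_dist"
  )
}

#' @export
print.exact_boot_dist <- function(x, ...) {
  cat("exact tree-bootstrap distribution (", x$estimator, "): a = ",
      format(x$per_tree_count, scientific = FALSE), " resampled trees/seed, K = ",
      format(x$total_count, scientific = FALSE), " outcomes\n", sep = "")
  cat("  mean", format(x$mean, digits = 8), " variance",
      format(x$variance, digits = 8), " support size",
      length(x$support), "\n")
  invisible(x)
}
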