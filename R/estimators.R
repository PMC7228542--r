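#' @title RDS point estimators
#' @description
#' Three estimators of the population trait prevalence from a recruitment
#' forest: the plain sample mean (unbiased for the degree-weighted mean
#' `mu = sum_i x(i) pi_i`), the inverse-probability-weighted
#' Horvitz--Thompson estimator (unbiased for the true mean `mu0`, but
#' requiring the total-degree normalizing constant), and the
#' Volz--Heckathorn ratio (Hajek) estimator, which self-normalizes.
#' @name rds-estimators
NULL

new_estimate <- function(name, value, normalizer = NA_real_) {
  structure(list(estimator = name, value = value, normalizer = normalizer),
            class = "rds_estimate")
}

#' @export
print.rds_estimate <- function(x, ...) {
  cat(x$estimator, "estimate:", format(x$value, digits = 6))
  if (!is.na(x$normalizer)) {
    cat("  (normalizer", format(x$normalizer, digits = 6), ")")
  }
  cat("\n")
  invisible(x)
}

#' Sample mean of a recruitment forest
#'
#' `Xbar_n = (1/n) sum_s X_s` over all `n` sampled nodes.
#'
#' @param forest a `"recruitment_forest"`
#' @return an `"rds_estimate"` with `value` in `[0, 1]`
#' @export
sample_mean <- function(forest) {
  stopifnot(inherits(forest, "recruitment_forest"))
  if (nrow(forest$nodes) == 0L) stop("empty forest")
  new_estimate("sample_mean", mean(forest$nodes$trait))
}

#' Inverse-probability-weighted (Horvitz--Thompson) estimator
#'
#' `mu_hat_IPW = (sum_j deg(j) / (n N)) * sum_s X_s / deg(W_s)`.  The
#' total-degree normalizer is generally unknown in the field; here it is a
#' required argument (known-normalizer regime) and no attempt is made to
#' estimate it.
#'
#' @param forest a `"recruitment_forest"` with positive reported degrees.
#' @param total_degree `sum_j deg(j)` over the whole population.
#' @param population_size `N`.
#' @return an `"rds_estimate"`; `normalizer` holds `total_degree`.
#' @export
ipw_estimate <- function(forest, total_degree, population_size) {
  stopifnot(inherits(forest, "recruitment_forest"))
  nd <- forest$nodes
  if (nrow(nd) == 0L) stop("empty forest")
  if (any(is.na(nd$degree)) || any(nd$degree <= 0)) {
    stop("every node needs a positive reported degree")
  }
  if (!is.numeric(total_degree) || total_degree <= 0) {
    stop("total_degree must be positive")
  }
  n <- nrow(nd)
  value <- total_degree / (n * population_size) * sum(nd$trait / nd$degree)
  new_estimate("ipw", value, normalizer = total_degree)
}

#' Volz--Heckathorn (Hajek) estimator
#'
#' The ratio of Horvitz--Thompson sums
#' `sum_s X_s/deg_s / sum_s 1/deg_s`, equivalently `(1/(nH)) sum_s X_s/deg_s`
#' with `H = (1/n) sum_s 1/deg_s` the harmonic normalizer.  The degree used
#' is that of the sampled member (the participant's reported network size).
#'
#' @param forest a `"recruitment_forest"` with positive reported degrees.
#' @return an `"rds_estimate"`; `normalizer` holds `H`.
#' @export
vh_estimate <- function(forest) {
  stopifnot(inherits(forest, "recruitment_forest"))
  nd <- forest$nodes
  if (nrow(nd) == 0L) stop("empty forest")
  if (any(is.na(nd$degree)) || any(nd$degree <= 0)) {
    stop("every node needs a positive reported degree")
  }
  H <- mean(1 / nd$degree)
  value <- sum(nd$trait / nd$degree) / sum(1 / nd$degree)
  new_estimate("volz_heckathorn", value, normalizer = H)
}

#' Inverse-probability trait transform
#'
#' `x_pi = x / (pi * N)`: the per-observation relabelling under which the
#' plain sample mean of the transformed values is exactly the IPW
#' estimator.  Vectorized over its arguments.
#'
#' @param trait binary trait value(s).
#' @param sampling_prob stationary sampling probability `pi` (> 0).
#' @param population_size `N`.
#' @return transformed value(s)
#' @export
pi_transform <- function(trait, sampling_prob, population_size) {
  if (any(sampling_prob <= 0)) stop("sampling probabilities must be positive")
  trait / (sampling_prob * population_size)
}

# Per-node values whose plain mean reproduces a linear estimator; used by
# exact enumeration and the vectorized bootstrap.
estimator_node_values <- function(forest, estimator,
                                  total_degree = NULL,
                                  population_size = NULL) {
  nd <- forest$nodes
  switch(estimator,
    sample_mean = as.numeric(nd$trait),
    ipw = {
      if (is.null(total_degree) || is.null(population_size)) {
        stop("ipw needs total_degree and population_size")
      }
      total_degree * nd$trait / (population_size * nd$degree)
    },
    stop("unknown or non-linear estimator: ", estimator)
  )
}
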