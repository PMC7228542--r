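#' Construct a hidden population graph
#'
#' The population graph `G` holds the hidden population: vertices are
#' population members, undirected edges are referral ties, and each vertex
#' carries a binary trait (e.g. HIV status).  The graph is simple: no
#' self-loops and no multi-edges, since a self-referral is not an RDS
#' referral.
#'
#' @param edges two-column matrix (or data frame) of undirected edges,
#'   1-based vertex ids.  Each row is an unordered pair; duplicates and
#'   reversed copies are collapsed.
#' @param trait integer vector of per-vertex binary traits, values in
#'   `{0, 1}`.  Its length fixes the number of vertices `N`.
#' @param block optional integer vector of per-vertex block labels.
#' @param num_vertices number of vertices; defaults to `length(trait)`.
#'
#' @return An object of class `"population_graph"` with fields
#'   `igraph` (the underlying [igraph][igraph::graph_from_edgelist] object),
#'   `trait`, `block` and `num_vertices`.
#' @export
#' @examples
#' g <- population_graph(rbind(c(1, 2), c(2, 3), c(1, 3)), trait = c(1, 0, 1))
#' stationary_distribution(g)
population_graph <- function(edges, trait, block = NULL,
                             num_vertices = length(trait)) {
  n <- as.integer(num_vertices)
  if (n < 1L) stop("population graph needs at least one vertex")
  trait <- as.integer(trait)
  if (length(trait) != n) stop("trait vector must have one entry per vertex")
  if (!all(trait %in% c(0L, 1L))) stop("trait values must be 0 or 1")
  if (!is.null(block)) {
    block <- as.integer(block)
    if (length(block) != n) stop("block vector must have one entry per vertex")
  }
  em <- as.matrix(edges)
  if (length(em) == 0L) {
    em <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(em) != 2L) stop("edges must be a two-column matrix")
  storage.mode(em) <- "integer"
  if (any(is.na(em)) || any(em < 1L) || any(em > n)) {
    stop("edge endpoints must be vertex ids in 1..", n)
  }
  if (any(em[, 1L] == em[, 2L])) stop("self-loops are not allowed")
  # canonical unordered form, drop duplicates
  em <- cbind(pmin(em[, 1L], em[, 2L]), pmax(em[, 1L], em[, 2L]))
  em <- unique(em)
  ig <- igraph::graph_from_edgelist(em, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  structure(
    list(igraph = ig, trait = trait, block = block, num_vertices = n),
    class = "population_graph"
  )
}

#' @export
print.population_graph <- function(x, ...) {
  cat("population_graph:", x$num_vertices, "vertices,",
      igraph::ecount(x$igraph), "edges; trait prevalence",
      format(mean(x$trait), digits = 4), "\n")
  if (!is.null(x$block)) {
    cat("  blocks:", paste(table(x$block), collapse = "/"), "\n")
  }
  invisible(x)
}

#' Per-vertex degrees of a population graph
#' @param graph a [population_graph()]
#' @return integer vector of degrees
#' @export
graph_degrees <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  as.integer(igraph::degree(graph$igraph))
}

#' True population mean of the binary trait
#'
#' `mu0 = (1/N) sum_i x(i)`, the quantity RDS studies ultimately target.
#' @param graph a [population_graph()]
#' @return scalar in `[0, 1]`
#' @export
population_mean <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  mean(graph$trait)
}

#' Degree-weighted population mean
#'
#' `mu = sum_i x(i) pi_i` with `pi` the stationary (degree-proportional)
#' sampling probabilities: the quantity the plain sample mean of an RDS
#' sample is unbiased for.
#' @param graph a connected [population_graph()]
#' @return scalar in `[0, 1]`
#' @export
degree_weighted_mean <- function(graph) {
  sum(graph$trait * stationary_distribution(graph))
}

check_connected <- function(graph, what = "this operation") {
  if (!igraph::is_connected(graph$igraph)) {
    stop("population graph is disconnected; ", what,
         " requires a connected graph", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stochastic block model parameters
#'
#' The model has `2K` equal-sized blocks; edges appear independently with
#' probability `p_within` inside a block and `r_between` across blocks.
#'
#' @param half_blocks `K`; the model has `2K` blocks.
#' @param block_size vertices per block, so `N = 2K * block_size`.
#' @param p_within within-block edge probability `p`.
#' @param r_between between-block edge probability `r`.
#' @return object of class `"sbm_params"`
#' @export
sbm_params <- function(half_blocks, block_size, p_within, r_between) {
  half_blocks <- as.integer(half_blocks)
  block_size <- as.integer(block_size)
  if (half_blocks < 1L) stop("half_blocks must be a positive integer")
  if (block_size < 1L) stop("block_size must be a positive integer")
  for (prob in c(p_within, r_between)) {
    if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
        prob < 0 || prob > 1) {
      stop("p_within and r_between must be probabilities in [0, 1]")
    }
  }
  structure(
    list(half_blocks = half_blocks, block_size = block_size,
         p_within = p_within, r_between = r_between),
    class = "sbm_params"
  )
}

#' Generate a stochastic-block-model population graph
#'
#' Draws a simple undirected graph with `2K` blocks of `block_size` vertices
#' each; each within-block pair is an edge independently with probability
#' `p_within`, each between-block pair with probability `r_between`.  Traits
#' are assigned by block (outcomes symmetric and related to block
#' membership), by default 1 for the first `K` blocks and 0 for the rest.
#'
#' @param params an [sbm_params()] object.
#' @param trait_rule either a function mapping a block label `1..2K` to a
#'   trait in `{0,1}`, a vector of length `2K` of per-block traits, or a
#'   vector of length `N` of per-vertex traits (the general override).
#'   `NULL` uses the symmetric default.
#' @param rng_seed optional integer seed for reproducibility.
#' @param require_connected if `TRUE`, redraw (up to `max_tries` times)
#'   until the realized graph is connected; error if the cap is hit.
#' @param max_tries retry cap for `require_connected`.
#' @return a [population_graph()] with block labels attached.
#' @export
make_sbm <- function(params, trait_rule = NULL, rng_seed = NULL,
                     require_connected = FALSE, max_tries = 100L) {
  stopifnot(inherits(params, "sbm_params"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  K <- params$half_blocks
  nb <- 2L * K
  bs <- params$block_size
  n <- nb * bs
  block <- rep(seq_len(nb), each = bs)
  trait <- resolve_trait_rule(trait_rule, K, nb, n, block)
  pm <- matrix(params$r_between, nb, nb)
  diag(pm) <- params$p_within
  for (try in seq_len(max_tries)) {
    ig <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = rep(bs, nb))
    if (!require_connected || igraph::is_connected(ig)) {
      em <- igraph::as_edgelist(ig, names = FALSE)
      return(population_graph(em, trait = trait, block = block,
                              num_vertices = n))
    }
  }
  stop("no connected SBM draw in ", max_tries, " tries; ",
       "increase edge probabilities or max_tries")
}

resolve_trait_rule <- function(trait_rule, K, nb, n, block) {
  if (is.null(trait_rule)) {
    return(as.integer(block <= K))
  }
  if (is.function(trait_rule)) {
    per_block <- vapply(seq_len(nb), function(b) as.integer(trait_rule(b)),
                        integer(1))
    return(per_block[block])
  }
  tv <- as.integer(trait_rule)
  if (length(tv) == nb) return(tv[block])
  if (length(tv) == n) return(tv)
  stop("trait_rule must be a function, a length-2K block vector, ",
       "or a length-N vertex vector")
}

#' Random-walk transition kernel of a population graph
#'
#' The recruitment process is Markov with transition matrix `P` where
#' `P[i, j] = 1/deg(i)` if `{i, j}` is an edge and 0 otherwise: each
#' recruit is a uniformly chosen contact of the recruiter.
#'
#' @param graph a [population_graph()]; every vertex must have degree >= 1.
#' @return an `N x N` row-stochastic matrix.
#' @export
transition_kernel <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  deg <- graph_degrees(graph)
  if (any(deg == 0L)) {
    stop("isolated vertex (degree 0) at id ", which(deg == 0L)[1L],
         "; the walk kernel is undefined there")
  }
  A <- as.matrix(igraph::as_adjacency_matrix(graph$igraph, sparse = TRUE))
  A / deg
}

#' Stationary distribution of the recruitment walk
#'
#' Individuals are recruited with probability proportional to degree:
#' `pi_i = deg(i) / sum_j deg(j)`.  Requires a connected graph so the
#' stationary distribution is unique.
#'
#' @param graph a connected [population_graph()]
#' @return numeric vector summing to 1
#' @export
stationary_distribution <- function(graph) {
  stopifnot(inherits(graph, "population_graph"))
  check_connected(graph, "the stationary distribution")
  deg <- graph_degrees(graph)
  deg / sum(deg)
}

#' Within-block relative connection strength of an SBM
#'
#' `p~ = p / {p + r (K - 1)}`, the quantity governing whether the tree
#' CLT holds for block-symmetric outcomes.  Note the formula degenerates
#' to 1 when `K = 1` regardless of `p` and `r`; it is computed exactly as
#' defined, without adjustment.
#'
#' @param params an [sbm_params()]
#' @return scalar in `[0, 1]`
#' @export
tilde_p <- function(params) {
  stopifnot(inherits(params, "sbm_params"))
  denom <- params$p_within + params$r_between * (params$half_blocks - 1L)
  if (denom <= 0) stop("tilde_p undefined: p + r(K-1) must be positive")
  params$p_within / denom
}

#' Is an SBM below the critical recruitment threshold?
#'
#' Returns `TRUE` iff `1/(2K) < p~ < 1/(2K) + 1/(2*sqrt(2))` with both
#' inequalities strict.  Below this threshold the tree-structured sample
#' mean satisfies a central limit theorem; at or beyond it the design
#' effect is unbounded and no such guarantee holds.
#'
#' @param params an [sbm_params()]
#' @return logical scalar
#' @export
below_threshold <- function(params) {
  pt <- tilde_p(params)
  lo <- 1 / (2 * params$half_blocks)
  hi <- lo + 1 / (2 * sqrt(2))
  pt > lo && pt < hi
}
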