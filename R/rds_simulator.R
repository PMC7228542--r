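#' Recruitment forest design
#'
#' A design fixes the shape of the observed sample: `k` seeds, each the
#' root of a complete `m`-ary recruitment tree of height `h`.  Each tree
#' then has `l = (m^(h+1) - 1)/(m - 1)` nodes (`h + 1` when `m = 1`) and
#' the total sample size is `n = k * l`.
#'
#' @param num_seeds number of seeds `k` (positive integer).
#' @param branching coupons per participant `m` (positive integer).
#' @param height recruitment waves beyond the seeds `h` (non-negative).
#' @return object of class `"forest_design"` with fields `num_seeds`,
#'   `branching`, `height`.
#' @export
#' @examples
#' d <- forest_design(num_seeds = 3, branching = 2, height = 2)
#' tree_size(d)      # 7
#' forest_size(d)    # 21
forest_design <- function(num_seeds, branching, height) {
  k <- as.integer(num_seeds)
  m <- as.integer(branching)
  h <- as.integer(height)
  if (is.na(k) || k < 1L) stop("num_seeds must be a positive integer")
  if (is.na(m) || m < 1L) stop("branching must be a positive integer (m >= 1)")
  if (is.na(h) || h < 0L) stop("height must be a non-negative integer")
  structure(list(num_seeds = k, branching = m, height = h),
            class = "forest_design")
}

#' @export
print.forest_design <- function(x, ...) {
  cat("forest_design: k =", x$num_seeds, "seeds, m =", x$branching,
      "coupons, height h =", x$height,
      "(l =", tree_size(x), ", n =", forest_size(x), ")\n")
  invisible(x)
}

#' Nodes per recruitment tree
#'
#' Closed form `l = (m^(h+1) - 1)/(m - 1)`, with the `m = 1` limit `h + 1`.
#' @param design a [forest_design()]
#' @return positive integer `l`
#' @export
tree_size <- function(design) {
  stopifnot(inherits(design, "forest_design"))
  m <- design$branching
  h <- design$height
  l <- if (m == 1L) h + 1 else (m^(h + 1) - 1) / (m - 1)
  if (l > .Machine$integer.max) stop("tree size overflows integer range")
  as.integer(round(l))
}

#' Total sample size of a design
#' @param design a [forest_design()]
#' @return `n = k * l`
#' @export
forest_size <- function(design) {
  design$num_seeds * tree_size(design)
}

# Canonical node layout: trees consecutive; within a tree, nodes in wave
# (breadth-first) order; the children of the t-th wave-w node are the
# ((t-1)m+1)..(tm)-th wave-(w+1) nodes.  All forests the package builds
# are stored in this order, so node index == slot index.
design_slots <- function(design) {
  k <- design$num_seeds
  m <- design$branching
  h <- design$height
  l <- tree_size(design)
  per_wave <- m^(0:h)
  wave1 <- rep.int(0:h, per_wave)
  start <- cumsum(c(1, per_wave))          # start[w+1] = first node of wave w
  parent1 <- rep(NA_integer_, l)
  if (h >= 1L) {
    for (w in 1:h) {
      idx <- start[w + 1]:(start[w + 2] - 1)
      within <- seq_along(idx)
      parent1[idx] <- start[w] + (within - 1L) %/% m
    }
  }
  n <- k * l
  offset <- rep((seq_len(k) - 1L) * l, each = l)
  data.frame(
    node = seq_len(n),
    tree = rep(seq_len(k), each = l),
    wave = rep.int(wave1, k),
    parent = rep.int(parent1, k) + ifelse(is.na(rep.int(parent1, k)), 0L, offset)
  )
}

# Build a recruitment_forest from canonical-order per-node vectors.
new_forest <- function(design, member, trait, degree) {
  slots <- design_slots(design)
  n <- nrow(slots)
  stopifnot(length(trait) == n, length(degree) == n)
  if (is.null(member)) member <- rep(NA_integer_, n)
  nodes <- data.frame(
    node = slots$node, tree = slots$tree, wave = slots$wave,
    parent = slots$parent,
    member = as.integer(member),
    trait = as.integer(trait),
    degree = as.numeric(degree)
  )
  structure(list(design = design, nodes = nodes),
            class = "recruitment_forest")
}

#' Construct a recruitment forest from per-node data
#'
#' Builds a forest in the package's canonical breadth-first node order
#' (trees consecutive; within each tree, wave by wave, children of the
#' t-th node of a wave occupying consecutive slots of the next wave).
#' Mainly useful for fixtures and for forests observed without the
#' underlying graph.
#'
#' @param design a [forest_design()]
#' @param trait per-node binary traits, canonical order.
#' @param degree per-node reported degrees (positive), canonical order.
#' @param member optional per-node population vertex ids.
#' @return a `"recruitment_forest"`
#' @export
make_forest <- function(design, trait, degree, member = NULL) {
  f <- new_forest(design, member, trait, degree)
  validate_forest(f)
  f
}

#' @export
print.recruitment_forest <- function(x, ...) {
  d <- x$design
  cat("recruitment_forest: k =", d$num_seeds, ", m =", d$branching,
      ", h =", d$height, "; n =", nrow(x$nodes),
      "nodes; sample trait mean", format(mean(x$nodes$trait), digits = 4), "\n")
  invisible(x)
}

#' Validate a recruitment forest
#'
#' Checks every structural invariant: canonical complete `m`-ary shape
#' (exactly `k` parentless wave-0 roots, every internal node with `m`
#' children, leaves exactly at wave `h`), node count `n = k l`, traits in
#' `{0,1}`, positive degrees; and, when the source graph is supplied, that
#' every recruiter--recruit pair is an edge of the graph and every node's
#' trait and degree match the graph's values for its member.
#'
#' @param forest a `"recruitment_forest"`
#' @param graph optional source [population_graph()]
#' @return `forest`, invisibly; errors describe the first violated invariant.
#' @export
validate_forest <- function(forest, graph = NULL) {
  if (!inherits(forest, "recruitment_forest")) {
    stop("not a recruitment_forest")
  }
  d <- forest$design
  nd <- forest$nodes
  slots <- design_slots(d)
  if (nrow(nd) != nrow(slots)) {
    stop("forest has ", nrow(nd), " nodes but the design implies ",
         nrow(slots))
  }
  same <- identical(nd$tree, slots$tree) &&
    identical(nd$wave, slots$wave) &&
    identical(nd$parent, slots$parent)
  if (!same) stop("forest nodes are not in canonical complete m-ary layout")
  if (!all(nd$trait %in% c(0L, 1L))) {
    bad <- which(!nd$trait %in% c(0L, 1L))[1L]
    stop("trait outside {0,1} at node ", bad)
  }
  if (any(!is.na(nd$degree) & nd$degree <= 0)) {
    bad <- which(nd$degree <= 0)[1L]
    stop("non-positive degree at node ", bad)
  }
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "population_graph"))
    if (any(is.na(nd$member))) stop("forest has nodes with unknown members")
    deg <- graph_degrees(graph)
    if (!all(nd$trait == graph$trait[nd$member])) {
      stop("node trait disagrees with the graph trait of its member")
    }
    if (!all(nd$degree == deg[nd$member])) {
      stop("node degree disagrees with the graph degree of its member")
    }
    nonroot <- which(!is.na(nd$parent))
    if (length(nonroot)) {
      pm <- nd$member[nd$parent[nonroot]]
      cm <- nd$member[nonroot]
      ok <- igraph::are_adjacent
      connected <- mapply(function(a, b) ok(graph$igraph, a, b), pm, cm)
      if (!all(connected)) {
        bad <- nonroot[which(!connected)[1L]]
        stop("recruiter-recruit pair at node ", bad,
             " is not an edge of the population graph")
      }
    }
  }
  invisible(forest)
}

# Flat adjacency arrays for fast vectorized neighbour sampling.
graph_adjacency <- function(graph) {
  adj <- igraph::as_adj_list(graph$igraph)
  deg <- lengths(adj)
  flat <- as.integer(unlist(adj, use.names = FALSE))
  offset <- c(0L, cumsum(deg))[seq_along(deg)]
  list(flat = flat, offset = offset, deg = as.integer(deg))
}

#' Simulate a respondent-driven sample
#'
#' Runs the RDS process as a Markov walk indexed by the recruitment
#' forest: the `k` seed members are drawn independently from the
#' stationary (degree-proportional) distribution, and each recruit's
#' member is drawn uniformly among its recruiter's contacts, independently
#' for each of the `m` coupons and with replacement (the same contact may
#' be recruited several times).  Traits and degrees are copied from the
#' graph onto the sampled nodes, so downstream estimation uses the sample
#' alone.
#'
#' @param graph a connected [population_graph()]
#' @param design a [forest_design()]
#' @param rng_seed optional integer seed; `NULL` uses the current RNG state.
#' @param seed_members optional vector of `k` vertex ids to use as seed
#'   members (convenience-seed mode for realism studies) instead of
#'   stationary draws.
#' @return a `"recruitment_forest"` with `n = k l` nodes.
#' @export
simulate_forest <- function(graph, design, rng_seed = NULL,
                            seed_members = NULL) {
  stopifnot(inherits(graph, "population_graph"),
            inherits(design, "forest_design"))
  check_connected(graph, "RDS simulation")
  if (!is.null(rng_seed)) set.seed(rng_seed)
  k <- design$num_seeds
  h <- design$height
  slots <- design_slots(design)
  n <- nrow(slots)
  pi <- stationary_distribution(graph)
  adj <- graph_adjacency(graph)
  member <- integer(n)
  roots <- which(slots$wave == 0L)
  if (is.null(seed_members)) {
    member[roots] <- sample.int(graph$num_vertices, k, replace = TRUE,
                                prob = pi)
  } else {
    seed_members <- as.integer(seed_members)
    if (length(seed_members) != k) stop("need exactly k seed members")
    member[roots] <- seed_members
  }
  if (h >= 1L) {
    for (w in 1:h) {
      idx <- which(slots$wave == w)
      pm <- member[slots$parent[idx]]
      d <- adj$deg[pm]
      pick <- sample_uniform_index(d)
      member[idx] <- adj$flat[adj$offset[pm] + pick]
    }
  }
  deg <- graph_degrees(graph)
  new_forest(design, member, graph$trait[member], deg[member])
}

# Vectorized draw of one uniform index in 1..d[i] for each i.
sample_uniform_index <- function(d) {
  pick <- 1L + as.integer(floor(stats::runif(length(d)) * d))
  pmin(pick, d)
}

#' Nodes of a forest at a given wave
#'
#' @param forest a `"recruitment_forest"`
#' @param wave recruitment depth, `0` (seeds) to `h` (final wave).
#' @return the rows of `forest$nodes` at that depth (`k * m^wave` of them).
#' @export
forest_waves <- function(forest, wave) {
  stopifnot(inherits(forest, "recruitment_forest"))
  h <- forest$design$height
  wave <- as.integer(wave)
  if (is.na(wave) || wave < 0L || wave > h) {
    stop("wave must be between 0 and the forest height ", h)
  }
  forest$nodes[forest$nodes$wave == wave, , drop = FALSE]
}

# Children matrix (n x m, NA rows for leaves) and root slots, in canonical
# order.  The workhorse lookup for resampling and enumeration.
forest_structure <- function(forest) {
  d <- forest$design
  slots <- design_slots(d)
  n <- nrow(slots)
  m <- d$branching
  children <- matrix(NA_integer_, n, m)
  nonroot <- which(!is.na(slots$parent))
  if (length(nonroot)) {
    ord <- nonroot  # canonical order: children of a parent are consecutive
    par <- slots$parent[ord]
    slot_within <- sequence(rle(par)$lengths)
    children[cbind(par, slot_within)] <- ord
  }
  list(children = children, roots = which(slots$wave == 0L), slots = slots)
}
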