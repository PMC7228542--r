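#' @title File formats
#' @description
#' Two plain-text formats, fixed so outputs are bit-comparable: a graph as
#' a whitespace-separated edge list (`u v` per line, 0-based vertex ids)
#' with a sidecar vertex CSV `vertex_id,trait,block`; and a recruitment
#' forest as an RDS-data-style CSV with header
#' `node_id,tree_id,wave,parent_id,member_id,trait,degree` (0-based
#' `node_id`/`parent_id`/`member_id`, `parent_id` empty for seeds).
#' @name rds-file-formats
NULL

#' Write a recruitment forest to CSV
#'
#' @param forest a `"recruitment_forest"`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_forest <- function(forest, path) {
  validate_forest(forest)
  nd <- forest$nodes
  out <- data.frame(
    node_id = nd$node - 1L,
    tree_id = nd$tree,
    wave = nd$wave,
    parent_id = ifelse(is.na(nd$parent), "", as.character(nd$parent - 1L)),
    member_id = ifelse(is.na(nd$member), "", as.character(nd$member - 1L)),
    trait = nd$trait,
    degree = nd$degree
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recruitment forest from CSV
#'
#' Infers the design from the data (`k` = number of parentless rows, `h` =
#' maximum wave, `m` = common child count of internal nodes; `m = 1` for a
#' height-0 forest), reorders nodes into the canonical breadth-first
#' layout, and validates every shape invariant, reporting the offending
#' file row on failure.
#'
#' @param path a forest CSV written by [write_forest()] or compatible.
#' @return a `"recruitment_forest"`
#' @export
read_forest <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("node_id", "tree_id", "wave", "parent_id", "member_id",
            "trait", "degree")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("forest file missing columns: ", paste(missing_cols, collapse = ", "))
  }
  nrows <- nrow(raw)
  if (nrows == 0L) stop("forest file has no rows")
  row_of <- function(i) i + 1L  # header line offset for messages
  num <- function(col) suppressWarnings(as.numeric(raw[[col]]))
  node0 <- suppressWarnings(as.integer(raw$node_id))
  if (any(is.na(node0))) {
    stop("bad node_id at file row ", row_of(which(is.na(node0))[1L]))
  }
  if (anyDuplicated(node0)) {
    stop("duplicate node_id at file row ", row_of(anyDuplicated(node0)))
  }
  parent_chr <- trimws(raw$parent_id)
  parent0 <- suppressWarnings(as.integer(parent_chr))
  is_root <- parent_chr == ""
  if (any(!is_root & is.na(parent0))) {
    stop("bad parent_id at file row ", row_of(which(!is_root & is.na(parent0))[1L]))
  }
  # map 0-based ids to row indices
  idx_of <- match(parent0, node0)
  orphan <- which(!is_root & is.na(idx_of))
  if (length(orphan)) {
    stop("orphan parent_id ", parent0[orphan[1L]], " at file row ",
         row_of(orphan[1L]))
  }
  wave <- suppressWarnings(as.integer(raw$wave))
  trait <- suppressWarnings(as.integer(raw$trait))
  degree <- num("degree")
  member_chr <- trimws(raw$member_id)
  member <- suppressWarnings(as.integer(member_chr))
  member[member_chr == ""] <- NA_integer_
  if (any(is.na(wave))) {
    stop("bad wave at file row ", row_of(which(is.na(wave))[1L]))
  }
  bad_tr <- which(is.na(trait) | !(trait %in% c(0L, 1L)))
  if (length(bad_tr)) {
    stop("trait outside {0,1} at file row ", row_of(bad_tr[1L]))
  }
  bad_dg <- which(is.na(degree) | degree <= 0)
  if (length(bad_dg)) {
    stop("non-positive degree at file row ", row_of(bad_dg[1L]))
  }
  if (any(is_root & wave != 0L)) {
    stop("seed with nonzero wave at file row ",
         row_of(which(is_root & wave != 0L)[1L]))
  }
  if (any(!is_root & wave != wave[idx_of] + 1L)) {
    stop("wave not parent wave + 1 at file row ",
         row_of(which(!is_root & wave != wave[idx_of] + 1L)[1L]))
  }
  k <- sum(is_root)
  if (k == 0L) stop("forest file has no seeds (rows with empty parent_id)")
  h <- max(wave)
  # children per internal node must be a common m
  internal <- which(wave < h)
  child_counts <- tabulate(idx_of[!is_root], nbins = nrows)
  if (h == 0L) {
    m <- 1L
  } else {
    counts <- child_counts[internal]
    m <- unique(counts)
    if (length(m) != 1L || m[1L] < 1L) {
      stop("non-m-ary shape: internal nodes have child counts {",
           paste(sort(unique(counts)), collapse = ", "), "}")
    }
    m <- as.integer(m)
    leaf_children <- child_counts[wave == h]
    if (any(leaf_children != 0L)) {
      stop("node beyond declared height at file row ",
           row_of(which(wave == h & child_counts > 0L)[1L]))
    }
  }
  design <- forest_design(k, m, h)
  if (nrows != forest_size(design)) {
    stop("shape error: ", nrows, " rows but k=", k, ", m=", m, ", h=", h,
         " implies n=", forest_size(design))
  }
  # canonical (breadth-first, children by node_id) permutation
  children_by <- split(seq_len(nrows)[!is_root], idx_of[!is_root])
  order_tree <- function(root) {
    out <- integer(0)
    level <- root
    while (length(level)) {
      out <- c(out, level)
      level <- unlist(lapply(level, function(p) {
        ch <- children_by[[as.character(p)]]
        if (is.null(ch)) integer(0) else ch[order(node0[ch])]
      }), use.names = FALSE)
    }
    out
  }
  roots <- which(is_root)
  roots <- roots[order(node0[roots])]
  perm <- unlist(lapply(roots, order_tree), use.names = FALSE)
  f <- new_forest(design, member[perm] + 1L, trait[perm], degree[perm])
  validate_forest(f)
  f
}

#' Write a population graph as edge-list + vertex-table files
#'
#' @param graph a [population_graph()]
#' @param edge_path edge-list file (`u v` per line, 0-based ids).
#' @param vertex_path vertex CSV (`vertex_id,trait,block`).
#' @return invisibly, `c(edge_path, vertex_path)`
#' @export
write_graph_files <- function(graph, edge_path, vertex_path) {
  stopifnot(inherits(graph, "population_graph"))
  em <- igraph::as_edgelist(graph$igraph, names = FALSE)
  writeLines(paste(em[, 1L] - 1L, em[, 2L] - 1L), edge_path)
  vt <- data.frame(
    vertex_id = seq_len(graph$num_vertices) - 1L,
    trait = graph$trait,
    block = if (is.null(graph$block)) "" else graph$block
  )
  utils::write.csv(vt, vertex_path, row.names = FALSE, quote = FALSE)
  invisible(c(edge_path, vertex_path))
}

#' Read a population graph from edge-list + vertex-table files
#'
#' Validates simplicity (no self-loops, duplicates collapsed), id range
#' and binary traits.
#'
#' @param edge_path,vertex_path files as written by [write_graph_files()].
#' @return a [population_graph()]
#' @export
read_graph_files <- function(edge_path, vertex_path) {
  vt <- utils::read.csv(vertex_path, stringsAsFactors = FALSE)
  if (!all(c("vertex_id", "trait") %in% names(vt))) {
    stop("vertex file needs vertex_id and trait columns")
  }
  vt <- vt[order(vt$vertex_id), , drop = FALSE]
  n <- nrow(vt)
  if (!identical(as.integer(vt$vertex_id), seq_len(n) - 1L)) {
    stop("vertex_id must be 0..N-1 with no gaps")
  }
  block <- NULL
  if ("block" %in% names(vt)) {
    bl <- suppressWarnings(as.integer(vt$block))
    if (!all(is.na(bl))) block <- bl
  }
  lines <- readLines(edge_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines)) {
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    if (any(lengths(parts) != 2L)) {
      stop("edge list line ", which(lengths(parts) != 2L)[1L],
           " does not have two vertex ids")
    }
    em <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE) + 1L
  } else {
    em <- matrix(integer(0), ncol = 2L)
  }
  population_graph(em, trait = as.integer(vt$trait), block = block,
                   num_vertices = n)
}

#' Canonical small test forests
#'
#' Deterministic fixtures used throughout the test suite:
#' \describe{
#'   \item{`single_tree_h1`}{`k=1, m=2, h=1`; traits (root, child1, child2)
#'     = (1, 0, 1); degrees (2, 1, 3).  The worked enumeration example:
#'     its exact bootstrap mean law is 1/3, 2/3, 1 with probabilities
#'     1/4, 1/2, 1/4.}
#'   \item{`three_seeds_h0`}{`k=3, m=1, h=0`; traits (1, 0, 0), degrees
#'     (1, 2, 4).  Seed-only: the tree bootstrap is the classical i.i.d.
#'     bootstrap of the three seed values.}
#'   \item{`chain_m1`}{`k=1, m=1, h=3`; traits (1, 0, 0, 1), degrees
#'     (1, 3, 2, 2).  Every resample is forced, so the bootstrap is the
#'     identity map.}
#'   \item{`two_trees_h2`}{`k=2, m=2, h=2`; 14 nodes with alternating
#'     traits and degrees 1..7 in each tree.}
#' }
#'
#' @param name one of the fixture names above.
#' @return a `"recruitment_forest"`
#' @export
fixture_forest <- function(name = c("single_tree_h1", "three_seeds_h0",
                                    "chain_m1", "two_trees_h2")) {
  name <- match.arg(name)
  switch(name,
    single_tree_h1 = make_forest(forest_design(1L, 2L, 1L),
                                 trait = c(1L, 0L, 1L),
                                 degree = c(2, 1, 3)),
    three_seeds_h0 = make_forest(forest_design(3L, 1L, 0L),
                                 trait = c(1L, 0L, 0L),
                                 degree = c(1, 2, 4)),
    chain_m1 = make_forest(forest_design(1L, 1L, 3L),
                           trait = c(1L, 0L, 0L, 1L),
                           degree = c(1, 3, 2, 2)),
    two_trees_h2 = make_forest(forest_design(2L, 2L, 2L),
                               trait = rep(c(1L, 0L, 1L, 1L, 0L, 0L, 1L), 2L),
                               degree = rep(1:7, 2L))
  )
}
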