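#' Construct a signed weighted graph from an edge table
#'
#' A signed graph is an undirected weighted network whose edge weights carry
#' meaningful positive and negative signs, e.g. co-occurrence vs mutual
#' exclusion in a microbial association network. The constructor takes a data
#' frame of edges, canonicalises it (undirected pairs, deterministic node
#' order) and validates the invariants the clustering algorithm relies on:
#' no self-loops, at most one edge per pair, finite nonzero weights.
#'
#' Zero-weight edges are dropped with a warning (a zero carries no sign
#' information). Self-loops are dropped with a warning; the diffusion uses the
#' matrix diagonal for its own bookkeeping. Duplicate edges with equal weight
#' (within 1e-9) are merged silently; duplicates with unequal weight are an
#' error naming the pair, because silently averaging could flip a sign.
#'
#' @param edges data frame with columns `from`, `to`, `weight` (the first two
#'   coerced to character, the third numeric). Extra columns are ignored.
#' @param nodes optional character vector of node identifiers; nodes without
#'   edges may be listed here. Defaults to the nodes seen in `edges`.
#' @param node_attrs optional data frame of per-node attributes with a `node`
#'   column.
#' @return An object of class `signed_graph`: a list with `nodes` (sorted
#'   character vector), `edges` (tibble `from`, `to`, `weight` with
#'   `from < to`), and `node_attrs` (tibble).
#' @examples
#' g <- signed_graph(data.frame(
#'   from = c("A", "B", "A"), to = c("B", "C", "C"),
#'   weight = c(1, -0.5, 0.7)
#' ))
#' g
#' @export
signed_graph <- function(edges, nodes = NULL, node_attrs = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0 && !all(c("from", "to", "weight") %in% names(edges))) {
    # tolerate positional 3-column tables
    if (ncol(edges) >= 3) {
      names(edges)[1:3] <- c("from", "to", "weight")
    } else {
      stop("`edges` must have columns from, to, weight", call. = FALSE)
    }
  }
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  }
  edges <- tibble::as_tibble(edges[, c("from", "to", "weight")])
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)

  if (any(!is.finite(edges$weight))) {
    stop("edge weights must be finite numbers", call. = FALSE)
  }
  nz <- edges$weight != 0
  if (any(!nz)) {
    warning(sprintf("dropping %d zero-weight edge(s): no sign information",
                    sum(!nz)), call. = FALSE)
    edges <- edges[nz, ]
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)), call. = FALSE)
    edges <- edges[!loops, ]
  }

  # canonical unordered pairs: from < to
  swap <- edges$from > edges$to
  if (any(swap)) {
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }

  key <- paste(edges$from, edges$to, sep = "\r")
  if (anyDuplicated(key)) {
    rng <- tapply(edges$weight, key, function(w) diff(range(w)))
    bad <- names(rng)[rng > 1e-9]
    if (length(bad) > 0) {
      pair <- strsplit(bad[1], "\r", fixed = TRUE)[[1]]
      stop(sprintf(
        "conflicting duplicate edge %s -- %s: weights disagree; refusing to average",
        pair[1], pair[2]), call. = FALSE)
    }
    edges <- edges[!duplicated(key), ]
  }

  node_set <- sort(unique(c(edges$from, edges$to, as.character(nodes))))
  edges <- edges[order(edges$from, edges$to), ]

  if (is.null(node_attrs)) {
    node_attrs <- tibble::tibble(node = node_set)
  } else {
    node_attrs <- tibble::as_tibble(node_attrs)
    stopifnot("node" %in% names(node_attrs))
    node_attrs$node <- as.character(node_attrs$node)
    node_attrs <- dplyr::left_join(tibble::tibble(node = node_set),
                                   node_attrs, by = "node")
  }

  structure(
    list(nodes = node_set, edges = edges, node_attrs = node_attrs),
    class = "signed_graph"
  )
}

#' @export
print.signed_graph <- function(x, ...) {
  npos <- sum(x$edges$weight > 0)
  nneg <- sum(x$edges$weight < 0)
  cat(sprintf("<signed_graph> %d nodes, %d edges (%d positive, %d negative)\n",
              length(x$nodes), nrow(x$edges), npos, nneg))
  invisible(x)
}

#' @export
format.signed_graph <- function(x, ...) {
  sprintf("<signed_graph: %d nodes, %d edges>", length(x$nodes), nrow(x$edges))
}

is_signed_graph <- function(x) inherits(x, "signed_graph")

n_nodes <- function(g) length(g$nodes)
n_edges <- function(g) nrow(g$edges)

#' Weighted adjacency matrix of a signed graph
#'
#' Dense symmetric matrix with zero diagonal, rows and columns indexed by the
#' graph's sorted node identifiers so that matrix positions are reproducible.
#'
#' @param g a `signed_graph`.
#' @return numeric matrix, `dimnames` set to the node identifiers.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(is_signed_graph(g))
  n <- n_nodes(g)
  m <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  if (n_edges(g) > 0) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    m[cbind(i, j)] <- g$edges$weight
    m[cbind(j, i)] <- g$edges$weight
  }
  m
}

#' Replace edge weights by their signs
#'
#' Maps every edge weight to -1 or +1 according to its sign, leaving the
#' topology untouched. Used when only the inferred sign of an association is
#' trusted, not its magnitude.
#'
#' @param g a `signed_graph`.
#' @return a `signed_graph` with all weights in \{-1, +1\}.
#' @export
binarize_weights <- function(g) {
  stopifnot(is_signed_graph(g))
  g$edges$weight <- sign(g$edges$weight)
  g
}

#' Tidy edge table of a signed graph
#'
#' @param x a `signed_graph`.
#' @param ... unused.
#' @return tibble with columns `from`, `to`, `weight`, `sign`.
#' @method tidy signed_graph
#' @export
tidy.signed_graph <- function(x, ...) {
  dplyr::mutate(x$edges, sign = sign(.data$weight))
}

# internal: igraph view (topology + weights), vertex order == g$nodes
as_igraph <- function(g) {
  ig <- igraph::make_empty_graph(n = n_nodes(g), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$nodes)
  if (n_edges(g) > 0) {
    idx <- rbind(match(g$edges$from, g$nodes), match(g$edges$to, g$nodes))
    ig <- igraph::add_edges(ig, as.vector(idx))
    ig <- igraph::set_edge_attr(ig, "weight", value = g$edges$weight)
  }
  ig
}

# internal: induced subgraph on a node subset (names), keeping class invariants
subgraph_nodes <- function(g, keep) {
  keep <- sort(unique(keep))
  e <- g$edges[g$edges$from %in% keep & g$edges$to %in% keep, ]
  signed_graph(e, nodes = keep)
}
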