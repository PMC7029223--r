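#' Clustering parameters
#'
#' @param min_clusters,max_clusters range of cluster numbers searched by the
#'   sparsity criterion. Defaults 2 and 4: the algorithm tends to produce a
#'   small number of clusters separated by weakly assigned nodes.
#' @param minsize fraction of the node count below which a cluster counts as
#'   "small" and is dissolved and reassigned. Default 0.1; 0 disables the
#'   step.
#' @return list of class `clustering_params`.
#' @export
clustering_params <- function(min_clusters = 2, max_clusters = 4,
                              minsize = 0.1) {
  stopifnot(min_clusters >= 2, min_clusters <= max_clusters,
            minsize >= 0, minsize < 0.5)
  structure(list(min_clusters = as.integer(min_clusters),
                 max_clusters = as.integer(max_clusters),
                 minsize = minsize),
            class = "clustering_params")
}

#' Sparsity score of a cluster assignment
#'
#' Edge-sign bookkeeping statistic in \[-1, 1\] that rewards positive
#' intracluster and negative intercluster edges:
#' \deqn{s = \frac{1}{|N|}\left[|e_{w<0} \notin C| + |e_{w>0} \in C|
#'       - |e_{w<0} \in C| - |e_{w>0} \notin C|\right]}
#' where \eqn{C} is the set of intracluster edges and \eqn{N} all edges. The
#' worst possible assignment (all negative edges inside clusters, all positive
#' edges cut) scores -1; the mirror-image best case scores +1. This is the
#' criterion used to choose the cluster number.
#'
#' @param g a `signed_graph`.
#' @param membership data frame with columns `node`, `cluster` (or a named
#'   vector of cluster ids), covering every node incident to an edge.
#' @return the sparsity score, a real in \[-1, 1\].
#' @export
sparsity_score <- function(g, membership) {
  stopifnot(is_signed_graph(g))
  if (n_edges(g) == 0) {
    stop("sparsity score undefined on an edgeless graph", call. = FALSE)
  }
  memb <- membership_vector(membership)
  touched <- unique(c(g$edges$from, g$edges$to))
  if (!all(touched %in% names(memb))) {
    stop("membership must cover all nodes incident to edges", call. = FALSE)
  }
  inside <- memb[g$edges$from] == memb[g$edges$to]
  pos <- g$edges$weight > 0
  (sum(!pos & !inside) + sum(pos & inside) -
     sum(!pos & inside) - sum(pos & !inside)) / n_edges(g)
}

membership_vector <- function(membership) {
  if (is.data.frame(membership)) {
    stats::setNames(membership$cluster, as.character(membership$node))
  } else if (!is.null(names(membership))) {
    membership
  } else {
    stop("membership must be a node/cluster data frame or a named vector",
         call. = FALSE)
  }
}

#' Cut the scoring matrix into k clusters by Ward agglomeration
#'
#' Rows of the scoring matrix are the observations; pairwise Euclidean
#' distances are clustered with Ward's minimum-variance linkage (`ward.D2`,
#' the Euclidean-distance Ward variant) and the dendrogram is cut at `k`.
#' Cluster ids are relabelled canonically: 0..k-1 by decreasing cluster size,
#' ties broken by the lexicographically smallest member, so output is stable
#' across runs and node permutations.
#'
#' @param m a `scoring_matrix` or a plain numeric matrix with node dimnames.
#' @param k number of clusters, at most the node count.
#' @return tibble with columns `node`, `cluster`.
#' @export
agglomerate <- function(m, k) {
  vals <- if (inherits(m, "scoring_matrix")) m$values else m
  stopifnot(is.matrix(vals), !is.null(rownames(vals)))
  if (k > nrow(vals)) {
    stop("k = ", k, " exceeds node count ", nrow(vals), call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(vals, method = "euclidean"),
                      method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  canonical_labels(tibble::tibble(node = rownames(vals),
                                  cluster = as.integer(raw)))
}

# relabel clusters 0..k-1 by decreasing size, ties by smallest member
canonical_labels <- function(memb) {
  stats_tbl <- memb |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(), first = min(.data$node)) |>
    dplyr::arrange(dplyr::desc(.data$size), .data$first)
  remap <- stats::setNames(seq_len(nrow(stats_tbl)) - 1L, stats_tbl$cluster)
  memb$cluster <- unname(remap[as.character(memb$cluster)])
  memb[order(memb$node), ]
}

#' Choose the cluster assignment maximizing the sparsity score
#'
#' Evaluates every cluster number in `min_clusters..max_clusters` (capped at
#' the node count), scores each Ward cut with [sparsity_score()], keeps the
#' maximizer (ties toward fewer clusters), then dissolves and reassigns small
#' clusters via [reassign_small()].
#'
#' When the graph carries no negative edges the score cannot reach 1 for any
#' k >= 2 (every positive cut edge is penalized); the maximal-sparsity cut is
#' still returned, with a message — networks with few or no negative edges
#' are outside this algorithm's design envelope.
#'
#' @param g a `signed_graph`.
#' @param m its `scoring_matrix`.
#' @param params a [clustering_params()].
#' @return object of class `cluster_assignment`: list with `membership`
#'   (tibble `node`, `cluster`), `k`, `sparsity`, and `profile` (tibble of
#'   `k`, `sparsity` over the searched range).
#' @export
select_assignment <- function(g, m, params = clustering_params()) {
  stopifnot(is_signed_graph(g))
  if (all(g$edges$weight > 0)) {
    message("graph has no negative edges: sparsity-guided clustering ",
            "separates central from peripheral nodes in this regime")
  }
  sel <- select_k(g, m, params$min_clusters, params$max_clusters)
  a <- structure(list(membership = sel$membership, k = sel$k,
                      sparsity = sel$sparsity, profile = sel$profile),
                 class = "cluster_assignment")
  reassign_small(g, m, a, params$minsize)
}

select_k <- function(g, m, kmin, kmax) {
  vals <- if (inherits(m, "scoring_matrix")) m$values else m
  n <- nrow(vals)
  ks <- seq(min(kmin, n), min(kmax, n))
  fits <- lapply(ks, function(k) agglomerate(vals, k))
  scores <- vapply(fits, function(f) sparsity_score(g, f), numeric(1))
  best <- which.max(scores)   # which.max takes the first (smallest k) on ties
  list(membership = fits[[best]], k = ks[best], sparsity = scores[best],
       profile = tibble::tibble(k = ks, sparsity = scores))
}

#' Dissolve clusters below the size threshold and reassign their nodes
#'
#' High scores accumulating on central nodes can split off tiny clusters that
#' obscure the real structure. Clusters smaller than `minsize * |V|` are
#' removed from the scoring matrix, the remaining submatrix is re-clustered
#' with the same sparsity-guided k-selection, and each removed node is then
#' attached to the retained cluster with the highest mean shortest-path weight
#' product: over all fewest-hop paths to each cluster member, the product of
#' max-scaled edge weights, averaged per member and then over members.
#'
#' @param g a `signed_graph`.
#' @param m its `scoring_matrix`.
#' @param a a `cluster_assignment` (pre small-cluster handling).
#' @param minsize small-cluster threshold as a fraction of the node count;
#'   0 is a no-op. If every cluster falls below the threshold the original
#'   assignment is returned with a warning.
#' @return a `cluster_assignment` with updated membership, `k` and
#'   `sparsity`.
#' @export
reassign_small <- function(g, m, a, minsize = 0.1) {
  stopifnot(is_signed_graph(g))
  if (minsize <= 0) return(a)
  memb <- a$membership
  sizes <- table(memb$cluster)
  small <- as.integer(names(sizes)[sizes < minsize * n_nodes(g)])
  if (length(small) == 0) return(a)
  if (length(small) == length(sizes)) {
    warning("every cluster is below the size threshold; keeping original ",
            "assignment", call. = FALSE)
    return(a)
  }
  removed <- memb$node[memb$cluster %in% small]
  kept <- setdiff(memb$node, removed)

  vals <- if (inherits(m, "scoring_matrix")) m$values else m
  sub <- vals[kept, kept, drop = FALSE]
  kmax_allowed <- min(length(sizes) - length(small), length(kept))
  sel <- select_k(g = subgraph_nodes(g, kept), m = sub,
                  kmin = min(2, kmax_allowed),
                  kmax = max(2, kmax_allowed))
  new_memb <- sel$membership

  clusters <- sort(unique(new_memb$cluster))
  for (v in removed) {
    score <- vapply(clusters, function(cl) {
      members <- new_memb$node[new_memb$cluster == cl]
      mean(vapply(members, function(u) mean_path_product(g, v, u), numeric(1)))
    }, numeric(1))
    new_memb <- dplyr::bind_rows(
      new_memb, tibble::tibble(node = v, cluster = clusters[which.max(score)]))
  }
  new_memb <- canonical_labels(new_memb)
  structure(list(membership = new_memb,
                 k = length(unique(new_memb$cluster)),
                 sparsity = sparsity_score(g, new_memb),
                 profile = a$profile),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d, sparsity = %.3f\n",
              x$k, x$sparsity))
  print(table(cluster = x$membership$cluster))
  invisible(x)
}
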