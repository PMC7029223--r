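#' Cluster a signed weighted network
#'
#' The full pipeline: test the graph for structural balance, build the
#' scoring matrix ([converge_balanced()] on balanced graphs,
#' [score_unbalanced()] subset consensus on unbalanced ones), choose the
#' cluster number by the sparsity criterion ([select_assignment()]), and — on
#' the unbalanced path, where oscillators exist — flag weakly assigned nodes
#' ([flag_weak()]).
#'
#' @param x a `signed_graph`, or a data frame of edges (`from`, `to`,
#'   `weight`) which is passed through [signed_graph()] first.
#' @param diffusion a [diffusion_params()].
#' @param clustering a [clustering_params()].
#' @param weak compute weak-assignment flags (unbalanced graphs only).
#'   Default `TRUE`.
#' @param edgescale weak-assignment threshold on the mean edge product.
#'   Default 0.8.
#' @param binarize replace weights by their signs before clustering.
#'   Default `FALSE`.
#' @return object of class `signed_clusters`: list with `membership` (tibble
#'   `node`, `cluster`, `weak`), `k`, `sparsity`, `profile` (sparsity over the
#'   searched k range), `balanced`, `oscillators`, `scoring`
#'   (`scoring_matrix`), `graph`, and the parameter objects.
#' @examples
#' edges <- data.frame(
#'   from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1", "a3"),
#'   to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1", "b3"),
#'   weight = c(1, 1, 1, 1, 1, 1, -1, -1)
#' )
#' fit <- cluster_signed(edges)
#' tidy(fit)
#' glance(fit)
#' @export
cluster_signed <- function(x, diffusion = diffusion_params(),
                           clustering = clustering_params(),
                           weak = TRUE, edgescale = 0.8, binarize = FALSE) {
  g <- if (is_signed_graph(x)) x else signed_graph(x)
  if (n_edges(g) == 0) stop("graph has no edges to cluster", call. = FALSE)
  if (binarize) g <- binarize_weights(g)
  bal <- is_balanced(g)
  scoring <- if (bal$balanced) {
    converge_balanced(g, diffusion)
  } else {
    score_unbalanced(g, diffusion)
  }
  a <- select_assignment(g, scoring, clustering)

  oscillators <- character()
  flagged <- character()
  if (!bal$balanced) {
    oscillators <- detect_oscillators(g, diffusion)
    if (weak && length(oscillators) > 0) {
      flagged <- flag_weak(g, a, oscillators, edgescale = edgescale)
    }
  }
  memb <- a$membership
  memb$weak <- memb$node %in% flagged

  structure(list(
    membership = memb, k = a$k, sparsity = a$sparsity, profile = a$profile,
    balanced = bal$balanced, oscillators = oscillators,
    scoring = scoring, graph = g,
    diffusion = diffusion, clustering = clustering, edgescale = edgescale
  ), class = "signed_clusters")
}

#' @export
print.signed_clusters <- function(x, ...) {
  cat(sprintf(
    "<signed_clusters> %d nodes, %d clusters (sparsity %.3f), %s graph\n",
    nrow(x$membership), x$k, x$sparsity,
    if (x$balanced) "balanced" else "unbalanced"))
  if (length(x$oscillators) > 0) {
    cat(sprintf("oscillators: %s\n", paste(x$oscillators, collapse = ", ")))
  }
  nw <- sum(x$membership$weak)
  if (nw > 0) cat(sprintf("%d weakly assigned node(s)\n", nw))
  print(table(cluster = x$membership$cluster))
  invisible(x)
}

#' Tidy per-node view of a clustering
#'
#' @param x a `signed_clusters` object.
#' @param ... unused.
#' @return tibble with one row per node: `node`, `cluster`, `weak`,
#'   `oscillator`.
#' @method tidy signed_clusters
#' @export
tidy.signed_clusters <- function(x, ...) {
  dplyr::mutate(x$membership, oscillator = .data$node %in% x$oscillators)
}

#' One-row summary of a clustering
#'
#' @param x a `signed_clusters` object.
#' @param ... unused.
#' @return one-row tibble: node/edge counts, balance, cluster number,
#'   sparsity, diffusion iterations and convergence, weak/oscillator counts.
#' @method glance signed_clusters
#' @export
glance.signed_clusters <- function(x, ...) {
  tibble::tibble(
    n_nodes = n_nodes(x$graph), n_edges = n_edges(x$graph),
    balanced = x$balanced, k = x$k, sparsity = x$sparsity,
    iterations = x$scoring$iterations, converged = x$scoring$converged,
    n_weak = sum(x$membership$weak),
    n_oscillators = length(x$oscillators)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
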