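#' Mean edge product between a node and an oscillator
#'
#' For every fewest-hop path between `v` and `t`, the product of the scaled
#' edge weights (each weight divided by the graph's maximum absolute weight)
#' is taken; the mean edge product is the average of these products over all
#' such paths:
#' \deqn{P_{v,t} = \frac{1}{|n|}\sum_{i=1}^{|n|} \delta_i(v, t)}
#' A chain of positive associations keeps the product positive; a single
#' negative edge on the path flips it — "the enemy of my enemy is my friend".
#' A nonpositive or small \eqn{|P|} to a same-cluster oscillator marks `v` as
#' weakly assigned.
#'
#' @param g a `signed_graph`.
#' @param v,t distinct node identifiers.
#' @return the mean edge product, in \[-1, 1\] for weights in \[-1, 1\].
#'   Disconnected pairs return 0 with a warning (no path evidence).
#' @export
mean_edge_product <- function(g, v, t) {
  stopifnot(is_signed_graph(g), v != t,
            v %in% g$nodes, t %in% g$nodes)
  ctx <- path_context(g)
  p <- mean_path_product_ctx(ctx, v, t)
  if (is.na(p)) {
    warning("nodes ", v, " and ", t, " are disconnected; mean edge product ",
            "defined as 0", call. = FALSE)
    return(0)
  }
  p
}

# precomputed context for repeated path-product queries
path_context <- function(g) {
  list(ig = as_igraph(g),
       adj = adjacency_matrix(g) / max(abs(g$edges$weight)),
       nodes = g$nodes)
}

mean_path_product_ctx <- function(ctx, v, t) {
  res <- suppressWarnings(
    igraph::all_shortest_paths(ctx$ig, from = v, to = t, weights = NA))
  paths <- res$vpaths %||% res$res
  if (length(paths) == 0) return(NA_real_)
  deltas <- vapply(paths, function(p) {
    idx <- as.integer(p)
    prod(ctx$adj[cbind(idx[-length(idx)], idx[-1])])
  }, numeric(1))
  mean(deltas)
}

# quiet scalar version used by small-cluster reassignment (disconnected -> 0)
mean_path_product <- function(g, v, t) {
  p <- mean_path_product_ctx(path_context(g), v, t)
  if (is.na(p)) 0 else p
}

#' Flag weakly assigned nodes
#'
#' A node is weakly assigned when its shortest-path evidence conflicts with
#' (or insufficiently supports) its cluster label, judged against the
#' oscillator nodes of the flip-flop regime: node `v` is flagged iff, for
#' some oscillator `t` in the same cluster, (i) the mean edge product
#' \eqn{P_{v,t}} is not positive, or (ii) \eqn{|P_{v,t}|} falls below the
#' `edgescale` threshold. Flags annotate the membership — they never remove a
#' node from it; the test filters out nodes that could not be assigned to any
#' cluster rather than finding nodes shared by two clusters.
#'
#' Raising `edgescale` can only grow the flagged set (criterion ii is a
#' threshold), so the flag set is monotone in it.
#'
#' @param g a `signed_graph`.
#' @param assignment a `cluster_assignment` (or data frame `node`/`cluster`).
#' @param oscillators character vector from [detect_oscillators()]. Empty
#'   input (e.g. a balanced graph) yields an empty flag set with a warning.
#' @param edgescale threshold on `|P|` in \[0, 1\]. Default 0.8; 0.3 is the
#'   preset used for noisy benchmark networks.
#' @param all_oscillators evaluate criterion (ii) against every oscillator
#'   rather than only same-cluster ones. Default `FALSE`.
#' @return character vector of flagged node ids.
#' @export
flag_weak <- function(g, assignment, oscillators, edgescale = 0.8,
                      all_oscillators = FALSE) {
  stopifnot(is_signed_graph(g), edgescale >= 0, edgescale <= 1)
  if (length(oscillators) == 0) {
    warning("no oscillators supplied (balanced graph?); no weak flags",
            call. = FALSE)
    return(character())
  }
  memb <- membership_vector(
    if (inherits(assignment, "cluster_assignment")) assignment$membership
    else assignment)
  stopifnot(all(oscillators %in% names(memb)))
  ctx <- path_context(g)

  flagged <- vapply(g$nodes, function(v) {
    ts <- setdiff(oscillators, v)
    if (length(ts) == 0) return(FALSE)
    same <- ts[memb[ts] == memb[v]]
    pool2 <- if (all_oscillators) ts else same
    for (t in same) {
      p <- mean_path_product_ctx(ctx, v, t)
      if (is.na(p)) p <- 0
      if (p <= 0) return(TRUE)           # criterion (i)
    }
    for (t in pool2) {
      p <- mean_path_product_ctx(ctx, v, t)
      if (is.na(p)) p <- 0
      if (abs(p) < edgescale) return(TRUE)  # criterion (ii)
    }
    FALSE
  }, logical(1))
  g$nodes[flagged]
}
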