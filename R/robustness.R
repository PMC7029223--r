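#' Rewire a fraction of the network, preserving degrees
#'
#' Repositions approximately `fraction * |E|` edges through double-edge swaps
#' (edges a-b and c-d become a-d and c-b), the standard degree-preserving null
#' move: every node keeps its degree exactly, weights travel with their edges,
#' and swaps that would create self-loops or parallel edges are rejected.
#' Used to generate permuted cluster assignments with identical degree
#' distributions for the robustness estimate.
#'
#' @param g a `signed_graph` with at least 2 edges.
#' @param fraction fraction of edges to reposition, in \[0, 1\]. Each
#'   successful swap repositions two edges; the swap count is
#'   `round(fraction * |E| / 2)`, so a vanishing fraction returns the graph
#'   unchanged. Default 0.1.
#' @param seed integer seed.
#' @return a rewired `signed_graph`. If the swap budget cannot be met within
#'   a bounded number of attempts, the achieved fraction is reported in a
#'   warning and the partial result returned.
#' @export
rewire_graph <- function(g, fraction = 0.1, seed = 1L) {
  stopifnot(is_signed_graph(g), fraction >= 0, fraction <= 1, n_edges(g) >= 2)
  ne <- n_edges(g)
  target <- round(fraction * ne / 2)
  if (target == 0) return(g)

  from <- g$edges$from
  to <- g$edges$to
  weight <- g$edges$weight
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  for (k in seq_len(ne)) assign(ekey(from[k], to[k]), TRUE, envir = keyset)

  done <- 0L
  withr::with_seed(seed, {
    attempts <- 0L
    budget <- 200L * target + 200L
    while (done < target && attempts < budget) {
      attempts <- attempts + 1L
      ks <- sample.int(ne, 2)
      a <- from[ks[1]]; b <- to[ks[1]]
      c_ <- from[ks[2]]; d <- to[ks[2]]
      if (stats::runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }  # orientation
      if (length(unique(c(a, b, c_, d))) < 4) next
      k1 <- ekey(a, d); k2 <- ekey(c_, b)
      if (exists(k1, envir = keyset) || exists(k2, envir = keyset)) next
      rm(list = c(ekey(a, b), ekey(c_, d)), envir = keyset)
      assign(k1, TRUE, envir = keyset)
      assign(k2, TRUE, envir = keyset)
      from[ks[1]] <- a; to[ks[1]] <- d       # weight of edge 1 travels to a-d
      from[ks[2]] <- c_; to[ks[2]] <- b
      done <- done + 1L
    }
  })
  if (done < target) {
    warning(sprintf("rewire: only %d/%d swaps achieved (fraction %.3f of %.3f)",
                    done, target, 2 * done / ne, fraction), call. = FALSE)
  }
  signed_graph(data.frame(from = from, to = to, weight = weight),
               nodes = g$nodes)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Robustness of cluster assignments under partial rewiring
#'
#' Repeatedly rewires a fraction of the network (degree-preserving double-edge
#' swaps), re-runs the full clustering pipeline on each replicate, and
#' summarizes the agreement with the original assignment as percentile
#' confidence intervals of Jaccard similarity coefficients:
#' cluster-wise, each original cluster is matched to its best replicate
#' cluster (maximum Jaccard of member sets); node-wise, each node's set of
#' co-members is compared between original and replicate. Low similarity
#' means the cluster or node lands in different company after a few inference
#' errors; a wide node interval means the node sometimes keeps its company
#' and sometimes does not.
#'
#' @param g a `signed_graph`.
#' @param diffusion a [diffusion_params()] used for every replicate.
#' @param clustering a [clustering_params()].
#' @param n_replicates number of rewired replicates. Default 100.
#' @param fraction rewired edge fraction per replicate. Default 0.1.
#' @param ci_level percentile-interval coverage. Default 0.95.
#' @param seed integer seed; replicate seeds are derived from it.
#' @param exclude_weak drop weakly assigned nodes from member sets before
#'   computing Jaccard similarities. Default `FALSE`.
#' @param edgescale weak-assignment threshold, used only when
#'   `exclude_weak = TRUE`.
#' @return object of class `robustness_report`: list with
#'   `cluster_robustness` (tibble `cluster`, `jaccard_lower`, `jaccard_upper`,
#'   `jaccard_mean`), `node_robustness` (tibble `node`, same columns),
#'   `n_replicates` (replicates that clustered successfully), `fraction`,
#'   `ci_level`.
#' @export
cluster_robustness <- function(g, diffusion = diffusion_params(),
                               clustering = clustering_params(),
                               n_replicates = 100, fraction = 0.1,
                               ci_level = 0.95, seed = 1L,
                               exclude_weak = FALSE, edgescale = 0.8) {
  stopifnot(is_signed_graph(g), n_replicates >= 1,
            ci_level > 0, ci_level < 1)
  orig <- cluster_signed(g, diffusion = diffusion, clustering = clustering,
                         weak = exclude_weak, edgescale = edgescale)
  orig_members <- member_sets(orig, exclude_weak)
  orig_clusters <- names(orig_members$clusters)

  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 n_replicates))
  cl_jac <- matrix(NA_real_, n_replicates, length(orig_clusters),
                   dimnames = list(NULL, orig_clusters))
  nd_jac <- matrix(NA_real_, n_replicates, n_nodes(g),
                   dimnames = list(NULL, g$nodes))
  ok <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    rep_fit <- tryCatch({
      gr <- suppressWarnings(rewire_graph(g, fraction, seed = rep_seeds[r]))
      dp <- diffusion
      dp$seed <- rep_seeds[r]
      suppressWarnings(suppressMessages(
        cluster_signed(gr, diffusion = dp, clustering = clustering,
                       weak = exclude_weak, edgescale = edgescale)))
    }, error = function(e) NULL)
    if (is.null(rep_fit)) next
    ok[r] <- TRUE
    rep_members <- member_sets(rep_fit, exclude_weak)
    for (cl in orig_clusters) {
      cl_jac[r, cl] <- max(vapply(rep_members$clusters, jaccard,
                                  numeric(1), a = orig_members$clusters[[cl]]))
    }
    for (v in g$nodes) {
      nd_jac[r, v] <- jaccard(orig_members$comembers[[v]],
                              rep_members$comembers[[v]])
    }
  }
  if (!any(ok)) stop("all replicates failed to cluster", call. = FALSE)
  if (any(!ok)) {
    warning(sum(!ok), " replicate(s) dropped (clustering failure)",
            call. = FALSE)
  }
  probs <- c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)
  ci_tbl <- function(mat, idcol, ids) {
    qs <- apply(mat[ok, , drop = FALSE], 2, stats::quantile, probs = probs,
                names = FALSE)
    tibble::tibble(!!idcol := ids,
                   jaccard_lower = qs[1, ], jaccard_upper = qs[2, ],
                   jaccard_mean = colMeans(mat[ok, , drop = FALSE]))
  }
  structure(list(
    cluster_robustness = ci_tbl(cl_jac, "cluster",
                                as.integer(orig_clusters)),
    node_robustness = ci_tbl(nd_jac, "node", g$nodes),
    n_replicates = sum(ok), fraction = fraction, ci_level = ci_level,
    original = orig
  ), class = "robustness_report")
}

# member sets per cluster and co-member set per node (optionally minus weak)
member_sets <- function(fit, exclude_weak) {
  memb <- fit$membership
  counted <- if (exclude_weak) memb[!memb$weak, ] else memb
  clusters <- split(counted$node, counted$cluster)
  comembers <- lapply(stats::setNames(memb$node, memb$node), function(v) {
    cl <- memb$cluster[memb$node == v]
    setdiff(clusters[[as.character(cl)]] %||% character(), v)
  })
  list(clusters = clusters, comembers = comembers)
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf(
    "<robustness_report> %d replicate(s), rewire fraction %.2f, %.0f%% CI\n",
    x$n_replicates, x$fraction, 100 * x$ci_level))
  print(x$cluster_robustness)
  invisible(x)
}

#' @rdname cluster_robustness
#' @param x a `robustness_report`.
#' @param ... unused.
#' @method tidy robustness_report
#' @export
tidy.robustness_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(x$cluster_robustness, id = "cluster"),
      id = as.character(.data$id), level = "cluster", .before = 1),
    dplyr::mutate(dplyr::rename(x$node_robustness, id = "node"),
                  level = "node", .before = 1)
  )
}
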