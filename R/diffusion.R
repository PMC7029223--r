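#' Diffusion parameters
#'
#' Collects the tunable settings of the score-matrix diffusion.
#'
#' @param epsilon convergence threshold, in percent: iteration stops once 100
#'   times the mean absolute change over nonzero entries drops to `epsilon`
#'   or below. Default 2.
#' @param max_iterations iteration cap; between 50 and 100 iterations are
#'   generally sufficient, balanced graphs need fewer. Default 100.
#' @param n_subsets number of edge subsets scored in the consensus used for
#'   unbalanced graphs. Default 100.
#' @param subset_fraction fraction of edges sampled into each subset.
#'   Default 0.8.
#' @param ratio fraction of subsets that must agree on an entry's sign for it
#'   to enter the consensus matrix. Default 0.8.
#' @param seed integer seed governing all subset sampling.
#' @return a list of class `diffusion_params`.
#' @export
diffusion_params <- function(epsilon = 2, max_iterations = 100,
                             n_subsets = 100, subset_fraction = 0.8,
                             ratio = 0.8, seed = 1L) {
  stopifnot(epsilon > 0, max_iterations >= 1,
            n_subsets >= 1, subset_fraction > 0, subset_fraction <= 1,
            ratio > 0, ratio <= 1)
  structure(list(epsilon = epsilon, max_iterations = as.integer(max_iterations),
                 n_subsets = as.integer(n_subsets),
                 subset_fraction = subset_fraction, ratio = ratio,
                 seed = as.integer(seed)),
            class = "diffusion_params")
}

new_scoring_matrix <- function(values, iterations, converged) {
  structure(list(values = values, iterations = as.integer(iterations),
                 converged = converged),
            class = "scoring_matrix")
}

#' @export
print.scoring_matrix <- function(x, ...) {
  cat(sprintf("<scoring_matrix> %d x %d, %d iteration(s), %s\n",
              nrow(x$values), ncol(x$values), x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Normalize a matrix by its maximum absolute entry
#'
#' Divides every entry by `max(abs(m))`, so that the largest magnitude becomes
#' exactly 1 while all signs are preserved. This is the normalization applied
#' after every expansion and inflation step of the diffusion; unlike the
#' column-stochastic normalization of Markov-chain clustering it never
#' discards signs.
#'
#' @param m numeric matrix (or a `scoring_matrix`).
#' @return object of the same shape, normalized.
#' @export
normalize_max_abs <- function(m) {
  if (inherits(m, "scoring_matrix")) {
    m$values <- normalize_max_abs(m$values)
    return(m)
  }
  mx <- max(abs(m))
  if (mx == 0) {
    stop("degenerate state: scoring matrix is all zero (diffusion collapsed)",
         call. = FALSE)
  }
  m / mx
}

# entries below this magnitude are numerically zero: the inflation x + 1/x
# would overflow on them, and they carry no sign information
NZ_TOL <- 1e-12

# one expansion + inflation pass: square, normalize, x <- x + 1/x on nonzero
# entries, normalize. Zeros stay zero within the inflation; squaring fills
# them in over iterations.
diffusion_step <- function(m) {
  m <- m %*% m
  m <- normalize_max_abs(m)
  m[abs(m) < NZ_TOL] <- 0
  nz <- m != 0
  m[nz] <- m[nz] + 1 / m[nz]
  normalize_max_abs(m)
}

#' Iterate the score-matrix diffusion on a balanced graph to convergence
#'
#' Starting from the weighted adjacency matrix, repeatedly squares the matrix,
#' normalizes by the maximum absolute value, applies the sign-preserving
#' inflation `x + 1/x` to nonzero entries, and normalizes again. On a
#' structurally balanced graph the entries converge to -1 and +1, positive
#' within clusters and negative across, and the sign of every nonzero entry
#' agrees with the adjacency matrix throughout. Iteration stops when 100 times
#' the mean absolute change over the nonzero entries falls to `epsilon`, or at
#' `max_iterations`.
#'
#' On an unbalanced graph the recurrence flip-flops and never settles; use
#' [score_unbalanced()] there (and [detect_oscillators()] to harvest the
#' flip-flop information).
#'
#' @param g a `signed_graph`, structurally balanced (caller's responsibility;
#'   see [is_balanced()]).
#' @param params a [diffusion_params()] object.
#' @return a `scoring_matrix`: list with `values` (dense symmetric matrix in
#'   \[-1, 1\], dimnames = node ids), `iterations`, `converged`. A warning is
#'   raised if the cap is hit without convergence.
#' @export
converge_balanced <- function(g, params = diffusion_params()) {
  stopifnot(is_signed_graph(g))
  if (n_edges(g) == 0) {
    stop("graph has no edges: scoring matrix is all zero", call. = FALSE)
  }
  m <- adjacency_matrix(g)
  prev <- m
  converged <- FALSE
  iter <- 0L
  for (i in seq_len(params$max_iterations)) {
    iter <- i
    m <- diffusion_step(prev)
    nz <- m != 0
    b <- sum(nz)
    e <- if (b > 0) sum(abs(m[nz] - prev[nz])) / b else 0
    prev <- m
    if (100 * e <= params$epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("diffusion did not converge within ", params$max_iterations,
            " iterations; the graph may be unbalanced", call. = FALSE)
  }
  new_scoring_matrix(m, iter, converged)
}

#' Detect oscillator nodes in an unbalanced graph
#'
#' On unbalanced graphs the diffusion enters a flip-flop regime in which the
#' matrix limits -1 and +1 are approached only by a few entries: the diagonal
#' entry of an oscillator node approaches +1 while some entry in the same row
#' reaches -1, and all other values oscillate near 0. Oscillators serve as
#' reference points for the weak-assignment test.
#'
#' The diffusion loop is run for `max_iterations` flip-flop iterations with no
#' convergence stop; because the alternating states hit their extremes at
#' different iterations, the per-node extrema are tracked across the whole
#' trajectory. A node is an oscillator if its diagonal entry reaches at least
#' `1 - tol` at some iteration and its row contains an entry reaching
#' `-1 + tol` or below.
#'
#' @param g a `signed_graph`, expected unbalanced. Balanced input yields an
#'   empty set with a warning (every diagonal approaches +1, no paired
#'   minimum).
#' @param params a [diffusion_params()].
#' @param tol detection tolerance on the \eqn{\pm 1} limits. Default 0.01.
#' @return character vector of oscillator node ids (possibly empty).
#' @export
detect_oscillators <- function(g, params = diffusion_params(), tol = 0.01) {
  stopifnot(is_signed_graph(g))
  if (is_balanced(g)$balanced) {
    warning("graph is balanced: no oscillators exist", call. = FALSE)
    return(character())
  }
  m <- adjacency_matrix(g)
  diag_max <- rep(-Inf, n_nodes(g))
  row_min <- rep(Inf, n_nodes(g))
  for (i in seq_len(params$max_iterations)) {
    m <- diffusion_step(m)
    diag_max <- pmax(diag_max, diag(m))
    row_min <- pmin(row_min, apply(m, 1, min))
  }
  g$nodes[diag_max >= 1 - tol & row_min <= -1 + tol]
}

#' Score an unbalanced graph by subset consensus
#'
#' Unbalanced graphs flip-flop under the diffusion, so the scoring matrix is
#' assembled from `n_subsets` edge subsamples instead. For each subset,
#' `ceiling(subset_fraction * |E|)` edges are drawn uniformly without
#' replacement; structurally balanced components of the subgraph are iterated
#' to convergence ([converge_balanced()]) and their scores embedded at their
#' nodes' rows/columns, while the full subset matrix receives exactly one
#' expansion + inflation pass (more would reintroduce flip-flops). The
#' component scores are added, and the result normalized. A consensus matrix
#' keeps a position only when more than `ratio * n_subsets` subsets agree on
#' its sign (unanimity always qualifies), summing the subset values there; the
#' consensus is finally normalized to \[-1, 1\].
#'
#' @param g a `signed_graph`, expected unbalanced.
#' @param params a [diffusion_params()]; `seed` governs all subset sampling.
#' @return a `scoring_matrix` (consensus values; `iterations` is the number of
#'   subsets actually used, `converged` is `TRUE` by construction).
#' @export
score_unbalanced <- function(g, params = diffusion_params()) {
  stopifnot(is_signed_graph(g))
  n <- n_nodes(g)
  ne <- n_edges(g)
  if (ne == 0) stop("graph has no edges", call. = FALSE)
  K <- params$n_subsets
  f <- ceiling(params$subset_fraction * ne)

  subset_scores <- withr::with_seed(params$seed, {
    lapply(seq_len(K), function(k) {
      idx <- sample.int(ne, f)
      sub_edges <- g$edges[idx, ]
      gs <- signed_graph(sub_edges, nodes = g$nodes)
      score_one_subset(gs, params)
    })
  })
  kept <- !vapply(subset_scores, is.null, logical(1))
  if (!any(kept)) {
    stop("degenerate state: every subset produced an all-zero matrix",
         call. = FALSE)
  }
  if (any(!kept)) {
    warning(sum(!kept), " subset(s) discarded (all-zero matrix)",
            call. = FALSE)
  }
  scores <- subset_scores[kept]
  K_eff <- length(scores)

  pos <- Reduce(`+`, lapply(scores, function(s) s > 0))
  neg <- Reduce(`+`, lapply(scores, function(s) s < 0))
  total <- Reduce(`+`, scores)
  agree <- (pos / K_eff > params$ratio) | (pos == K_eff & pos > 0) |
           (neg / K_eff > params$ratio) | (neg == K_eff & neg > 0)
  out <- matrix(0, n, n, dimnames = list(g$nodes, g$nodes))
  out[agree] <- total[agree]
  if (max(abs(out)) == 0) {
    stop("degenerate state: no position reached sign consensus", call. = FALSE)
  }
  new_scoring_matrix(normalize_max_abs(out), K_eff, TRUE)
}

# score a single edge subset: balanced components to convergence, full subset
# matrix one pass, add, normalize. Returns NULL for an all-zero subset.
score_one_subset <- function(gs, params) {
  n <- n_nodes(gs)
  b_mat <- matrix(0, n, n, dimnames = list(gs$nodes, gs$nodes))
  comps <- igraph::components(as_igraph(gs))
  for (cid in seq_len(comps$no)) {
    members <- gs$nodes[comps$membership == cid]
    if (length(members) < 2) next
    comp <- subgraph_nodes(gs, members)
    if (n_edges(comp) == 0) next
    if (is_balanced(comp)$balanced) {
      sm <- suppressWarnings(converge_balanced(comp, params))
      b_mat[comp$nodes, comp$nodes] <- sm$values
    }
  }
  m <- adjacency_matrix(gs)
  if (max(abs(m)) == 0) return(NULL)
  m <- diffusion_step(m)        # exactly one pass on the full subset matrix
  m <- m + b_mat
  if (max(abs(m)) == 0) return(NULL)
  normalize_max_abs(m)
}
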