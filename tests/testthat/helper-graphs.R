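# toy graphs and random-graph generators shared across the test files

# two all-positive triangles joined by two negative bridge edges: the
# canonical balanced two-cluster toy
balanced_toy <- function() {
  signed_graph(data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1", "a3"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1", "b3"),
    weight = c(1, 1, 1, 1, 1, 1, -1, -1)
  ))
}

# same toy with one within-cluster edge flipped negative: unbalanced
unbalanced_toy <- function() {
  signed_graph(data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1", "a3"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1", "b3"),
    weight = c(-1, 1, 1, 1, 1, 1, -1, -1)
  ))
}

# single unbalanced triangle (+, +, -)
unbalanced_triangle <- function() {
  signed_graph(data.frame(
    from = c("x", "x", "y"), to = c("y", "z", "z"),
    weight = c(1, 1, -1)
  ))
}

# random signed graph: Erdos-Renyi topology, weights U(-1,1) excluding 0
random_signed_graph <- function(n, p = 0.4, seed = 1) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    w <- stats::runif(nrow(pairs), -1, 1)
    w[w == 0] <- 0.5
    signed_graph(data.frame(
      from = sprintf("n%02d", pairs[, 1]),
      to = sprintf("n%02d", pairs[, 2]),
      weight = w
    ), nodes = sprintf("n%02d", seq_len(n)))
  })
}

# random structurally balanced graph: hidden two-coloring, positive weights
# within a side, negative across
random_balanced_graph <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    side <- stats::rbinom(n, 1, 0.5)
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) < p
    pairs <- pairs[keep, , drop = FALSE]
    mag <- stats::runif(nrow(pairs), 0.2, 1)
    sgn <- ifelse(side[pairs[, 1]] == side[pairs[, 2]], 1, -1)
    signed_graph(data.frame(
      from = sprintf("n%02d", pairs[, 1]),
      to = sprintf("n%02d", pairs[, 2]),
      weight = sgn * mag
    ), nodes = sprintf("n%02d", seq_len(n)))
  })
}

# planted two-block partition: complete positive blocks, complete negative
# bipartite connection (balanced by construction); truth = block labels
planted_partition <- function(n_per_block = 6, seed = 1, p = 1) {
  withr::with_seed(seed, {
    ids <- c(sprintf("u%02d", seq_len(n_per_block)),
             sprintf("v%02d", seq_len(n_per_block)))
    block <- rep(0:1, each = n_per_block)
    pairs <- t(utils::combn(length(ids), 2))
    keep <- stats::runif(nrow(pairs)) <= p
    # keep a spanning backbone so the graph stays connected at any p: ring
    # within each block plus one bridge
    ring <- cbind(seq_along(ids), c(seq_len(n_per_block)[-1], 1,
                                    n_per_block + c(seq_len(n_per_block)[-1], 1)))
    for (r in seq_len(nrow(ring))) {
      hit <- (pairs[, 1] == pmin(ring[r, 1], ring[r, 2]) &
                pairs[, 2] == pmax(ring[r, 1], ring[r, 2]))
      keep[hit] <- TRUE
    }
    keep[pairs[, 1] == 1 & pairs[, 2] == n_per_block + 1] <- TRUE
    pairs <- pairs[keep, , drop = FALSE]
    same <- block[pairs[, 1]] == block[pairs[, 2]]
    mag <- stats::runif(nrow(pairs), 0.3, 1)
    g <- signed_graph(data.frame(
      from = ids[pairs[, 1]], to = ids[pairs[, 2]],
      weight = ifelse(same, mag, -mag)
    ))
    truth <- tibble::tibble(node = ids, cluster = block)
    list(graph = g, truth = truth[order(truth$node), ])
  })
}

# independent balance oracle: a graph is balanced iff every fundamental
# cycle w.r.t. a spanning forest has a positive edge-sign product
balance_oracle <- function(g) {
  if (nrow(g$edges) == 0) return(TRUE)
  visited <- rep(FALSE, length(g$nodes))
  adj <- lapply(seq_along(g$nodes), function(i) integer())
  ei <- match(g$edges$from, g$nodes); ej <- match(g$edges$to, g$nodes)
  for (k in seq_along(ei)) {
    adj[[ei[k]]] <- c(adj[[ei[k]]], k)
    adj[[ej[k]]] <- c(adj[[ej[k]]], k)
  }
  sgn <- sign(g$edges$weight)
  # product of signs along tree path to root, per node
  prod_to_root <- rep(NA_real_, length(g$nodes))
  in_tree <- rep(FALSE, nrow(g$edges))
  for (root in seq_along(g$nodes)) {
    if (visited[root]) next
    visited[root] <- TRUE
    prod_to_root[root] <- 1
    queue <- root
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (k in adj[[u]]) {
        v <- if (ei[k] == u) ej[k] else ei[k]
        if (!visited[v]) {
          visited[v] <- TRUE
          in_tree[k] <- TRUE
          prod_to_root[v] <- prod_to_root[u] * sgn[k]
          queue <- c(queue, v)
        }
      }
    }
  }
  # each non-tree edge closes one fundamental cycle
  for (k in which(!in_tree)) {
    cyc_sign <- prod_to_root[ei[k]] * prod_to_root[ej[k]] * sgn[k]
    if (cyc_sign < 0) return(FALSE)
  }
  TRUE
}

# independent all-shortest-paths mean edge product by BFS layering
brute_mean_edge_product <- function(g, v, t) {
  adjm <- adjacency_matrix(g) / max(abs(g$edges$weight))
  n <- length(g$nodes)
  vi <- match(v, g$nodes); ti <- match(t, g$nodes)
  # BFS distances from v
  dist <- rep(Inf, n); dist[vi] <- 0
  queue <- vi
  while (length(queue) > 0) {
    u <- queue[1]; queue <- queue[-1]
    nb <- which(adjm[u, ] != 0)
    for (w in nb) if (is.infinite(dist[w])) {
      dist[w] <- dist[u] + 1
      queue <- c(queue, w)
    }
  }
  if (is.infinite(dist[ti])) return(NA_real_)
  # enumerate all shortest paths recursively (t backwards to v)
  paths <- list()
  walk <- function(node, acc) {
    if (node == vi) {
      paths[[length(paths) + 1]] <<- rev(acc)
      return(invisible())
    }
    preds <- which(adjm[node, ] != 0 & dist == dist[node] - 1)
    for (p in preds) walk(p, c(acc, p))
  }
  walk(ti, ti)
  deltas <- vapply(paths, function(p) {
    prod(adjm[cbind(p[-length(p)], p[-1])])
  }, numeric(1))
  mean(deltas)
}
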