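test_that("sparsity score hits the exact extremes on mirrored assignments", {
  # two triangles with internal +1 edges joined by two -1 bridges: the natural
  # bipartition puts every positive edge inside and every negative edge across
  g <- balanced_toy()
  best <- data.frame(node = g$nodes, cluster = rep(0:1, each = 3))
  expect_identical(sparsity_score(g, best), 1)
  # mirror image: internal -1 triangles joined by +1 edges, same bipartition
  worst_g <- signed_graph(data.frame(
    from = c("a1", "a1", "a2", "b1", "b1", "b2", "a1", "a2", "a3", "a3"),
    to   = c("a2", "a3", "a3", "b2", "b3", "b3", "b1", "b2", "b3", "b1"),
    weight = c(-1, -1, -1, -1, -1, -1, 1, 1, 1, 1)))
  worst <- data.frame(node = worst_g$nodes, cluster = rep(0:1, each = 3))
  expect_identical(sparsity_score(worst_g, worst), -1)
})

test_that("sparsity of the hand-enumerated 5-node example is 0.2", {
  g <- signed_graph(data.frame(
    from = c("n1", "n2", "n1", "n3", "n2"),
    to   = c("n2", "n3", "n3", "n4", "n5"),
    weight = c(1, 1, -1, -1, 1)))
  memb <- data.frame(node = c("n1", "n2", "n3", "n4", "n5"),
                     cluster = c(0, 0, 0, 1, 1))
  # inside: n1-n2 (+), n2-n3 (+), n1-n3 (-); cut: n3-n4 (-), n2-n5 (+)
  # s = (1 + 2 - 1 - 1) / 5
  expect_equal(sparsity_score(g, memb), 0.2)
})

test_that("sparsity is undefined on an edgeless graph", {
  g <- signed_graph(data.frame(from = character(), to = character(),
                               weight = numeric()), nodes = c("A", "B"))
  expect_error(sparsity_score(g, data.frame(node = c("A", "B"),
                                            cluster = c(0, 1))),
               "edgeless")
})

test_that("Ward cut of the converged toy matrix recovers the sign blocks", {
  sm <- converge_balanced(balanced_toy())
  memb <- agglomerate(sm, 2)
  expect_equal(memb$cluster[memb$node %in% c("a1", "a2", "a3")],
               rep(memb$cluster[memb$node == "a1"], 3))
  expect_equal(length(unique(memb$cluster)), 2)
})

test_that("k equal to the node count gives singletons; k beyond it errors", {
  sm <- converge_balanced(balanced_toy())
  memb <- agglomerate(sm, 6)
  expect_equal(sort(unique(memb$cluster)), 0:5)
  expect_error(agglomerate(sm, 7), "exceeds")
})

test_that("agglomerate matches an independent Lance-Williams Ward implementation", {
  # naive Ward agglomeration via the Lance-Williams update, written
  # independently of hclust
  naive_ward <- function(d2, k) {          # d2: squared Euclidean distances
    n <- nrow(d2)
    active <- seq_len(n)
    size <- rep(1, n)
    members <- as.list(seq_len(n))
    while (length(active) > k) {
      best <- c(NA, NA); best_val <- Inf
      for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
        i <- active[ii]; j <- active[jj]
        if (d2[i, j] < best_val) { best_val <- d2[i, j]; best <- c(i, j) }
      }
      i <- best[1]; j <- best[2]
      for (h in setdiff(active, c(i, j))) {
        d2[i, h] <- d2[h, i] <-
          ((size[i] + size[h]) * d2[i, h] + (size[j] + size[h]) * d2[j, h] -
             size[h] * d2[i, j]) / (size[i] + size[j] + size[h])
      }
      members[[i]] <- c(members[[i]], members[[j]])
      size[i] <- size[i] + size[j]
      active <- setdiff(active, j)
    }
    lab <- integer(n)
    for (c_idx in seq_along(active)) lab[members[[active[c_idx]]]] <- c_idx
    lab
  }
  m <- withr::with_seed(8, {
    x <- matrix(rnorm(36), 6); x <- (x + t(x)) / 2
    dimnames(x) <- list(sprintf("n%d", 1:6), sprintf("n%d", 1:6))
    x
  })
  d2 <- as.matrix(dist(m))^2
  # Ward's objective: merge cost = d2 * size terms; Lance-Williams on d^2 / 2
  expected <- naive_ward(d2 / 2, 3)
  got <- agglomerate(m, 3)
  # compare as partitions (labels may differ)
  expect_equal(length(unique(expected)), 3)
  part_a <- split(got$node, got$cluster)
  part_b <- split(rownames(m), expected)
  expect_setequal(lapply(part_a, sort), lapply(part_b, sort))
})

test_that("agglomerate is equivariant under node relabeling", {
  g <- planted_partition(4, seed = 6)$graph
  sm <- converge_balanced(g)
  memb1 <- agglomerate(sm, 2)
  # permute the matrix rows/cols; canonical labels must induce the same partition
  perm <- withr::with_seed(1, sample(nrow(sm$values)))
  m2 <- sm$values[perm, perm]
  memb2 <- agglomerate(m2, 2)
  p1 <- lapply(split(memb1$node, memb1$cluster), sort)
  p2 <- lapply(split(memb2$node, memb2$cluster), sort)
  expect_setequal(p1, p2)
})

test_that("sparsity-guided selection picks k = 2 on the balanced toy", {
  g <- balanced_toy()
  sm <- converge_balanced(g)
  a <- select_assignment(g, sm)
  expect_equal(a$k, 2)
  expect_identical(a$sparsity, 1)
  expect_true(all(a$profile$sparsity <= a$sparsity))
})

test_that("selected sparsity dominates every other k in range (by construction)", {
  g <- random_balanced_graph(14, seed = 12)
  sm <- converge_balanced(g)
  a <- select_assignment(g, sm, clustering_params(min_clusters = 2,
                                                  max_clusters = 5,
                                                  minsize = 0))
  expect_true(all(a$profile$sparsity <= a$sparsity + 1e-12))
})

test_that("a pure positive clique triggers the few-negative-edges message", {
  pairs <- t(combn(5, 2))
  g <- signed_graph(data.frame(from = sprintf("n%d", pairs[, 1]),
                               to = sprintf("n%d", pairs[, 2]),
                               weight = 1))
  sm <- converge_balanced(g)
  expect_message(a <- select_assignment(g, sm), "no negative edges")
  expect_lt(a$sparsity, 1)    # any k >= 2 cuts positive edges
})

test_that("min_clusters = max_clusters = 2 reduces to the plain 2-cut", {
  g <- balanced_toy()
  sm <- converge_balanced(g)
  a <- select_assignment(g, sm, clustering_params(2, 2, minsize = 0))
  expect_equal(a$membership, agglomerate(sm, 2))
})

test_that("reassign_small is a no-op when nothing is small or minsize is 0", {
  g <- balanced_toy()
  sm <- converge_balanced(g)
  a <- select_assignment(g, sm, clustering_params(minsize = 0))
  expect_identical(reassign_small(g, sm, a, 0), a)
  expect_equal(reassign_small(g, sm, a, 0.3)$membership, a$membership)
})

test_that("a dissolved singleton rejoins through its positive shortest path", {
  # two-cluster toy plus a pendant node attached by one +1 edge to cluster 0:
  # with minsize above 1/7 the singleton cluster dissolves and the pendant
  # node must land in the cluster its only path evidence supports
  edges <- rbind(balanced_toy()$edges,
                 tibble::tibble(from = "a1", to = "p1", weight = 1))
  g <- signed_graph(edges)
  sm <- converge_balanced(g)
  a3 <- structure(list(
    membership = tibble::tibble(
      node = sort(g$nodes),
      cluster = c(0L, 0L, 0L, 1L, 1L, 1L, 2L)[order(c("a1", "a2", "a3",
                                                      "b1", "b2", "b3",
                                                      "p1"))]),
    k = 3L, sparsity = NA_real_, profile = NULL),
    class = "cluster_assignment")
  out <- reassign_small(g, sm, a3, minsize = 0.2)
  memb <- setNames(out$membership$cluster, out$membership$node)
  expect_equal(unname(memb["p1"]), unname(memb["a1"]))
  expect_equal(out$k, 2)
})

test_that("all-small clusters fall back to the original assignment with warning", {
  g <- balanced_toy()
  sm <- converge_balanced(g)
  # three clusters of two: with minsize 0.45 the threshold is 2.7 nodes, so
  # every cluster is small and the step must refuse to dissolve them all
  a <- structure(list(
    membership = tibble::tibble(node = sort(g$nodes),
                                cluster = rep(0:2, each = 2)),
    k = 3L, sparsity = NA_real_, profile = NULL),
    class = "cluster_assignment")
  expect_warning(out <- reassign_small(g, sm, a, 0.45),
                 "below the size threshold")
  expect_equal(out$membership, a$membership)
})

test_that("planted bipartitions are recovered exactly across 50 seeds", {
  for (seed in 1:50) {
    pp <- planted_partition(5, seed = seed)
    fit <- cluster_signed(pp$graph)
    expect_true(fit$balanced)
    expect_equal(fit$k, 2, info = paste("seed", seed))
    got <- lapply(split(fit$membership$node, fit$membership$cluster), sort)
    want <- lapply(split(pp$truth$node, pp$truth$cluster), sort)
    expect_setequal(got, want)
    expect_identical(fit$sparsity, 1)
  }
})
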