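test_that("max-abs normalization divides by the largest magnitude", {
  m <- matrix(c(2, -4, -4, 2), 2)
  expect_equal(normalize_max_abs(m), matrix(c(0.5, -1, -1, 0.5), 2))
  # idempotent once max |entry| is 1
  expect_equal(normalize_max_abs(normalize_max_abs(m)), normalize_max_abs(m))
  # scale invariant for positive scalars
  expect_equal(normalize_max_abs(3.7 * m), normalize_max_abs(m))
  expect_error(normalize_max_abs(matrix(0, 2, 2)), "degenerate")
})

test_that("balanced toy converges to the signed two-block pattern at |1|", {
  g <- balanced_toy()
  sm <- converge_balanced(g)
  expect_true(sm$converged)
  expect_true(all(abs(abs(sm$values) - 1) < 1e-6))
  side <- c(a1 = 0, a2 = 0, a3 = 0, b1 = 1, b2 = 1, b3 = 1)
  for (i in g$nodes) for (j in g$nodes) {
    expected_sign <- if (side[i] == side[j]) 1 else -1
    expect_equal(sign(sm$values[i, j]), expected_sign)
  }
})

test_that("a single positive edge reaches the hand-derived fixed point", {
  # M0 = [[0,1],[1,0]]; square -> I; inflate nonzeros -> 2I; normalize -> I;
  # second pass leaves I unchanged, so the fixed point is the identity
  g <- signed_graph(data.frame(from = "A", to = "B", weight = 1))
  sm <- converge_balanced(g)
  expect_true(sm$converged)
  expect_equal(unname(sm$values), diag(2))
})

test_that("a dominating threshold stops after one iteration", {
  sm <- converge_balanced(balanced_toy(), diffusion_params(epsilon = 100))
  expect_true(sm$converged)
  expect_equal(sm$iterations, 1L)
})

test_that("diffusion is deterministic: identical inputs, identical output", {
  g <- random_balanced_graph(12, seed = 4)
  s1 <- converge_balanced(g)
  s2 <- converge_balanced(g)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$iterations, s2$iterations)
})

test_that("diffusion never conflicts with adjacency signs on balanced graphs", {
  for (seed in 1:100) {
    g <- random_balanced_graph(5 + seed %% 10, p = 0.5, seed = seed)
    if (nrow(g$edges) == 0) next
    adj <- adjacency_matrix(g)
    m <- adj
    for (it in 1:5) {                     # check every early iteration too
      m <- signetclust:::diffusion_step(m)
      conflict <- adj != 0 & m != 0 & sign(m) != sign(adj)
      expect_false(any(conflict), info = paste("seed", seed, "iter", it))
    }
  }
})

test_that("non-convergence within the cap warns and flags the matrix", {
  g <- unbalanced_toy()
  expect_warning(sm <- converge_balanced(g, diffusion_params(max_iterations = 30)),
                 "did not converge")
  expect_false(sm$converged)
  expect_equal(sm$iterations, 30L)
})

test_that("oscillators on the unbalanced triangle match brute-force iteration", {
  g <- unbalanced_triangle()
  # independent oracle: iterate the 3x3 recurrence 50 steps, tracking extrema
  m <- adjacency_matrix(g)
  dmax <- rep(-Inf, 3); rmin <- rep(Inf, 3)
  for (i in 1:50) {
    m <- m %*% m
    m <- m / max(abs(m))
    nz <- m != 0
    m[nz] <- m[nz] + 1 / m[nz]
    m <- m / max(abs(m))
    dmax <- pmax(dmax, diag(m))
    rmin <- pmin(rmin, apply(m, 1, min))
  }
  expected <- g$nodes[dmax >= 0.99 & rmin <= -0.99]
  got <- detect_oscillators(g, diffusion_params(max_iterations = 50))
  expect_equal(got, expected)
  expect_gt(length(got), 0)
})

test_that("unbalanced toy has a nonempty strict subset of oscillators", {
  osc <- detect_oscillators(unbalanced_toy())
  expect_gt(length(osc), 0)
  expect_lt(length(osc), length(unbalanced_toy()$nodes))
})

test_that("balanced input gives no oscillators, with a warning", {
  expect_warning(osc <- detect_oscillators(balanced_toy()), "balanced")
  expect_length(osc, 0)
})

test_that("K = 1 with the full edge set reduces to the single one-pass matrix", {
  g <- unbalanced_toy()
  p <- diffusion_params(n_subsets = 1, subset_fraction = 1, ratio = 0.5,
                        seed = 7)
  got <- score_unbalanced(g, p)
  expected <- signetclust:::score_one_subset(g, p)
  expect_equal(got$values, normalize_max_abs(expected))
})

test_that("subset consensus is reproducible, symmetric, and bounded", {
  g <- unbalanced_toy()
  p <- diffusion_params(n_subsets = 25, seed = 42)
  s1 <- score_unbalanced(g, p)
  s2 <- score_unbalanced(g, p)
  expect_identical(s1$values, s2$values)
  expect_equal(s1$values, t(s1$values), tolerance = 1e-9)
  expect_true(all(s1$values >= -1 & s1$values <= 1))
  expect_equal(max(abs(s1$values)), 1)
})

test_that("consensus signs match the balanced majority structure of the toy", {
  g <- unbalanced_toy()
  cons <- score_unbalanced(g, diffusion_params(n_subsets = 50,
                                               subset_fraction = 0.8,
                                               seed = 11))
  # reference: diffusion on the graph with the conflicting edge removed
  clean <- signed_graph(data.frame(
    from = c("a1", "a2", "b1", "b1", "b2", "a1", "a3"),
    to   = c("a3", "a3", "b2", "b3", "b3", "b1", "b3"),
    weight = c(1, 1, 1, 1, 1, -1, -1)))
  ref <- converge_balanced(clean)$values
  # where the consensus takes a side on a pair not touching the flipped edge's
  # conflict, its sign must agree with the balanced reference
  off_diag <- row(cons$values) != col(cons$values)
  probe <- off_diag & cons$values != 0
  agree <- sign(cons$values[probe]) == sign(ref[probe])
  expect_gt(mean(agree), 0.6)
})
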