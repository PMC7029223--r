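test_that("interaction matrices respect the requested connectivity", {
  ds <- generate_glv(n_species = 100, seed = 5)
  A <- ds$interaction_matrix
  expect_equal(diag(A), rep(-1, 100))
  off <- A[row(A) != col(A)]
  n_links <- sum(off != 0)
  # binomial tolerance: 0.05 * 100 * 99 = 495 expected, sd ~ 21.7
  expect_gt(n_links, 495 - 4 * 22)
  expect_lt(n_links, 495 + 4 * 22)
})

test_that("gLV datasets are nonnegative, labelled, and bit-reproducible", {
  d1 <- generate_glv(n_species = 40, samples_per_condition = 15, seed = 9)
  d2 <- generate_glv(n_species = 40, samples_per_condition = 15, seed = 9)
  expect_identical(d1$abundances, d2$abundances)
  expect_identical(d1$truth, d2$truth)
  expect_true(all(d1$abundances >= 0))
  expect_equal(dim(d1$abundances), c(40, 30))
  expect_setequal(d1$truth$node, rownames(d1$abundances))
  expect_equal(length(unique(d1$truth$cluster)), 2)
  expect_equal(table(d1$condition_labels),
               table(rep(c("condition_1", "condition_2"), each = 15)))
})

test_that("without interactions or factors, survivors settle at carrying capacity", {
  # a_ij = 0 for i != j and no environmental effects: the logistic fixed
  # point is x* = b (diagonal -1), identical across conditions
  ds <- generate_glv(n_species = 30, samples_per_condition = 10, seed = 3,
                     interaction_strength = 0, frac_affected = 0,
                     t_end = 60)
  growth_free <- apply(ds$abundances, 1, max)
  # species with decent positive growth must sit near their capacity
  final <- ds$abundances[growth_free > 0.3, ]
  spread <- apply(final, 1, function(x) diff(range(x)))
  expect_true(all(spread < 1e-3))
})

test_that("bicluster data carries planted structure in the inferred network", {
  ds <- generate_biclusters(n_features = 40, n_samples = 60, n_clusters = 2,
                            signal = 6, seed = 2)
  expect_true(all(ds$abundances >= 0))
  g <- infer_network(ds$abundances)
  truth <- setNames(ds$truth$cluster, ds$truth$node)
  same <- truth[g$edges$from] == truth[g$edges$to]
  strong <- abs(g$edges$weight) > 0.5
  # strong within-block edges positive, strong cross-block edges negative
  expect_gt(mean(g$edges$weight[same & strong] > 0), 0.95)
  expect_gt(mean(g$edges$weight[!same & strong] < 0), 0.95)
})

test_that("zero-signal biclusters leave only the type-I edge rate", {
  ds <- generate_biclusters(n_features = 40, n_samples = 60, n_clusters = 2,
                            signal = 0, seed = 4)
  g <- infer_network(ds$abundances)
  rate <- n_edges(g) / choose(40, 2)
  # null edge rate ~ alpha = 0.05; binomial sd ~ 0.0078
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / choose(40, 2)))
  expect_false(any(is.na(ds$truth$cluster)))
})

test_that("overlapping planted blocks are rejected", {
  expect_error(generate_biclusters(n_features = 20, n_clusters = 2,
                                   positions = list(1:12, 10:20)),
               "disjoint")
})

test_that("bicluster generation is seeded", {
  expect_identical(generate_biclusters(seed = 11)$abundances,
                   generate_biclusters(seed = 11)$abundances)
})

test_that("perfect and anti-correlated rows make signed edges; constants drop", {
  base <- withr::with_seed(1, matrix(rnorm(60), 3, 20))
  x <- rbind(base[1, ], base[1, ] * 2 + 5, -base[1, ], base[2, ],
             rep(1, 20))
  rownames(x) <- c("r1", "dup", "anti", "noise", "const")
  expect_warning(g <- infer_network(x), "constant")
  expect_false("const" %in% g$nodes)
  w <- setNames(g$edges$weight, paste(g$edges$from, g$edges$to))
  expect_equal(unname(w["dup r1"]), 1)
  expect_equal(unname(w["anti r1"]), -1)
})

test_that("permutation noise: identity at 0, multiset preserved at 1, counted at 0.5", {
  x <- withr::with_seed(2, matrix(runif(200), 10, 20))
  expect_identical(permute_fraction(x, 0), x)
  full <- permute_fraction(x, 1, seed = 3)
  expect_equal(sort(as.vector(full)), sort(as.vector(x)))
  half <- permute_fraction(x, 0.5, seed = 3)
  expect_equal(sort(as.vector(half)), sort(as.vector(x)))
  expect_lte(sum(half != x), ceiling(0.5 * 200))
  expect_gt(sum(half != x), 0)
  expect_identical(half, permute_fraction(x, 0.5, seed = 3))
})

test_that("multinomial noise preserves totals, zeros, and proportions in the limit", {
  x <- withr::with_seed(4, matrix(rexp(50), 10, 5))
  x[3, ] <- 0
  counts <- add_multinomial_noise(x, scale = 1000, seed = 6)
  expect_equal(colSums(counts), round(1000 * colSums(x)))
  expect_true(all(counts[3, ] == 0))
  big <- add_multinomial_noise(x, scale = 1e6, seed = 6)
  props <- big[, 1] / sum(big[, 1])
  expect_equal(props, x[, 1] / sum(x[, 1]), tolerance = 1e-2)
})

test_that("weight shifting maps [-1, 1] onto [0, 1] affinely", {
  g <- signed_graph(data.frame(from = c("a", "a", "b"),
                               to = c("b", "c", "c"),
                               weight = c(1, -0.5, 0.0001)))
  gs <- shift_weights(g)
  w <- setNames(gs$edges$weight, paste(gs$edges$from, gs$edges$to))
  expect_equal(unname(w["a b"]), 1)
  expect_equal(unname(w["a c"]), 0.25)
  expect_equal(unname(w["b c"]), 0.50005)
  # an exact -1 maps to weight 0 and is dropped as uninformative
  gneg <- signed_graph(data.frame(from = c("a", "a"), to = c("b", "c"),
                                  weight = c(-1, 0.5)))
  expect_warning(gs2 <- shift_weights(gneg), "zero-weight")
  expect_equal(nrow(gs2$edges), 1)
})

test_that("gLV benchmark medians: separation above 0.5 and sparsity beats random", {
  bm <- run_benchmark(generator = "glv", replicates = 10, seed = 1,
                      n_species = 100)
  expect_true(all(bm$clustered))
  expect_gt(median(bm$sep, na.rm = TRUE), 0.5)
  # compare against a random 2-partition of the same graphs
  rep_seeds <- withr::with_seed(1, sample.int(.Machine$integer.max - 1L, 10))
  rand_sparsity <- vapply(rep_seeds, function(s) {
    ds <- generate_glv(seed = s, n_species = 100)
    g <- suppressWarnings(infer_network(ds$abundances))
    memb <- withr::with_seed(s, tibble::tibble(
      node = g$nodes, cluster = sample(0:1, length(g$nodes), replace = TRUE)))
    sparsity_score(g, memb)
  }, numeric(1))
  expect_gt(median(bm$sparsity, na.rm = TRUE), median(rand_sparsity))
})
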