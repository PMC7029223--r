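#' Simulate species abundances with generalized Lotka-Volterra dynamics
#'
#' Generates a ground-truthed benchmark dataset: a random species interaction
#' matrix (self-limiting diagonal, off-diagonal entries present with
#' probability `connectivity`) drives the gLV system
#' \deqn{dx/dt = x \circ (b + A x)}
#' whose growth rates `b` differ between environmental conditions. Three
#' environmental factors act on growth: each factor affects a random subset
#' of species (`frac_affected`), with per-species factor effects drawn from
#' N(1, 1) and factor strengths from N(3, 1); in each condition one factor is
#' positively weighted and the remaining ones negative, with the positive
#' slot rotated across conditions so every condition's cumulative effect
#' vector is unique. Species untouched by any factor keep their base growth
#' rate (Uniform(0, 1)) in every condition, so their covariance is driven by
#' the sparse interaction matrix alone — the resulting correlation networks
#' combine a dense environmentally induced signed core with a weakly
#' attached, interaction-driven periphery. Each sample is the endpoint of a
#' fixed-step Euler integration from random initial abundances
#' (initial-condition variation supplies within-condition variability);
#' species below the extinction threshold at the endpoint are recorded as
#' absent. Interaction matrices that cause population explosions are
#' regenerated, up to a retry budget.
#'
#' Ground-truth cluster labels are obtained by K-means on the species
#' abundance profiles with k = `n_conditions` (10 restarts, seeded).
#'
#' @param n_species number of species. Default 100.
#' @param n_conditions number of environmental conditions (>= 2). Default 2.
#' @param connectivity probability of an off-diagonal interaction.
#'   Default 0.05.
#' @param samples_per_condition samples simulated per condition. Default 50.
#' @param seed integer seed; the dataset is bit-reproducible from it.
#' @param interaction_strength half-width of the uniform interaction-weight
#'   distribution (diagonal is -1). Default 0.5.
#' @param frac_affected probability that an environmental factor affects a
#'   given species. Default 0.3.
#' @param t_end,dt integration horizon and Euler step. Defaults 5 and 0.01
#'   (near-steady endpoints on the O(1) growth-rate timescale).
#' @param extinction_threshold endpoint abundances below this are set to 0.
#'   Default 1e-6.
#' @param retry_budget regenerations allowed before giving up. Default 100.
#' @return object of class `synthetic_dataset`: list with `abundances`
#'   (species x samples matrix, nonnegative), `truth` (tibble `node`,
#'   `cluster`), `interaction_matrix`, `condition_labels` (per sample),
#'   `params`.
#' @export
generate_glv <- function(n_species = 100, n_conditions = 2,
                         connectivity = 0.05, samples_per_condition = 50,
                         seed = 1L, interaction_strength = 0.5,
                         frac_affected = 0.3, t_end = 5, dt = 0.01,
                         extinction_threshold = 1e-6, retry_budget = 100) {
  stopifnot(connectivity > 0, connectivity < 1, n_conditions >= 2,
            n_species >= 2, samples_per_condition >= 2)
  n_factors <- 3
  res <- withr::with_seed(seed, {
    base_growth <- stats::runif(n_species, 0, 1)
    affected <- matrix(stats::runif(n_species * n_factors) < frac_affected,
                       n_species, n_factors)
    effects <- matrix(stats::rnorm(n_species * n_factors, mean = 1, sd = 1),
                      n_species, n_factors) * affected
    strengths <- abs(stats::rnorm(n_factors, mean = 3, sd = 1))
    growth <- vapply(seq_len(n_conditions), function(cond) {
      signs <- rep(-1, n_factors)
      signs[(cond - 1) %% n_factors + 1] <- 1
      base_growth + as.numeric(effects %*% (signs * strengths))
    }, numeric(n_species))

    for (attempt in seq_len(retry_budget)) {
      A <- matrix(0, n_species, n_species)
      mask <- matrix(stats::runif(n_species^2) < connectivity,
                     n_species, n_species)
      diag(mask) <- FALSE
      A[mask] <- stats::runif(sum(mask), -interaction_strength,
                              interaction_strength)
      diag(A) <- -1

      ok <- TRUE
      blocks <- vector("list", n_conditions)
      for (cond in seq_len(n_conditions)) {
        x0 <- matrix(stats::runif(n_species * samples_per_condition, 0, 1),
                     n_species, samples_per_condition)
        xs <- integrate_glv(x0, growth[, cond], A, t_end, dt)
        if (is.null(xs)) { ok <- FALSE; break }
        xs[xs < extinction_threshold] <- 0
        blocks[[cond]] <- xs
      }
      if (ok) break
    }
    if (!ok) {
      stop("gLV generation failed: every interaction matrix in the retry ",
           "budget caused a population explosion", call. = FALSE)
    }
    abund <- do.call(cbind, blocks)
    species <- sprintf("sp%03d", seq_len(n_species))
    rownames(abund) <- species
    cond_lab <- rep(sprintf("condition_%d", seq_len(n_conditions)),
                    each = samples_per_condition)
    colnames(abund) <- sprintf("%s_s%02d", cond_lab,
                               rep(seq_len(samples_per_condition),
                                   n_conditions))
    km <- stats::kmeans(abund, centers = n_conditions, nstart = 10)
    list(abundances = abund,
         truth = tibble::tibble(node = species,
                                cluster = as.integer(km$cluster) - 1L),
         interaction_matrix = A, condition_labels = cond_lab)
  })
  structure(c(res, list(params = list(
    generator = "glv", n_species = n_species, n_conditions = n_conditions,
    connectivity = connectivity,
    samples_per_condition = samples_per_condition, seed = seed,
    interaction_strength = interaction_strength,
    frac_affected = frac_affected, t_end = t_end, dt = dt,
    extinction_threshold = extinction_threshold
  ))), class = "synthetic_dataset")
}

# fixed-step Euler on all samples of a condition at once; extinction floor at
# zero; NULL signals a population explosion (abundance > 1e6 x initial total)
integrate_glv <- function(x0, b, A, t_end, dt) {
  x <- x0
  cap <- 1e6 * sum(x0)
  steps <- ceiling(t_end / dt)
  check_every <- 50L
  for (s in seq_len(steps)) {
    x <- x + dt * x * (b + A %*% x)
    x[x < 0] <- 0
    if (s %% check_every == 0L || s == steps) {
      if (!all(is.finite(x)) || max(x) > cap) return(NULL)
    }
  }
  x
}

#' Generate planted-bicluster abundance data
#'
#' Adapted bicluster design: a Gaussian background matrix receives additive
#' signal blocks at fixed feature positions, each block activated over its
#' own window of samples with positive feature and sample loadings. Features
#' of one block co-vary positively; features of blocks active in disjoint
#' sample windows anti-correlate, so negative edges arise by construction.
#' Because correlation networks inferred from such data have no underlying
#' interaction topology, they are much more densely connected than the gLV
#' networks. The whole matrix is shifted by its minimum so abundances are
#' nonnegative (Pearson and Spearman correlations are shift-invariant).
#'
#' @param n_features,n_samples matrix dimensions. Defaults 100 and 100.
#' @param n_clusters number of planted blocks. Default 2.
#' @param positions optional list of disjoint feature-index vectors, one per
#'   block; defaults to an even split of all features. Overlapping blocks are
#'   an error.
#' @param signal signal amplitude added inside blocks. Default 3.
#' @param noise_sd background standard deviation. Default 1.
#' @param seed integer seed.
#' @return a `synthetic_dataset` (no interaction matrix; `truth` labels
#'   features by block).
#' @export
generate_biclusters <- function(n_features = 100, n_samples = 100,
                                n_clusters = 2, positions = NULL,
                                signal = 3, noise_sd = 1, seed = 1L) {
  stopifnot(n_features >= 2, n_samples >= 3, n_clusters >= 1)
  if (is.null(positions)) {
    positions <- split(seq_len(n_features),
                       cut(seq_len(n_features), n_clusters, labels = FALSE))
  }
  stopifnot(length(positions) == n_clusters)
  all_feats <- unlist(positions)
  if (anyDuplicated(all_feats)) {
    stop("planted blocks must be disjoint in feature space", call. = FALSE)
  }
  windows <- split(seq_len(n_samples),
                   cut(seq_len(n_samples), n_clusters, labels = FALSE))
  res <- withr::with_seed(seed, {
    x <- matrix(stats::rnorm(n_features * n_samples, sd = noise_sd),
                n_features, n_samples)
    for (b in seq_len(n_clusters)) {
      u <- stats::runif(length(positions[[b]]), 0.8, 1.2)
      z <- stats::runif(length(windows[[b]]), 0.8, 1.2)
      x[positions[[b]], windows[[b]]] <-
        x[positions[[b]], windows[[b]]] + signal * (u %o% z)
    }
    x - min(x)
  })
  features <- sprintf("f%03d", seq_len(n_features))
  rownames(res) <- features
  colnames(res) <- sprintf("s%03d", seq_len(n_samples))
  truth_cl <- rep(NA_integer_, n_features)
  for (b in seq_len(n_clusters)) truth_cl[positions[[b]]] <- b - 1L
  structure(list(
    abundances = res,
    truth = tibble::tibble(node = features, cluster = truth_cl),
    interaction_matrix = NULL,
    condition_labels = rep(sprintf("window_%d", seq_len(n_clusters)),
                           lengths(windows)),
    params = list(generator = "biclusters", n_features = n_features,
                  n_samples = n_samples, n_clusters = n_clusters,
                  signal = signal, noise_sd = noise_sd, seed = seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s: %d species x %d samples, %d true cluster(s)\n",
              x$params$generator, nrow(x$abundances), ncol(x$abundances),
              length(unique(x$truth$cluster))))
  invisible(x)
}

#' Infer a signed correlation network from an abundance matrix
#'
#' Computes all pairwise Pearson or Spearman correlations between species
#' (rows), keeps pairs whose two-sided p-value (t approximation on the
#' correlation coefficient) is below `alpha`, and uses the correlation
#' coefficient as the signed edge weight. Constant rows have no defined
#' correlation and are excluded with a warning.
#'
#' @param abundances species x samples numeric matrix with row names, or a
#'   `synthetic_dataset`.
#' @param method `"pearson"` or `"spearman"`.
#' @param alpha significance threshold. Default 0.05.
#' @return a [signed_graph()] over the non-constant species (isolated species
#'   are kept as unconnected nodes).
#' @export
infer_network <- function(abundances, method = c("pearson", "spearman"),
                          alpha = 0.05) {
  if (inherits(abundances, "synthetic_dataset")) {
    abundances <- abundances$abundances
  }
  method <- match.arg(method)
  stopifnot(is.matrix(abundances), ncol(abundances) >= 3,
            !is.null(rownames(abundances)))
  sds <- apply(abundances, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant row(s) excluded: correlation undefined",
            call. = FALSE)
    abundances <- abundances[sds > 0, , drop = FALSE]
  }
  n <- ncol(abundances)
  r <- stats::cor(t(abundances), method = method)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  keep <- upper.tri(r) & p < alpha
  idx <- which(keep, arr.ind = TRUE)
  edges <- data.frame(from = rownames(r)[idx[, 1]],
                      to = rownames(r)[idx[, 2]],
                      weight = r[keep])
  signed_graph(edges, nodes = rownames(abundances))
}

#' Permute a fraction of abundance-matrix entries
#'
#' Shuffles the values at `ceiling(fraction * n_cells)` uniformly chosen
#' positions among themselves (the noise gradient of the permutation
#' benchmark). `scope` restricts the shuffle to within rows or columns.
#'
#' @param abundances numeric matrix.
#' @param fraction fraction of cells to permute, in \[0, 1\]. 0 is the
#'   identity.
#' @param seed integer seed.
#' @param scope `"global"` (default), `"rows"` or `"columns"`.
#' @return matrix of the same shape; the multiset of values is preserved.
#' @export
permute_fraction <- function(abundances, fraction, seed = 1L,
                             scope = c("global", "rows", "columns")) {
  stopifnot(is.matrix(abundances), fraction >= 0, fraction <= 1)
  scope <- match.arg(scope)
  if (fraction == 0) return(abundances)
  withr::with_seed(seed, {
    if (scope == "global") {
      ncell <- length(abundances)
      idx <- sample.int(ncell, ceiling(fraction * ncell))
      abundances[idx] <- abundances[sample(idx)]
    } else if (scope == "rows") {
      for (i in seq_len(nrow(abundances))) {
        m <- ncol(abundances)
        idx <- sample.int(m, ceiling(fraction * m))
        abundances[i, idx] <- abundances[i, sample(idx)]
      }
    } else {
      for (j in seq_len(ncol(abundances))) {
        m <- nrow(abundances)
        idx <- sample.int(m, ceiling(fraction * m))
        abundances[idx, j] <- abundances[sample(idx), j]
      }
    }
    abundances
  })
}

#' Resample abundances with multinomial noise
#'
#' Emulates sequencing-count noise: per sample, counts are drawn from a
#' multinomial with probabilities proportional to the sample's abundances and
#' a total of `scale` times the original sample total. Zero-abundance species
#' stay zero; as `scale` grows, proportions are recovered.
#'
#' @param abundances nonnegative species x samples matrix.
#' @param scale total-count multiplier. Default 1000.
#' @param seed integer seed.
#' @return integer count matrix of the same shape.
#' @export
add_multinomial_noise <- function(abundances, scale = 1000, seed = 1L) {
  stopifnot(is.matrix(abundances), all(abundances >= 0), scale > 0)
  withr::with_seed(seed, {
    out <- abundances
    for (j in seq_len(ncol(abundances))) {
      tot <- sum(abundances[, j])
      if (tot == 0) { out[, j] <- 0; next }
      out[, j] <- stats::rmultinom(1, size = round(scale * tot),
                                   prob = abundances[, j] / tot)
    }
    out
  })
}

#' Shift edge weights from \[-1, 1\] to \[0, 1\]
#'
#' Affine map `w' = (w + 1) / 2`, the transformation used to test how
#' clustering algorithms fare when the sign information of a correlation
#' network is encoded as magnitude instead. A weight of exactly -1 maps to 0
#' and is dropped (zero weights carry no information), with a warning.
#'
#' @param g a `signed_graph`.
#' @return a `signed_graph` with weights in (0, 1\].
#' @export
shift_weights <- function(g) {
  stopifnot(is_signed_graph(g))
  e <- g$edges
  e$weight <- (e$weight + 1) / 2
  signed_graph(e, nodes = g$nodes)
}

#' Approximated node connectivity of a network
#'
#' Vertex connectivity (minimum number of nodes whose removal disconnects the
#' graph) of the largest connected component — the topology summary that
#' separates the sparse interaction-driven gLV networks (median 1) from the
#' dense bicluster networks.
#'
#' @param g a `signed_graph`.
#' @return integer connectivity; 0 for graphs whose largest component has
#'   fewer than 2 nodes.
#' @export
node_connectivity_approx <- function(g) {
  stopifnot(is_signed_graph(g))
  ig <- as_igraph(g)
  comps <- igraph::components(ig)
  if (max(comps$csize) < 2) return(0L)
  big <- which.max(comps$csize)
  sub <- igraph::induced_subgraph(ig, which(comps$membership == big))
  as.integer(igraph::vertex_connectivity(sub))
}
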