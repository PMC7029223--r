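#' Evaluate a cluster assignment against ground truth
#'
#' Contingency-table metrics for comparing predicted clusters with
#' ground-truth clusters over the same node universe. With contingency matrix
#' \eqn{T}, \eqn{t_{ij} = |truth_i \cap predicted_j|}:
#' * complex-wise sensitivity `Sn` — coverage of each true cluster by its
#'   best-matching predicted cluster, size-weighted;
#' * cluster-wise positive predictive value `PPV` — how well each predicted
#'   cluster covers its best-matching true cluster, size-weighted;
#' * geometric accuracy `Acc = sqrt(Sn * PPV)`;
#' * separation `Sep` — the geometric mean of row-wise and column-wise sums
#'   of \eqn{(t_{ij}/t_{i\cdot})(t_{ij}/t_{\cdot j})}, which penalizes
#'   cluster overlap and mixing; a perfect assignment scores 1.
#'
#' Weakly assigned nodes count as unassigned and are excluded from the
#' contingency table. Two pathological regimes are flagged rather than
#' scored blindly: a single predicted cluster holding more than 80% of the
#' assigned nodes, or more than 50 predicted clusters.
#'
#' @param predicted a `signed_clusters` or `cluster_assignment` object, or a
#'   data frame with columns `node`, `cluster` and optionally `weak`.
#' @param truth data frame with columns `node`, `cluster` (or a named
#'   vector).
#' @return one-row tibble: `sn`, `ppv`, `acc`, `sep`, `sparsity` (taken from
#'   the fitted object when available, else `NA`), `n_assigned`,
#'   `pathological`, `pathological_reason`.
#' @export
evaluate_clusters <- function(predicted, truth) {
  sparsity <- NA_real_
  if (inherits(predicted, c("signed_clusters", "cluster_assignment"))) {
    sparsity <- predicted$sparsity
    pred_tbl <- predicted$membership
  } else {
    pred_tbl <- tibble::as_tibble(predicted)
  }
  stopifnot(all(c("node", "cluster") %in% names(pred_tbl)))
  if (nrow(pred_tbl) == 0) stop("empty prediction", call. = FALSE)
  if (!"weak" %in% names(pred_tbl)) pred_tbl$weak <- FALSE
  truth_v <- membership_vector(truth)

  # pathological filters judged on the assigned (non-weak) prediction
  assigned <- pred_tbl[!pred_tbl$weak, ]
  if (nrow(assigned) == 0) stop("no assigned (non-weak) nodes", call. = FALSE)
  sizes <- table(assigned$cluster)
  reason <- NA_character_
  if (max(sizes) > 0.8 * nrow(assigned)) {
    reason <- "one cluster holds >80% of assigned nodes"
  } else if (length(sizes) > 50) {
    reason <- ">50 clusters"
  }

  common <- intersect(assigned$node, names(truth_v))
  if (length(common) == 0) stop("prediction and truth share no nodes",
                                call. = FALSE)
  tt <- table(truth = truth_v[common],
              predicted = assigned$cluster[match(common, assigned$node)])
  tt <- unclass(tt)
  row_tot <- rowSums(tt)
  col_tot <- colSums(tt)
  sn <- sum(apply(tt, 1, max)) / sum(row_tot)
  ppv <- sum(apply(tt, 2, max)) / sum(col_tot)
  acc <- sqrt(sn * ppv)
  sep_m <- (tt / row_tot) * (tt / rep(col_tot, each = nrow(tt)))
  sep_row <- mean(rowSums(sep_m))
  sep_col <- mean(colSums(sep_m))
  sep <- sqrt(sep_row * sep_col)

  tibble::tibble(sn = sn, ppv = ppv, acc = acc, sep = sep,
                 sparsity = sparsity, n_assigned = nrow(assigned),
                 pathological = !is.na(reason),
                 pathological_reason = reason)
}

#' Run the synthetic clustering benchmark
#'
#' Generates ground-truthed datasets, optionally injects noise, infers a
#' significance-filtered correlation network from each, clusters it with the
#' full pipeline, and scores the assignment against the ground truth. One
#' tidy row per replicate.
#'
#' @param generator `"glv"` (interaction-driven dynamics) or `"fabia"`
#'   (planted biclusters, no interaction topology).
#' @param replicates number of independently seeded datasets. Default 10.
#' @param noise `"none"`, `"permute"` (entry permutation,
#'   see [permute_fraction()]), `"multinomial"` ([add_multinomial_noise()];
#'   networks are then inferred with Spearman correlation), or `"shift"`
#'   (weights mapped to \[0, 1\] with [shift_weights()]).
#' @param noise_level permuted fraction for `noise = "permute"`. Default 0.5.
#' @param alpha significance threshold for edges. Default 0.05.
#' @param method correlation method; defaults to Pearson except under
#'   multinomial noise, where Spearman is used.
#' @param seed master seed; replicate seeds derive from it.
#' @param edgescale weak-assignment threshold for the benchmark preset.
#'   Default 0.3.
#' @param diffusion,clustering parameter objects for the pipeline.
#' @param ... passed to the generator ([generate_glv()] or
#'   [generate_biclusters()]).
#' @return tibble with one row per replicate: seed, network summaries
#'   (`n_edges`, `frac_negative`, `node_connectivity`), fit summaries (`k`,
#'   `sparsity`, `n_weak`, `balanced`) and evaluation metrics (`sn`, `ppv`,
#'   `acc`, `sep`, `pathological`).
#' @export
run_benchmark <- function(generator = c("glv", "fabia"), replicates = 10,
                          noise = c("none", "permute", "multinomial", "shift"),
                          noise_level = 0.5, alpha = 0.05, method = NULL,
                          seed = 1L, edgescale = 0.3,
                          diffusion = diffusion_params(),
                          clustering = clustering_params(), ...) {
  generator <- match.arg(generator)
  noise <- match.arg(noise)
  if (is.null(method)) {
    method <- if (noise == "multinomial") "spearman" else "pearson"
  }
  rep_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, replicates))

  purrr::map_dfr(seq_len(replicates), function(r) {
    ds <- if (generator == "glv") {
      generate_glv(seed = rep_seeds[r], ...)
    } else {
      generate_biclusters(seed = rep_seeds[r], ...)
    }
    abund <- ds$abundances
    if (noise == "permute") {
      abund <- permute_fraction(abund, noise_level, seed = rep_seeds[r])
    } else if (noise == "multinomial") {
      abund <- add_multinomial_noise(abund, seed = rep_seeds[r])
    }
    g <- suppressWarnings(infer_network(abund, method = method, alpha = alpha))
    if (noise == "shift") g <- suppressWarnings(shift_weights(g))
    net_row <- tibble::tibble(
      replicate = r, seed = rep_seeds[r], generator = generator,
      noise = noise, n_nodes = n_nodes(g), n_edges = n_edges(g),
      frac_negative = if (n_edges(g) > 0) mean(g$edges$weight < 0) else NA_real_,
      node_connectivity = node_connectivity_approx(g))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        cluster_signed(g, diffusion = diffusion, clustering = clustering,
                       edgescale = edgescale))),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(dplyr::mutate(net_row, clustered = FALSE))
    }
    ev <- tryCatch(evaluate_clusters(fit, ds$truth), error = function(e) {
      tibble::tibble(sn = NA_real_, ppv = NA_real_, acc = NA_real_,
                     sep = NA_real_, pathological = TRUE)
    })
    dplyr::bind_cols(
      net_row,
      tibble::tibble(clustered = TRUE, balanced = fit$balanced, k = fit$k,
                     sparsity = fit$sparsity,
                     n_weak = sum(fit$membership$weak)),
      ev[, c("sn", "ppv", "acc", "sep", "pathological")])
  })
}
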