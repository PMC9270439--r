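# Hierarchical evaluation: per-threshold hierarchical precision/recall/F1
# over ancestor-closed predicted vs true term sets, the term-frequency null
# model, trained/null ratio curves, threshold selection and final
# most-specific predictions.

eval_roots <- function(truth, graph) {
  if (!is.null(truth$namespace) && truth$namespace %in% names(graph$roots)) {
    unname(graph$roots[[truth$namespace]])
  } else {
    unname(graph$roots)
  }
}

# Shared core: hPrec/hRec/hF1 at each threshold. Truth sets and predicted
# sets both include the ontology root(s), which are never scored terms.
hf_stats <- function(truth, scores, graph, thresholds) {
  genes <- rownames(scores)
  have <- unique(truth$assoc$gene_id)
  missing <- setdiff(genes, have)
  if (length(missing) > 0) {
    abort(paste0(
      "Scored gene(s) absent from the truth store: ",
      paste(head(missing, 5), collapse = ", ")
    ))
  }
  if (!truth$propagated) abort("`truth` must be a propagated annotation store.")
  roots <- eval_roots(truth, graph)
  n_roots <- length(roots)
  sets <- gene_term_sets(truth, genes)
  size_T <- vapply(sets, function(s) length(union(s, roots)), integer(1))
  terms <- colnames(scores)
  in_truth <- matrix(FALSE, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  for (i in seq_along(genes)) in_truth[i, ] <- terms %in% sets[[i]]

  hprec <- hrec <- hf1 <- numeric(length(thresholds))
  sum_T <- sum(size_T)
  for (j in seq_along(thresholds)) {
    P <- scores >= thresholds[[j]]
    tp <- sum(P & in_truth) + n_roots * length(genes)
    sz_p <- sum(P) + n_roots * length(genes)
    pr <- if (sz_p == 0) 0 else tp / sz_p
    rc <- if (sum_T == 0) 0 else tp / sum_T
    hprec[[j]] <- pr
    hrec[[j]] <- rc
    hf1[[j]] <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
  }
  tibble(threshold = thresholds, hprec = hprec, hrec = hrec, hf1 = hf1)
}

#' Hierarchical precision, recall and F1 at one threshold
#'
#' For each gene i, the predicted set P_i is the ontology root plus every
#' term scored at or above the threshold, and the true set T_i is the gene's
#' propagated annotation set plus the root. Then hPrec = sum |P_i ∩ T_i| /
#' sum |P_i|, hRec = sum |P_i ∩ T_i| / sum |T_i| and hF1 is their harmonic
#' mean (0/0 defined as 0).
#'
#' @param truth A propagated `annotation_store` covering every scored gene.
#' @param scores A hierarchy-consistent `score_matrix` for the evaluation
#'   genes.
#' @param threshold Classification threshold in \[0, 1\].
#' @param graph The companion `ontology_graph`.
#' @return A one-row tibble with `threshold`, `hprec`, `hrec`, `hf1`.
#' @export
hierarchical_prf <- function(truth, scores, threshold, graph) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single number in [0, 1].")
  }
  hf_stats(truth, scores, graph, threshold)
}

#' Hierarchical F1 curve over a threshold grid
#'
#' Evaluates [hierarchical_prf()] at every threshold of an ascending grid
#' and records the maximum hF1 (hF-max) and the smallest threshold
#' attaining it.
#'
#' @inheritParams hierarchical_prf
#' @param thresholds Ascending threshold grid in \[0, 1\]
#'   (default `seq(0, 1, 0.01)`).
#' @return A tibble of class `hf_curve` with columns `threshold`, `hprec`,
#'   `hrec`, `hf1` and attributes `hf_max` and `threshold_at_max`.
#' @export
hf_curve <- function(truth, scores, graph, thresholds = seq(0, 1, 0.01)) {
  if (length(thresholds) == 0) abort("`thresholds` must be non-empty.")
  if (is.unsorted(thresholds)) abort("`thresholds` must be ascending.")
  out <- hf_stats(truth, scores, graph, thresholds)
  best <- which.max(out$hf1)  # ties -> smallest threshold
  attr(out, "hf_max") <- out$hf1[[best]]
  attr(out, "threshold_at_max") <- out$threshold[[best]]
  class(out) <- c("hf_curve", class(out))
  out
}

#' @describeIn hf_curve One-row summary: hF-max and its threshold.
#' @param x An `hf_curve`.
#' @param ... Unused.
#' @export
glance.hf_curve <- function(x, ...) {
  best <- which.max(x$hf1)
  tibble(
    hf_max = x$hf1[[best]],
    threshold_at_max = x$threshold[[best]],
    hprec_at_max = x$hprec[[best]],
    hrec_at_max = x$hrec[[best]]
  )
}

#' Term-frequency null model scores
#'
#' The null predictor assigns every gene the same score for a term: the
#' term's relative annotation frequency among training genes. A term
#' annotated on 25% of training genes scores every evaluation gene 0.25.
#'
#' @param store A propagated `annotation_store`.
#' @param train_genes Character vector of training gene ids (the frequency
#'   base).
#' @param eval_genes Ordered character vector of genes to score.
#' @param terms Ordered character vector of terms to score.
#' @return A `score_matrix` with constant columns.
#' @export
random_scores <- function(store, train_genes, eval_genes, terms) {
  if (length(train_genes) == 0) abort("`train_genes` must be non-empty.")
  t_assoc <- store$assoc |>
    filter(.data$gene_id %in% train_genes, .data$term_id %in% terms) |>
    count(.data$term_id)
  freq <- setNames(rep(0, length(terms)), terms)
  freq[t_assoc$term_id] <- t_assoc$n / length(train_genes)
  m <- matrix(
    rep(freq, each = length(eval_genes)),
    nrow = length(eval_genes), ncol = length(terms),
    dimnames = list(eval_genes, terms)
  )
  structure(m, class = c("score_matrix", "matrix", "array"))
}

#' Ratio of trained to null hF1 across thresholds
#'
#' ratio(θ) = hF1_trained(θ) / hF1_null(θ) on the shared threshold grid.
#' Grid points where the null hF1 is 0 are undefined (`NA`) and excluded
#' from the argmax rather than treated as infinite. The selected threshold
#' θ* is the smallest defined argmax.
#'
#' @param trained An `hf_curve` for the trained model.
#' @param random An `hf_curve` for the null model, on the same grid.
#' @return A tibble of class `ratio_curve` with columns `threshold`,
#'   `hf1_trained`, `hf1_random`, `ratio`, and attributes `theta_star` and
#'   `max_ratio`.
#' @export
ratio_curve <- function(trained, random) {
  if (!isTRUE(all.equal(trained$threshold, random$threshold))) {
    abort("The two curves must share an identical threshold grid.")
  }
  out <- tibble(
    threshold = trained$threshold,
    hf1_trained = trained$hf1,
    hf1_random = random$hf1,
    ratio = ifelse(random$hf1 == 0, NA_real_, trained$hf1 / random$hf1)
  )
  if (all(is.na(out$ratio))) {
    attr(out, "theta_star") <- NA_real_
    attr(out, "max_ratio") <- NA_real_
  } else {
    best <- which.max(out$ratio)  # NAs never win; ties -> smallest threshold
    attr(out, "theta_star") <- out$threshold[[best]]
    attr(out, "max_ratio") <- out$ratio[[best]]
  }
  class(out) <- c("ratio_curve", class(out))
  out
}

#' @describeIn ratio_curve One-row summary: θ* and the maximum ratio.
#' @param x A `ratio_curve`.
#' @param ... Unused.
#' @export
glance.ratio_curve <- function(x, ...) {
  tibble(
    theta_star = attr(x, "theta_star"),
    max_ratio = attr(x, "max_ratio")
  )
}

#' Final most-specific predictions above a threshold
#'
#' Keeps every (gene, term) pair scoring at or above the threshold, then,
#' within each gene, drops any kept term that is an ancestor of another kept
#' term — retaining only the most specific prediction within each branch.
#' Roots are never emitted. Optionally drops pairs already present in a
#' store of known annotations.
#'
#' @param scores A hierarchy-consistent `score_matrix`.
#' @param threshold Classification threshold (typically θ* from
#'   [ratio_curve()]).
#' @param graph The companion `ontology_graph`.
#' @param known Optional `annotation_store` of already-known associations to
#'   exclude.
#' @return A tibble of class `prediction_set` with columns `gene_id`,
#'   `term_id`, `score`, `depth`, and attribute `threshold`.
#' @export
finalize_predictions <- function(scores, threshold, graph, known = NULL) {
  if (!is.numeric(threshold) || length(threshold) != 1L) {
    abort("`threshold` must be a single number.")
  }
  hits <- which(scores >= threshold, arr.ind = TRUE)
  out <- tibble(
    gene_id = rownames(scores)[hits[, 1L]],
    term_id = colnames(scores)[hits[, 2L]],
    score = scores[hits]
  ) |> filter(!.data$term_id %in% unname(graph$roots))
  if (!is.null(known)) {
    out <- anti_join(out, known$assoc, by = c("gene_id", "term_id"))
  }
  if (nrow(out) > 0) {
    out <- out |>
      group_by(.data$gene_id) |>
      filter(!.data$term_id %in%
               unique(unlist(graph$ancestors[.data$term_id], use.names = FALSE))) |>
      ungroup()
  }
  out <- out |>
    mutate(depth = term_depth(graph, .data$term_id)) |>
    arrange(.data$gene_id, .data$term_id)
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_set", class(out))
  out
}

#' Histogram of predictions by ontology depth
#'
#' Counts emitted predictions at every depth of the ontology, including
#' zero-count depths up to the ontology's maximum depth.
#'
#' @param preds A `prediction_set`.
#' @param graph The companion `ontology_graph`.
#' @return A tibble with columns `depth` and `n`.
#' @export
predictions_by_depth <- function(preds, graph) {
  max_depth <- max(graph$depth_shortest)
  counts <- as_tibble(preds) |> count(.data$depth)
  tibble(depth = 0:max_depth) |>
    left_join(counts, by = "depth") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' Write an evaluation curve TSV
#'
#' Columns `threshold`, `hprec`, `hrec`, `hf1`, `hf1_random`, `ratio`.
#' @param trained An `hf_curve` for the trained model.
#' @param ratio A `ratio_curve` on the same grid.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve_tsv <- function(trained, ratio, path) {
  out <- as_tibble(trained) |>
    left_join(
      as_tibble(ratio) |> select("threshold", "hf1_random", "ratio"),
      by = "threshold"
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' Write a prediction set TSV
#'
#' Columns `gene_id`, `term_id`, `score`, `depth`; the threshold used is
#' recorded in a header comment.
#' @param preds A `prediction_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_tsv <- function(preds, path) {
  writeLines(sprintf("# threshold=%g", attr(preds, "threshold")), path)
  readr::write_tsv(as_tibble(preds), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Plot an hF1 curve
#'
#' hPrec, hRec and hF1 against the classification threshold; the hF-max
#' point is marked.
#' @param object An `hf_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hf_curve <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("hprec", "hrec", "hf1"),
                        names_to = "metric", values_to = "value")
  best <- glance(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$threshold, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble(threshold = best$threshold_at_max, value = best$hf_max),
      ggplot2::aes(.data$threshold, .data$value), inherit.aes = FALSE
    ) +
    ggplot2::labs(x = "classification threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a trained/null ratio curve
#'
#' @param object A `ratio_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ratio_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$threshold, .data$ratio)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "classification threshold", y = "hF1 trained / hF1 null") +
    ggplot2::theme_minimal()
}

#' Plot predictions by ontology depth
#'
#' @param object A `prediction_set`.
#' @param graph The companion `ontology_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.prediction_set <- function(object, graph, ...) {
  ggplot2::ggplot(predictions_by_depth(object, graph),
                  ggplot2::aes(.data$depth, .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "ontology depth", y = "predicted associations") +
    ggplot2::theme_minimal()
}
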