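# Per-term binary classifiers: siblings-policy training sets, random-forest
# fits with grid search + stratified cross-validation, scoring, and DAG
# consistency of the resulting score matrix.

#' Siblings-policy training set for one target term
#'
#' Positives are the training genes annotated (after propagation) with the
#' target term. Negatives are training genes annotated with at least one
#' sibling or uncle of the target and not with the target itself — genes
#' known to do something related but different, which makes them informative
#' negatives. If no such gene exists, the documented fallback samples
#' negatives uniformly from training genes not annotated with the target
#' (as many as there are positives), which is logged.
#'
#' @param graph An `ontology_graph`.
#' @param store A propagated `annotation_store` (only training-gene rows are
#'   consulted).
#' @param split A `train_eval_split`.
#' @param target Target term id.
#' @param seed Seed for the fallback sampler (default 1).
#' @return An object of class `training_set` with elements `target`,
#'   `positives`, `negatives` and logical `fallback`.
#' @export
siblings_training_set <- function(graph, store, split, target, seed = 1L) {
  check_term(graph, target)
  t_assoc <- store$assoc |> filter(.data$gene_id %in% split$train)
  positives <- unique(t_assoc$gene_id[t_assoc$term_id == target])
  neg_terms <- union(
    relatives(graph, target, "siblings"),
    relatives(graph, target, "uncles")
  )
  negatives <- setdiff(
    unique(t_assoc$gene_id[t_assoc$term_id %in% neg_terms]),
    positives
  )
  fallback <- FALSE
  if (length(negatives) == 0) {
    fallback <- TRUE
    pool <- setdiff(split$train, positives)
    n_take <- min(length(positives), length(pool))
    negatives <- with_seed(derive_seed(seed, paste0("negfallback:", target)),
                           sample(pool, n_take))
    inform(sprintf(
      "Target %s has no sibling/uncle negatives; sampled %d fallback negative(s).",
      target, length(negatives)
    ))
  }
  structure(
    list(
      target = target, positives = sort(positives),
      negatives = sort(negatives), fallback = fallback
    ),
    class = "training_set"
  )
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf(
    "<training_set> target %s: %d positives, %d negatives%s\n",
    x$target, length(x$positives), length(x$negatives),
    if (x$fallback) " (fallback negatives)" else ""
  ))
  invisible(x)
}

#' Default random-forest hyperparameter grid
#'
#' Tree count, maximum depth (0 = unlimited) and split rule. The split-rule
#' axis is limited to the criteria the ranger backend implements; the whole
#' grid is configuration, not a fixed constant.
#'
#' @param num_trees Tree counts to try.
#' @param max_depth Maximum depths to try (0 means unlimited).
#' @param splitrule Split criteria to try (any of ranger's
#'   `"gini"`, `"extratrees"`, `"hellinger"`).
#' @return A tibble with one row per grid point.
#' @export
default_grid <- function(num_trees = c(100L, 200L, 500L),
                         max_depth = c(5L, 10L, 0L),
                         splitrule = "gini") {
  tidyr::expand_grid(
    num_trees = as.integer(num_trees),
    max_depth = as.integer(max_depth),
    splitrule = splitrule
  )
}

binary_f1 <- function(truth, pred) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Fit one per-term random-forest classifier
#'
#' Selects the grid point maximising mean F1 of the positive class across
#' stratified cross-validation folds (probability threshold 0.5), then
#' refits on all examples. Deterministic given `seed`. With a single grid
#' point the cross-validation is reporting only; pass `folds = 0` to skip it.
#'
#' @param features Numeric matrix (examples x features).
#' @param labels Logical vector (`TRUE` = positive), one per row.
#' @param grid Hyperparameter grid from [default_grid()].
#' @param folds Number of CV folds (default 3; 0 skips CV, allowed only for
#'   a single-point grid).
#' @param seed Integer seed.
#' @param target Optional term id, used in error messages.
#' @return An object of class `term_model`.
#' @export
fit_term_model <- function(features, labels, grid = default_grid(),
                           folds = 3L, seed = 1L, target = NULL) {
  labels <- as.logical(labels)
  if (length(labels) != nrow(features)) abort("`labels` length must match feature rows.")
  if (length(unique(labels)) < 2L) {
    abort(sprintf(
      "Training set for term %s has a single class; cannot fit.",
      target %||% "<unknown>"
    ))
  }
  if (sum(labels) < 2L || sum(!labels) < 2L) {
    abort(sprintf(
      "Term %s needs at least 2 examples per class.", target %||% "<unknown>"
    ))
  }
  grid <- as_tibble(grid)
  if (folds == 0L && nrow(grid) > 1L) {
    abort("`folds = 0` is only allowed with a single-point grid.")
  }

  y <- factor(ifelse(labels, "pos", "neg"), levels = c("neg", "pos"))
  fit_one <- function(x, yy, p, fit_seed) {
    ranger::ranger(
      x = x, y = yy, probability = TRUE,
      num.trees = p$num_trees,
      max.depth = if (p$max_depth == 0L) NULL else p$max_depth,
      splitrule = p$splitrule,
      seed = fit_seed, num.threads = 1L, verbose = FALSE
    )
  }

  cv_scores <- rep(NA_real_, nrow(grid))
  if (folds > 0L) {
    # stratified fold assignment, deterministic given seed
    fold_id <- integer(length(labels))
    fold_id[labels] <- with_seed(
      derive_seed(seed, "folds-pos"),
      sample(rep_len(seq_len(folds), sum(labels)))
    )
    fold_id[!labels] <- with_seed(
      derive_seed(seed, "folds-neg"),
      sample(rep_len(seq_len(folds), sum(!labels)))
    )
    for (gi in seq_len(nrow(grid))) {
      p <- grid[gi, ]
      f1s <- vapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        if (length(unique(y[tr])) < 2L) return(NA_real_)
        fit <- fit_one(features[tr, , drop = FALSE], y[tr], p,
                       derive_seed(seed, sprintf("cv:%d:%d", gi, f)))
        prob <- predict(fit, data = features[!tr, , drop = FALSE],
                        num.threads = 1L)$predictions[, "pos"]
        binary_f1(labels[!tr], prob >= 0.5)
      }, double(1))
      cv_scores[[gi]] <- mean(f1s, na.rm = TRUE)
    }
    best <- which.max(cv_scores)  # ties -> first grid row
  } else {
    best <- 1L
  }

  chosen <- grid[best, ]
  fit <- fit_one(features, y, chosen, derive_seed(seed, "final"))
  structure(
    list(
      target = target, fit = fit, params = chosen,
      cv_f1 = cv_scores[[best]], grid = grid, cv_scores = cv_scores,
      n_pos = sum(labels), n_neg = sum(!labels),
      seed = as.integer(seed), feature_names = colnames(features)
    ),
    class = "term_model"
  )
}

#' @export
print.term_model <- function(x, ...) {
  cat(sprintf(
    "<term_model> %s: %d+/%d- examples, trees=%d depth=%s rule=%s, CV F1 %s\n",
    x$target %||% "?", x$n_pos, x$n_neg,
    x$params$num_trees,
    ifelse(x$params$max_depth == 0L, "unlimited", x$params$max_depth),
    x$params$splitrule,
    ifelse(is.na(x$cv_f1), "NA", sprintf("%.3f", x$cv_f1))
  ))
  invisible(x)
}

#' @describeIn fit_term_model Grid points with their CV scores; the chosen
#'   point is flagged.
#' @param x A `term_model`.
#' @param ... Unused.
#' @export
tidy.term_model <- function(x, ...) {
  x$grid |>
    mutate(
      cv_f1 = x$cv_scores,
      chosen = .data$num_trees == x$params$num_trees &
        .data$max_depth == x$params$max_depth &
        .data$splitrule == x$params$splitrule
    )
}

#' @describeIn fit_term_model One-row fit summary.
#' @export
glance.term_model <- function(x, ...) {
  tibble(
    target = x$target %||% NA_character_,
    n_pos = x$n_pos, n_neg = x$n_neg,
    num_trees = x$params$num_trees, max_depth = x$params$max_depth,
    splitrule = x$params$splitrule, cv_f1 = x$cv_f1, seed = x$seed
  )
}

#' Train one classifier per eligible term
#'
#' For each target term: build the siblings-policy training set, compute the
#' FLA feature matrix on the masked store, and fit a random forest with grid
#' search. Per-term seeds are derived from the master seed and the term id,
#' so terms can be trained in any order (or in parallel) with identical
#' results. Per-term failures (e.g. degenerate training sets) are logged and
#' skipped, not fatal.
#'
#' @param model A `genome_model`.
#' @param store A propagated `annotation_store` with evaluation genes masked.
#' @param graph The companion `ontology_graph`.
#' @param split A `train_eval_split`.
#' @param targets Character vector of target term ids (e.g. from
#'   [eligible_terms()]).
#' @param grid Hyperparameter grid, see [default_grid()].
#' @param folds CV folds (default 3; 0 skips CV for single-point grids).
#' @param seed Master seed.
#' @param half_widths FLA window half-widths.
#' @param mode FLA column-set mode, see [fla_term_set()].
#' @return A tibble of class `term_model_set`: one row per trained term with
#'   fit metadata and the fitted `term_model` in a list column `model`.
#' @export
train_term_models <- function(model, store, graph, split, targets,
                              grid = default_grid(), folds = 3L, seed = 1L,
                              half_widths = c(5, 10, 20, 50, 100),
                              mode = c("relatives_down", "relatives_up")) {
  mode <- match.arg(mode)
  rows <- list()
  for (target in targets) {
    res <- tryCatch({
      ts <- siblings_training_set(graph, store, split, target,
                                  seed = derive_seed(seed, target))
      genes <- c(ts$positives, ts$negatives)
      labels <- c(rep(TRUE, length(ts$positives)), rep(FALSE, length(ts$negatives)))
      feats <- build_feature_matrix(
        model, store, genes, target, graph,
        half_widths = half_widths, mode = mode
      )
      tm <- fit_term_model(
        feats, labels, grid = grid, folds = folds,
        seed = derive_seed(seed, paste0("fit:", target)), target = target
      )
      glance(tm) |> mutate(fallback_negatives = ts$fallback, model = list(tm))
    }, error = function(e) {
      warn(sprintf("Skipping term %s: %s", target, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows) == 0) abort("No term model could be trained.")
  out <- bind_rows(rows)
  attr(out, "half_widths") <- half_widths
  attr(out, "mode") <- mode
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("term_model_set", class(out))
  out
}

#' @describeIn train_term_models One-row summary of a model set.
#' @param x A `term_model_set`.
#' @param ... Unused.
#' @export
glance.term_model_set <- function(x, ...) {
  tibble(
    n_terms = nrow(x),
    mean_cv_f1 = mean(x$cv_f1, na.rm = TRUE),
    n_fallback = sum(x$fallback_negatives),
    seed = attr(x, "seed")
  )
}

#' Score genes with a set of per-term models
#'
#' Builds each gene's FLA features (on the same masked store used in
#' training) and collects the positive-class probability of every term
#' model, yielding a gene x term score matrix in \[0, 1\].
#'
#' @param models A `term_model_set` from [train_term_models()].
#' @param model A `genome_model`.
#' @param store The masked, propagated `annotation_store` used for training
#'   features.
#' @param graph The companion `ontology_graph`.
#' @param genes Ordered character vector of genes to score.
#' @return A numeric matrix of class `score_matrix` (genes x terms).
#' @export
score_genes <- function(models, model, store, graph, genes) {
  half_widths <- attr(models, "half_widths")
  mode <- attr(models, "mode")
  scores <- matrix(
    NA_real_, nrow = length(genes), ncol = nrow(models),
    dimnames = list(genes, models$target)
  )
  for (i in seq_len(nrow(models))) {
    tm <- models$model[[i]]
    feats <- build_feature_matrix(
      model, store, genes, tm$target, graph,
      half_widths = half_widths, mode = mode
    )
    if (!identical(colnames(feats), tm$feature_names)) {
      abort(sprintf("Feature columns for term %s do not match the trained model.", tm$target))
    }
    scores[, i] <- predict(tm$fit, data = feats, num.threads = 1L)$predictions[, "pos"]
  }
  structure(scores, class = c("score_matrix", class(scores)))
}

#' Make a score matrix consistent with the ontology
#'
#' Post-processes per-term scores so that no gene scores higher on a term
#' than on any of its ancestors (the true-path constraint): scores are
#' propagated top-down from the root (implicit score 1), each term capped at
#' the minimum of its parents' effective scores. Unscored intermediate terms
#' pass their parents' constraint through. The operation is idempotent and
#' never increases a score.
#'
#' @param scores A `score_matrix` (genes x terms).
#' @param graph The companion `ontology_graph`.
#' @return A consistent `score_matrix` of the same shape.
#' @export
enforce_hierarchy <- function(scores, graph) {
  terms <- colnames(scores)
  for (t in terms) check_term(graph, t)
  needed <- unique(c(terms, unlist(graph$ancestors[terms], use.names = FALSE)))
  order_terms <- intersect(graph$topo, needed)
  eff <- matrix(1, nrow = nrow(scores), ncol = length(order_terms),
                dimnames = list(rownames(scores), order_terms))
  for (t in order_terms) {
    ps <- intersect(graph$parents[[t]], order_terms)
    cap <- if (length(ps) == 0) 1 else do.call(pmin, lapply(ps, function(p) eff[, p]))
    eff[, t] <- if (t %in% terms) pmin(scores[, t], cap) else cap
  }
  out <- eff[, terms, drop = FALSE]
  structure(out, class = c("score_matrix", "matrix", "array"))
}

#' @describeIn score_genes Long (gene_id, term_id, score) tibble.
#' @param x A `score_matrix`.
#' @param ... Unused.
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x), times = ncol(x)),
    term_id = rep(colnames(x), each = nrow(x)),
    score = as.vector(x)
  ) |> arrange(.data$gene_id, .data$term_id)
}

#' Write a score matrix as a 3-column TSV
#'
#' CAFA-like layout: `gene_id`, `term_id`, `score`.
#' @param scores A `score_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  readr::write_tsv(tidy(scores), path)
  invisible(path)
}

#' Read a score matrix written by [write_scores_tsv()]
#'
#' @param path File path.
#' @return A `score_matrix`.
#' @export
read_scores_tsv <- function(path) {
  long <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), term_id = readr::col_character(),
    score = readr::col_double()
  ))
  genes <- sort(unique(long$gene_id))
  terms <- sort(unique(long$term_id))
  m <- matrix(NA_real_, length(genes), length(terms), dimnames = list(genes, terms))
  m[cbind(match(long$gene_id, genes), match(long$term_id, terms))] <- long$score
  structure(m, class = c("score_matrix", "matrix", "array"))
}

#' Write a model-set manifest TSV
#'
#' One row per trained term: hyperparameters, CV score, class sizes, seed.
#' @param models A `term_model_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_manifest <- function(models, path) {
  readr::write_tsv(as_tibble(models) |> select(-"model"), path)
  invisible(path)
}
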