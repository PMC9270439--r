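# End-to-end orchestration: one config drives genome building, annotation
# propagation, the T/E split, per-term training, scoring, hierarchy
# enforcement, evaluation against the term-frequency null and the final
# most-specific predictions, with per-stage outputs and reproducible seeds.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end procedure. All randomness is
#' derived from `seed`; the configuration hash (computed over everything
#' except `outdir`) uniquely determines every numeric output.
#'
#' @param genome Path to a genome file (`.gff`/`.gff3`/`.gtf` or the
#'   4-column gene TSV dialect).
#' @param obo Path to an OBO ontology file.
#' @param annotations Path to a GAF or two-column TSV annotation file.
#' @param outdir Output directory for stage artifacts.
#' @param centromeres Optional path to a centromere TSV.
#' @param namespace Optional namespace restriction (e.g. `"BP"`).
#' @param half_widths FLA window half-widths.
#' @param split_fraction Fraction of genes in the training set T.
#' @param min_train,min_eval Term eligibility floors (genes annotated in T
#'   and E respectively).
#' @param fla_mode FLA column-set mode, see [fla_term_set()].
#' @param grid Hyperparameter grid (tibble, see [default_grid()]).
#' @param folds Cross-validation folds.
#' @param thresholds Classification-threshold grid.
#' @param map_floor Map-mode eligibility floor for enrichment maps.
#' @param keep_part_of Treat `part_of` as a hierarchical edge.
#' @param seed Master seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(genome, obo, annotations, outdir,
                       centromeres = NULL, namespace = NULL,
                       half_widths = c(5, 10, 20, 50, 100),
                       split_fraction = 0.8,
                       min_train = 40L, min_eval = 10L,
                       fla_mode = "relatives_down",
                       grid = default_grid(), folds = 3L,
                       thresholds = seq(0, 1, 0.01),
                       map_floor = 20L, keep_part_of = TRUE, seed = 1L) {
  cfg <- list(
    genome = genome, obo = obo, annotations = annotations, outdir = outdir,
    centromeres = centromeres, namespace = namespace,
    half_widths = as.numeric(half_widths),
    split_fraction = split_fraction,
    min_train = as.integer(min_train), min_eval = as.integer(min_eval),
    fla_mode = fla_mode, grid = as_tibble(grid), folds = as.integer(folds),
    thresholds = as.numeric(thresholds), map_floor = as.integer(map_floor),
    keep_part_of = isTRUE(keep_part_of), seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  genome:      %s\n", x$genome))
  cat(sprintf("  obo:         %s\n", x$obo))
  cat(sprintf("  annotations: %s\n", x$annotations))
  cat(sprintf("  outdir:      %s\n", x$outdir))
  cat(sprintf("  seed: %d  split: %.2f  floors: %d/%d  hash: %s\n",
              x$seed, x$split_fraction, x$min_train, x$min_eval,
              run_config_hash(x)))
  invisible(x)
}

run_config_hash <- function(config) {
  config_hash(config[setdiff(names(config), "outdir")])
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [run_config()]; `grid` may be a
#' mapping with `num_trees`, `max_depth`, `splitrule` vectors. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @param outdir Optional override of the configured output directory.
#' @param seed Optional override of the master seed.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (startsWith(p, "/")) p else file.path(base, p)
  }
  if (!is.null(y$grid)) y$grid <- do.call(default_grid, y$grid)
  args <- y
  for (key in c("genome", "obo", "annotations", "centromeres")) {
    args[[key]] <- resolve(y[[key]])
  }
  if (!is.null(outdir)) args$outdir <- outdir
  if (!is.null(args$outdir) && !startsWith(args$outdir, "/")) {
    args$outdir <- file.path(base, args$outdir)
  }
  if (!is.null(seed)) args$seed <- as.integer(seed)
  do.call(run_config, args)
}

log_stage <- function(outdir, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  inform(line)
  cat(line, "\n", file = file.path(outdir, "run.log"), append = TRUE)
}

stage_path <- function(config, name) file.path(config$outdir, name)

#' Run the full prediction pipeline
#'
#' Executes every stage in order: build the genome model; parse the
#' ontology; read and up-propagate annotations; split genes into T and E;
#' determine eligible terms; train one classifier per term on masked
#' features; score the evaluation genes; enforce DAG consistency; compute
#' hF1 curves for the trained and null models and their ratio; select the
#' threshold maximising the ratio; and emit the most-specific predictions
#' with a depth histogram. Each stage writes a numbered artifact into
#' `outdir`; the summary JSON carries the configuration hash and seed.
#' A stage failure halts the run naming the stage; completed artifacts are
#' retained. With `resume = TRUE`, expensive completed stages (models,
#' scores) are reloaded instead of recomputed.
#'
#' @param config A `run_config`.
#' @param resume Reuse stage outputs already present in `outdir`.
#' @param stop_after Optionally halt after a named stage (`"genome"`,
#'   `"train"` or `"evaluate"`), returning the objects computed so far —
#'   the building block for stage-wise subcommands.
#' @return Invisibly, a list with the run's main objects (model set, score
#'   matrix, curves, predictions, summary list).
#' @export
run_all <- function(config, resume = FALSE, stop_after = NULL) {
  stopifnot(inherits(config, "run_config"))
  for (f in c("genome", "obo", "annotations")) {
    if (!file.exists(config[[f]])) abort(sprintf("Config file `%s` not found: %s", f, config[[f]]))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- run_config_hash(config)
  stage <- "init"
  result <- tryCatch({
    stage <- "genome"
    centro <- if (!is.null(config$centromeres)) read_centromeres(config$centromeres)
    ext <- tolower(sub(".*\\.", "", basename(config$genome)))
    model <- if (ext %in% c("gff", "gff3", "gtf")) {
      read_genome_gff(config$genome, centromeres = centro)
    } else {
      read_genome_tsv(config$genome, centromeres = centro)
    }
    write_gene_order(model, stage_path(config, "01_gene_order.tsv"))
    log_stage(config$outdir, stage, sprintf("%d genes on %d arm(s)", nrow(model$genes), nrow(model$arms)))
    if (identical(stop_after, "genome")) return(list(model = model))

    stage <- "ontology"
    graph <- parse_obo(config$obo, keep_part_of = config$keep_part_of)
    write_ontology_summary(graph, stage_path(config, "02_ontology_summary.tsv"))
    log_stage(config$outdir, stage, sprintf("%d terms, %d edges", nrow(graph$terms), nrow(graph$edges)))

    stage <- "annotations"
    store <- read_annotations(config$annotations, graph, namespace = config$namespace)
    store <- propagate(store, graph)
    store <- annotation_store(
      store$assoc |> filter(.data$gene_id %in% genome_genes(model)),
      namespace = store$namespace, propagated = TRUE
    )
    log_stage(config$outdir, stage, sprintf("%d propagated associations", nrow(store$assoc)))

    stage <- "split"
    split <- split_train_eval(model, config$split_fraction,
                              seed = derive_seed(config$seed, "split"))
    write_split_tsv(split, stage_path(config, "03_split.tsv"))
    log_stage(config$outdir, stage, sprintf("|T| = %d, |E| = %d", length(split$train), length(split$eval)))

    stage <- "eligible_terms"
    targets <- eligible_terms(store, split, graph,
                              min_train = config$min_train, min_eval = config$min_eval)
    if (length(targets) == 0) abort("No term meets the eligibility floors.")
    writeLines(targets, stage_path(config, "04_eligible_terms.tsv"))
    log_stage(config$outdir, stage, sprintf("%d eligible term(s)", length(targets)))

    stage <- "train"
    masked <- mask_annotations(store, split$eval)
    models_rds <- stage_path(config, "models.rds")
    models <- if (resume && file.exists(models_rds)) {
      readRDS(models_rds)
    } else {
      m <- train_term_models(
        model, masked, graph, split, targets,
        grid = config$grid, folds = config$folds,
        seed = derive_seed(config$seed, "train"),
        half_widths = config$half_widths, mode = config$fla_mode
      )
      saveRDS(m, models_rds)
      m
    }
    write_model_manifest(models, stage_path(config, "05_model_manifest.tsv"))
    log_stage(config$outdir, stage, sprintf("%d model(s) trained", nrow(models)))
    if (identical(stop_after, "train")) {
      return(list(model = model, graph = graph, store = store, split = split,
                  targets = targets, models = models))
    }

    stage <- "score"
    eval_genes <- split$eval
    scores_path <- stage_path(config, "06_scores.tsv")
    consistent <- if (resume && file.exists(scores_path)) {
      read_scores_tsv(scores_path)
    } else {
      raw_scores <- score_genes(models, model, masked, graph, eval_genes)
      s <- enforce_hierarchy(raw_scores, graph)
      write_scores_tsv(s, scores_path)
      s
    }
    log_stage(config$outdir, stage, sprintf("scored %d gene(s) x %d term(s)", nrow(consistent), ncol(consistent)))

    stage <- "evaluate"
    annotated_eval <- intersect(eval_genes, unique(store$assoc$gene_id))
    truth <- annotation_store(
      store$assoc |> filter(.data$gene_id %in% annotated_eval),
      namespace = store$namespace, propagated = TRUE
    )
    trained_curve <- hf_curve(truth, consistent[annotated_eval, , drop = FALSE],
                              graph, config$thresholds)
    null_scores <- random_scores(store, split$train, annotated_eval, colnames(consistent))
    null_curve <- hf_curve(truth, null_scores, graph, config$thresholds)
    rc <- ratio_curve(trained_curve, null_curve)
    write_curve_tsv(trained_curve, rc, stage_path(config, "07_curves.tsv"))
    log_stage(config$outdir, stage, sprintf(
      "hF-max %.4f (null %.4f), max ratio %.3f at theta* %.2f",
      attr(trained_curve, "hf_max"), attr(null_curve, "hf_max"),
      attr(rc, "max_ratio"), attr(rc, "theta_star")
    ))
    if (identical(stop_after, "evaluate")) {
      return(list(model = model, graph = graph, store = store, split = split,
                  targets = targets, models = models, scores = consistent,
                  trained_curve = trained_curve, null_curve = null_curve,
                  ratio = rc))
    }

    stage <- "predict"
    theta_star <- attr(rc, "theta_star")
    preds <- finalize_predictions(consistent, theta_star, graph, known = masked)
    write_predictions_tsv(preds, stage_path(config, "08_predictions.tsv"))
    depth_hist <- predictions_by_depth(preds, graph)
    log_stage(config$outdir, stage, sprintf("%d prediction(s) at theta* %.2f", nrow(preds), theta_star))

    stage <- "summary"
    summary <- list(
      config_hash = hash,
      seed = config$seed,
      n_genes = nrow(model$genes),
      n_arms = nrow(model$arms),
      n_terms_ontology = nrow(graph$terms),
      n_terms_eligible = length(targets),
      n_models = nrow(models),
      hf_max = attr(trained_curve, "hf_max"),
      threshold_at_hf_max = attr(trained_curve, "threshold_at_max"),
      hf_max_random = attr(null_curve, "hf_max"),
      hf_max_ratio = attr(trained_curve, "hf_max") / attr(null_curve, "hf_max"),
      max_ratio = attr(rc, "max_ratio"),
      theta_star = theta_star,
      n_predictions = nrow(preds),
      predictions_by_depth = setNames(as.list(depth_hist$n), paste0("depth_", depth_hist$depth))
    )
    jsonlite::write_json(summary, stage_path(config, "09_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    manifest <- tibble(
      stage = c("genome", "ontology", "split", "eligible_terms", "train",
                "score", "evaluate", "predict", "summary"),
      artifact = c("01_gene_order.tsv", "02_ontology_summary.tsv", "03_split.tsv",
                   "04_eligible_terms.tsv", "05_model_manifest.tsv", "06_scores.tsv",
                   "07_curves.tsv", "08_predictions.tsv", "09_summary.json"),
      config_hash = hash, seed = config$seed
    )
    readr::write_tsv(manifest, stage_path(config, "00_manifest.tsv"))

    list(
      model = model, graph = graph, store = store, split = split,
      targets = targets, models = models, scores = consistent,
      trained_curve = trained_curve, null_curve = null_curve,
      ratio = rc, predictions = preds, summary = summary
    )
  }, error = function(e) {
    abort(sprintf("Pipeline failed at stage `%s`: %s", stage, conditionMessage(e)),
          parent = e)
  })
  invisible(result)
}

#' Simulate a dataset and write it in the pipeline's input dialects
#'
#' Generates a toy ontology and a clustered synthetic genome and writes
#' `genome.tsv` (4-column gene dialect), `ontology.obo` and
#' `annotations.tsv` into `outdir`, plus a ready-to-run `config.yaml`
#' pointing at them — files the real readers consume unchanged.
#'
#' @param outdir Output directory.
#' @param n_genes,n_arms,mean_terms_per_gene,cluster_strength,cluster_count
#'   Passed to [synthetic_spec()].
#' @param levels,branching,diamond_rate Passed to [make_toy_ontology()].
#' @param seed Master seed.
#' @return Invisibly, a list with the written paths and the generated
#'   objects.
#' @export
simulate_dataset <- function(outdir, n_genes = 2000L, n_arms = 4L,
                             levels = 3L, branching = 3L,
                             mean_terms_per_gene = 1.5,
                             cluster_strength = 0.8, cluster_count = 1L,
                             diamond_rate = 0, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  graph <- make_toy_ontology(levels, branching, seed = seed,
                             diamond_rate = diamond_rate)
  spec <- synthetic_spec(
    n_genes = n_genes, n_arms = n_arms,
    mean_terms_per_gene = mean_terms_per_gene,
    cluster_strength = cluster_strength, cluster_count = cluster_count,
    seed = seed
  )
  sim <- make_clustered_genome(spec, graph)
  paths <- list(
    genome = file.path(outdir, "genome.tsv"),
    obo = file.path(outdir, "ontology.obo"),
    annotations = file.path(outdir, "annotations.tsv"),
    config = file.path(outdir, "config.yaml")
  )
  write_genome_tsv(sim$model, paths$genome)
  write_toy_obo(graph, paths$obo)
  write_annotation_tsv(sim$store, paths$annotations)
  yaml::write_yaml(list(
    genome = "genome.tsv", obo = "ontology.obo",
    annotations = "annotations.tsv", outdir = "run", seed = as.integer(seed)
  ), paths$config)
  invisible(c(paths, list(graph = graph, model = sim$model, store = sim$store)))
}
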