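#' Create an annotation store
#'
#' An annotation store maps genes to the ontology terms they are annotated
#' with, as a long gene/term table. A store is either raw (direct
#' annotations) or up-propagated: under the true-path rule a gene annotated
#' with a term is implicitly annotated with every ancestor of that term, and
#' propagation makes this closure explicit.
#'
#' @param assoc Data frame with columns `gene_id` and `term_id`.
#' @param namespace Optional namespace label the store covers.
#' @param propagated Whether `assoc` is already ancestor-closed.
#' @return An object of class `annotation_store`.
#' @export
annotation_store <- function(assoc, namespace = NULL, propagated = FALSE) {
  assoc <- as_tibble(assoc) |>
    mutate(gene_id = as.character(.data$gene_id), term_id = as.character(.data$term_id)) |>
    distinct(.data$gene_id, .data$term_id) |>
    arrange(.data$gene_id, .data$term_id)
  structure(
    list(assoc = assoc, namespace = namespace, propagated = propagated),
    class = "annotation_store"
  )
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf(
    "<annotation_store> %d associations, %d genes, %d terms%s\n",
    nrow(x$assoc), dplyr::n_distinct(x$assoc$gene_id),
    dplyr::n_distinct(x$assoc$term_id),
    if (x$propagated) " (propagated)" else ""
  ))
  invisible(x)
}

#' @describeIn annotation_store Long gene/term association table.
#' @param x An `annotation_store`.
#' @param ... Unused.
#' @export
tidy.annotation_store <- function(x, ...) x$assoc

#' @describeIn annotation_store One-row summary.
#' @export
glance.annotation_store <- function(x, ...) {
  tibble(
    n_assoc = nrow(x$assoc),
    n_genes = dplyr::n_distinct(x$assoc$gene_id),
    n_terms = dplyr::n_distinct(x$assoc$term_id),
    propagated = x$propagated
  )
}

# named list: gene_id -> character vector of terms
gene_term_sets <- function(store, genes = NULL) {
  sets <- split(store$assoc$term_id, store$assoc$gene_id)
  if (is.null(genes)) return(sets)
  out <- setNames(vector("list", length(genes)), genes)
  hit <- intersect(genes, names(sets))
  out[hit] <- sets[hit]
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Read gene-term annotations
#'
#' Reads either GAF 2.x (`format = "gaf"`) or a headerless two-column TSV of
#' `gene_id`, `term_id` (`format = "tsv"`); `"auto"` sniffs GAF by the
#' `!gaf-version` pragma or column count. GAF rows whose qualifier contains
#' `NOT` are dropped. Rows whose term is absent from `graph` are dropped and
#' counted in the `n_unknown_terms` attribute. The result is unpropagated.
#'
#' @param path Annotation file path.
#' @param graph Companion `ontology_graph`; annotations are restricted to its
#'   terms (and to `namespace`, if given).
#' @param format `"auto"`, `"gaf"` or `"tsv"`.
#' @param namespace Optional namespace to keep (e.g. `"BP"`).
#' @param evidence_filter Optional character vector of GAF evidence codes to
#'   keep (default `NULL`: keep all).
#' @return An `annotation_store` (propagated = FALSE), with attribute
#'   `n_unknown_terms`.
#' @export
read_annotations <- function(path, graph, format = c("auto", "gaf", "tsv"),
                             namespace = NULL, evidence_filter = NULL) {
  format <- match.arg(format)
  first <- readLines(path, n = 5L, warn = FALSE)
  if (length(first) == 0) abort("Annotation file is empty.")
  if (format == "auto") {
    body <- first[!startsWith(first, "!")]
    nfields <- if (length(body) > 0) length(strsplit(body[[1L]], "\t")[[1L]]) else 2L
    format <- if (any(startsWith(first, "!gaf")) || nfields >= 15L) "gaf" else "tsv"
  }
  if (format == "gaf") {
    raw <- readr::read_tsv(
      path, comment = "!", col_names = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    if (ncol(raw) < 7) abort("GAF file has fewer than 7 columns.")
    assoc <- tibble(
      gene_id = raw[[2L]],
      term_id = raw[[5L]],
      qualifier = raw[[4L]] %||% NA_character_,
      evidence = raw[[7L]]
    )
    assoc <- assoc |> filter(is.na(.data$qualifier) |
                               !stringr::str_detect(.data$qualifier, "\\bNOT\\b"))
    if (!is.null(evidence_filter)) {
      assoc <- assoc |> filter(.data$evidence %in% evidence_filter)
    }
    assoc <- assoc |> select("gene_id", "term_id")
  } else {
    assoc <- readr::read_tsv(
      path, col_names = c("gene_id", "term_id"),
      col_types = readr::cols(.default = readr::col_character()),
      comment = "#"
    )
  }

  known <- assoc$term_id %in% graph$terms$term_id
  n_unknown <- sum(!known)
  if (n_unknown > 0) {
    warn(sprintf("Dropped %d annotation row(s) with terms absent from the ontology.", n_unknown))
  }
  assoc <- assoc[known, , drop = FALSE]
  if (!is.null(namespace)) {
    ns_of <- setNames(graph$terms$namespace, graph$terms$term_id)
    assoc <- assoc[ns_of[assoc$term_id] == namespace, , drop = FALSE]
  }
  if (nrow(assoc) == 0) abort("No usable annotation rows after filtering.")
  out <- annotation_store(assoc, namespace = namespace, propagated = FALSE)
  attr(out, "n_unknown_terms") <- n_unknown
  out
}

#' Up-propagate annotations under the true-path rule
#'
#' Replaces each gene's term set with its union with all ancestors of each
#' annotated term, up to the namespace root. Idempotent and monotone.
#'
#' @param store An `annotation_store`.
#' @param graph The companion `ontology_graph`.
#' @return A propagated `annotation_store`.
#' @export
propagate <- function(store, graph) {
  missing_terms <- setdiff(unique(store$assoc$term_id), graph$terms$term_id)
  if (length(missing_terms) > 0) {
    abort(paste0("Annotated term(s) absent from ontology: ",
                 paste(head(missing_terms, 5), collapse = ", ")))
  }
  anc <- graph$ancestors
  used <- unique(store$assoc$term_id)
  anc_map <- tibble(
    term_id = rep(used, lengths(anc[used])),
    anc_id = unlist(anc[used], use.names = FALSE)
  )
  extra <- store$assoc |>
    inner_join(anc_map, by = "term_id", relationship = "many-to-many") |>
    select("gene_id", term_id = "anc_id")
  annotation_store(
    bind_rows(store$assoc, extra),
    namespace = store$namespace, propagated = TRUE
  )
}

#' Randomly split genes into training and evaluation sets
#'
#' Uniform, unstratified random split of all model genes: the training set T
#' holds `round(fraction * n)` genes (round-half-even) and the evaluation set
#' E the complement. Deterministic given `seed`.
#'
#' @param model A `genome_model`.
#' @param fraction Fraction of genes assigned to T, in (0, 1). Default 0.8.
#' @param seed Integer seed.
#' @return An object of class `train_eval_split` with elements `train`,
#'   `eval`, `fraction`, `seed`.
#' @export
split_train_eval <- function(model, fraction = 0.8, seed = 1L) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be a single number in (0, 1).")
  }
  genes <- genome_genes(model)
  n_train <- as.integer(round(fraction * length(genes)))
  train <- with_seed(seed, sample(genes, n_train))
  structure(
    list(
      train = sort(train), eval = sort(setdiff(genes, train)),
      fraction = fraction, seed = as.integer(seed)
    ),
    class = "train_eval_split"
  )
}

#' @export
print.train_eval_split <- function(x, ...) {
  cat(sprintf(
    "<train_eval_split> |T| = %d, |E| = %d (fraction %.2f, seed %d)\n",
    length(x$train), length(x$eval), x$fraction, x$seed
  ))
  invisible(x)
}

#' @describeIn split_train_eval Long table of (gene_id, set) with set T or E.
#' @param x A `train_eval_split`.
#' @param ... Unused.
#' @export
tidy.train_eval_split <- function(x, ...) {
  bind_rows(
    tibble(gene_id = x$train, set = "T"),
    tibble(gene_id = x$eval, set = "E")
  ) |> arrange(.data$gene_id)
}

#' Terms with enough annotated genes to train and evaluate a classifier
#'
#' A term is eligible when at least `min_train` training genes and
#' `min_eval` evaluation genes are annotated with it (counted on propagated
#' annotations). Namespace roots are never eligible.
#'
#' @param store A propagated `annotation_store`.
#' @param split A `train_eval_split`.
#' @param graph The companion `ontology_graph` (used to exclude roots).
#' @param min_train Minimum annotated genes in T (default 40).
#' @param min_eval Minimum annotated genes in E (default 10).
#' @return Character vector of term ids, sorted.
#' @export
eligible_terms <- function(store, split, graph, min_train = 40L, min_eval = 10L) {
  if (!store$propagated) abort("`store` must be propagated before eligibility counting.")
  counts <- store$assoc |>
    mutate(set = ifelse(.data$gene_id %in% split$train, "T",
                        ifelse(.data$gene_id %in% split$eval, "E", NA))) |>
    filter(!is.na(.data$set)) |>
    count(.data$term_id, .data$set) |>
    tidyr::pivot_wider(names_from = "set", values_from = "n", values_fill = 0L)
  if (!"T" %in% names(counts)) counts$T <- 0L
  if (!"E" %in% names(counts)) counts$E <- 0L
  eligible <- counts$term_id[counts$T >= min_train & counts$E >= min_eval]
  sort(setdiff(eligible, unname(graph$roots)))
}

#' Mask the annotations of a set of genes
#'
#' Empties the term sets of `hidden_genes` while leaving the genes in place
#' in the genome: masked genes still occupy positions and count toward window
#' and arm sizes, but never contribute annotated counts. Used to hide
#' evaluation genes when building features.
#'
#' @param store An `annotation_store`.
#' @param hidden_genes Character vector of gene ids to mask.
#' @return An `annotation_store` with the hidden genes' rows removed; the
#'   masked set is recorded in the `masked_genes` attribute.
#' @export
mask_annotations <- function(store, hidden_genes) {
  out <- annotation_store(
    store$assoc |> filter(!.data$gene_id %in% hidden_genes),
    namespace = store$namespace, propagated = store$propagated
  )
  attr(out, "masked_genes") <- sort(unique(as.character(hidden_genes)))
  out
}

#' Write annotations as a two-column TSV
#'
#' @param store An `annotation_store`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_tsv <- function(store, path) {
  readr::write_tsv(store$assoc, path, col_names = FALSE)
  invisible(path)
}

#' Write a train/eval split as TSV
#'
#' Columns `gene_id`, `set` (T or E); header comment records fraction & seed.
#' @param split A `train_eval_split`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_tsv <- function(split, path) {
  writeLines(sprintf("# fraction=%g seed=%d", split$fraction, split$seed), path)
  readr::write_tsv(tidy(split), path, append = TRUE, col_names = TRUE)
  invisible(path)
}
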