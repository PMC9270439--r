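# Functional Landscape Arrays: per-(gene, target term) matrices of local
# enrichment, one row per window half-width and one column per term related
# to the target.

#' Terms whose enrichment enters a target's FLA
#'
#' Two column sets are supported. `relatives_down` (default): the target,
#' its parents, its siblings and all its descendants. `relatives_up`: the
#' target, its siblings and all its ancestors. The order is deterministic —
#' target first, then the remaining terms lexicographically — so every gene
#' sharing a target gets an identically laid-out FLA.
#'
#' @param graph An `ontology_graph`.
#' @param target Target term id.
#' @param mode `"relatives_down"` or `"relatives_up"`.
#' @param max_descendants Optional cap on the number of descendant columns
#'   (default `Inf`, no cap). When finite, descendants are ranked by
#'   annotated-gene count in `store` (ties lexicographic) and truncated; the
#'   truncation is logged.
#' @param store Optional `annotation_store`, required when `max_descendants`
#'   is finite.
#' @return Character vector of term ids, target first.
#' @export
fla_term_set <- function(graph, target,
                         mode = c("relatives_down", "relatives_up"),
                         max_descendants = Inf, store = NULL) {
  check_term(graph, target)
  mode <- match.arg(mode)
  if (mode == "relatives_down") {
    desc <- relatives(graph, target, "descendants")
    if (is.finite(max_descendants) && length(desc) > max_descendants) {
      if (is.null(store)) abort("`store` is required to cap descendants by annotation count.")
      cnt <- store$assoc |> filter(.data$term_id %in% desc) |> count(.data$term_id)
      n_of <- setNames(rep(0L, length(desc)), desc)
      n_of[cnt$term_id] <- cnt$n
      keep <- names(sort(n_of, decreasing = TRUE))[seq_len(max_descendants)]
      inform(sprintf(
        "FLA for %s: capped descendants from %d to %d by annotation count.",
        target, length(desc), as.integer(max_descendants)
      ))
      desc <- keep
    }
    rest <- unique(c(
      relatives(graph, target, "parents"),
      relatives(graph, target, "siblings"),
      desc
    ))
  } else {
    rest <- unique(c(
      relatives(graph, target, "siblings"),
      relatives(graph, target, "ancestors")
    ))
  }
  c(target, sort(setdiff(rest, target)))
}

#' Functional Landscape Array for one gene and target term
#'
#' The FLA is a matrix of local enrichments with one row per window
#' half-width and one column per term in [fla_term_set()]. Features must be
#' computed on a store with the evaluation genes masked, so that no feature
#' of any gene depends on held-out annotations.
#'
#' @param model A `genome_model`.
#' @param store A propagated `annotation_store`, masked for evaluation genes.
#' @param gene Gene id.
#' @param target Target term id.
#' @param graph The companion `ontology_graph`.
#' @param half_widths Window half-widths (rows). Default `c(5,10,20,50,100)`.
#' @param mode FLA column-set mode, see [fla_term_set()].
#' @param term_set Optional precomputed column set (must put `target` first).
#' @return A numeric matrix of class `fla` with `dimnames` = (half-widths,
#'   terms) and attributes `gene` and `target`.
#' @export
build_fla <- function(model, store, gene, target, graph,
                      half_widths = c(5, 10, 20, 50, 100),
                      mode = c("relatives_down", "relatives_up"),
                      term_set = NULL) {
  mode <- match.arg(mode)
  if (is.null(term_set)) term_set <- fla_term_set(graph, target, mode)
  fm <- build_feature_matrix(
    model, store, gene, target, graph,
    half_widths = half_widths, mode = mode, term_set = term_set
  )
  m <- matrix(
    fm[1L, ], nrow = length(half_widths), ncol = length(term_set), byrow = TRUE,
    dimnames = list(paste0("w", half_widths), term_set)
  )
  structure(m, class = c("fla", class(m)), gene = gene, target = target)
}

#' @export
print.fla <- function(x, ...) {
  cat(sprintf(
    "<fla> gene %s, target %s (%d half-widths x %d terms)\n",
    attr(x, "gene"), attr(x, "target"), nrow(x), ncol(x)
  ))
  print(unclass(x))
  invisible(x)
}

#' @describeIn build_fla Long tibble of (w, term_id, enrichment).
#' @param x An `fla`.
#' @param ... Unused.
#' @export
tidy.fla <- function(x, ...) {
  tibble(
    gene_id = attr(x, "gene"),
    target = attr(x, "target"),
    w = rep(as.integer(sub("^w", "", rownames(x))), times = ncol(x)),
    term_id = rep(colnames(x), each = nrow(x)),
    enrichment = as.vector(x)
  )
}

#' Feature matrix of flattened FLAs for a list of genes
#'
#' Row i is the row-major (width-major) flattening of gene i's FLA for
#' `target`: all terms at the first half-width, then all terms at the
#' second, and so on. Columns are named `w<width>:<term_id>`. All genes
#' share the same term set and column order, a prerequisite for training and
#' scoring with the same model.
#'
#' @inheritParams build_fla
#' @param genes Ordered character vector of gene ids (rows).
#' @return Numeric matrix `length(genes)` x `length(half_widths) *
#'   |term set|`, with gene ids as row names.
#' @export
build_feature_matrix <- function(model, store, genes, target, graph,
                                 half_widths = c(5, 10, 20, 50, 100),
                                 mode = c("relatives_down", "relatives_up"),
                                 term_set = NULL) {
  mode <- match.arg(mode)
  if (length(genes) == 0) abort("`genes` must contain at least one gene.")
  for (g in genes) check_gene(model, g)
  if (is.null(term_set)) term_set <- fla_term_set(graph, target, mode)

  arm_g <- unname(model$arm_of[genes])
  pos_g <- unname(model$rank_of[genes]) + 1L
  n_w <- length(half_widths)
  n_t <- length(term_set)
  out <- matrix(
    0, nrow = length(genes), ncol = n_w * n_t,
    dimnames = list(genes, paste0(
      "w", rep(half_widths, each = n_t), ":", rep(term_set, times = n_w)
    ))
  )
  rows_by_arm <- split(seq_along(genes), arm_g)
  saw_na <- FALSE
  for (ti in seq_along(term_set)) {
    ind <- term_arm_indicators(model, store, term_set[[ti]])
    for (wi in seq_len(n_w)) {
      col <- (wi - 1L) * n_t + ti
      for (arm in names(rows_by_arm)) {
        e <- arm_local_enrichment(ind[[arm]], as.integer(half_widths[[wi]]))
        idx <- rows_by_arm[[arm]]
        v <- e[pos_g[idx]]
        if (anyNA(v)) {
          saw_na <- TRUE
          v[is.na(v)] <- 0
        }
        out[idx, col] <- v
      }
    }
  }
  if (saw_na) warn("Gene(s) on a single-gene arm: their FLA entries are set to 0.")
  out
}
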