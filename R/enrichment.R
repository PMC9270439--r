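# Local enrichment: the over-representation of a term in a gene-count
# window relative to the gene's chromosomal arm,
#   E = (k/n) / (M/N)
# with N genes on the arm, M of them annotated, n genes in the window and k
# of those annotated. The focal gene is excluded from n and k.

# Per-arm annotation indicator vectors (rank order) for one term, under the
# store's active mask.
term_arm_indicators <- function(model, store, term) {
  annotated <- unique(store$assoc$gene_id[store$assoc$term_id == term])
  flag <- model$genes$gene_id %in% annotated
  split(flag, model$genes$arm)
}

# Enrichment at every rank of one arm for one half-width, via cumulative
# sums (O(L) per arm). `a` is the arm's logical annotation vector.
arm_local_enrichment <- function(a, w) {
  L <- length(a)
  if (L == 1L) return(NA_real_)
  cs <- c(0L, cumsum(a))  # cs[i + 1] = sum of a[1..i]
  i <- seq_len(L)
  lo <- pmax(i - w, 1L)
  hi <- pmin(i + w, L)
  k <- cs[hi + 1L] - cs[lo] - a
  n <- hi - lo  # window size with the focal gene excluded
  M <- cs[L + 1L]
  if (M == 0L) return(rep(0, L))
  (k / n) / (M / L)
}

#' Count annotated genes in a window and on its arm
#'
#' Computes the four counts behind the local enrichment statistic for one
#' (gene, term, half-width) triple: `N` genes on the focal gene's arm, `M` of
#' them annotated with the term, `n` genes in the window (focal excluded,
#' truncated at arm boundaries) and `k` of those annotated. Masked genes
#' count toward `N` and `n` but never toward `M` or `k`.
#'
#' @param model A `genome_model`.
#' @param store An `annotation_store` (typically propagated and masked).
#' @param term Term id.
#' @param gene Focal gene id.
#' @param w Window half-width (genes to each side).
#' @param graph Optional `ontology_graph`; when given, `term` is validated
#'   against it.
#' @return A one-row tibble with columns `gene_id`, `term_id`, `w`, `N`,
#'   `M`, `n`, `k`.
#' @export
window_counts <- function(model, store, term, gene, w, graph = NULL) {
  check_gene(model, gene)
  if (!is.null(graph)) check_term(graph, term)
  w <- assert_scalar_int(w, "w")
  members <- window_members(model, gene, w)
  arm <- model$arm_of[[gene]]
  arm_genes <- model$genes$gene_id[model$genes$arm == arm]
  annotated <- unique(store$assoc$gene_id[store$assoc$term_id == term])
  tibble(
    gene_id = gene, term_id = term, w = w,
    N = length(arm_genes),
    M = sum(arm_genes %in% annotated),
    n = length(members),
    k = sum(members %in% annotated)
  )
}

#' Local enrichment from window counts
#'
#' `(k/n) / (M/N)`. When no gene on the arm carries the term (`M = 0`, hence
#' `k = 0`) the enrichment is defined as 0 — "no signal" — keeping feature
#' matrices numeric. A single-gene arm (`n = 0`) has no defined enrichment
#' and yields `NA` with a warning.
#'
#' @param counts A data frame with columns `N`, `M`, `n`, `k` (e.g. from
#'   [window_counts()]); vectorised over rows.
#' @return Numeric vector of non-negative enrichment values.
#' @export
local_enrichment <- function(counts) {
  with(counts, {
    out <- rep(NA_real_, length(N))
    zero_n <- n == 0
    if (any(zero_n)) warn("Window of size 0 (single-gene arm): enrichment undefined, NA returned.")
    ok <- !zero_n
    out[ok] <- ifelse(M[ok] == 0, 0, (k[ok] / n[ok]) / (M[ok] / N[ok]))
    out
  })
}

#' Whole-genome functional enrichment map
#'
#' Computes the local enrichment of each term at every gene position of
#' every arm, for every half-width, by sliding the window one gene at a time.
#' A term's map shows which regions of the genome are enriched in that term.
#' In map mode only terms annotated to at least `min_annotated` genes are
#' mapped; terms below the floor are skipped with a notice.
#'
#' @param model A `genome_model`.
#' @param store An `annotation_store` (propagated; use all current
#'   annotations for descriptive maps).
#' @param terms Character vector of term ids to map.
#' @param half_widths Window half-widths (default `c(5, 10, 20, 50, 100)`).
#' @param min_annotated Minimum annotated genes for a term to be mapped
#'   (default 20); set to 0 to disable the floor.
#' @return A tibble of class `enrichment_map` with columns `term_id`, `arm`,
#'   `position` (1-based), `gene_id`, `w`, `enrichment`.
#' @export
enrichment_map <- function(model, store, terms,
                           half_widths = c(5, 10, 20, 50, 100),
                           min_annotated = 20L) {
  term_counts <- store$assoc |> count(.data$term_id)
  n_of <- setNames(term_counts$n, term_counts$term_id)
  rows <- list()
  base <- model$genes |>
    mutate(position = .data$rank + 1L) |>
    select("arm", "position", "gene_id")
  base_by_arm <- split(base, base$arm)
  for (term in terms) {
    n_ann <- if (term %in% names(n_of)) n_of[[term]] else 0L
    if (n_ann < min_annotated) {
      inform(sprintf(
        "Skipping map for %s: %d annotated gene(s) < floor %d.",
        term, n_ann, min_annotated
      ))
      next
    }
    ind <- term_arm_indicators(model, store, term)
    for (arm in names(ind)) {
      for (w in half_widths) {
        e <- arm_local_enrichment(ind[[arm]], as.integer(w))
        rows[[length(rows) + 1L]] <- base_by_arm[[arm]] |>
          mutate(term_id = term, w = as.integer(w), enrichment = e)
      }
    }
  }
  out <- if (length(rows) == 0) {
    tibble(
      term_id = character(), arm = character(), position = integer(),
      gene_id = character(), w = integer(), enrichment = double()
    )
  } else {
    bind_rows(rows) |> select("term_id", "arm", "position", "gene_id", "w", "enrichment")
  }
  class(out) <- c("enrichment_map", class(out))
  out
}

#' Write an enrichment map as long-format TSV
#'
#' Columns `term_id`, `arm`, `position` (1-based), `gene_id`, `w`,
#' `enrichment`.
#' @param map An `enrichment_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_map <- function(map, path) {
  writeLines("# local enrichment map; position is 1-based", path)
  readr::write_tsv(as_tibble(map), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write one term/half-width layer of a map as bedGraph
#'
#' Uses the original TSS coordinates of the genome model; each gene
#' contributes a 1-bp interval at its TSS.
#'
#' @param map An `enrichment_map`.
#' @param model The `genome_model` the map was computed on.
#' @param term Term id to export.
#' @param w Half-width to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_bedgraph <- function(map, model, term, w, path) {
  layer <- as_tibble(map) |> filter(.data$term_id == term, .data$w == !!w)
  if (nrow(layer) == 0) abort("No map rows for that term and half-width.")
  coords <- model$genes |> select("gene_id", "chrom", "tss")
  bed <- layer |>
    left_join(coords, by = "gene_id") |>
    mutate(start = as.integer(.data$tss) - 1L, end = as.integer(.data$tss)) |>
    select("chrom", "start", "end", "enrichment") |>
    arrange(.data$chrom, .data$start)
  writeLines(sprintf("track type=bedGraph name=\"%s w=%d\"", term, as.integer(w)), path)
  readr::write_tsv(bed, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Plot an enrichment map
#'
#' Enrichment along gene position, one colour per half-width, facetted by
#' arm (and by term when several are present).
#'
#' @param object An `enrichment_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_map <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$enrichment,
    colour = factor(.data$w)
  )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(
      x = "gene position (rank within arm)",
      y = "local enrichment", colour = "half-width"
    ) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(df$term_id) > 1) {
    p + ggplot2::facet_grid(term_id ~ arm, scales = "free_x")
  } else {
    p + ggplot2::facet_wrap(~arm, scales = "free_x")
  }
}
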