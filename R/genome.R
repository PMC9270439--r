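#' Build a genome model from gene records
#'
#' A genome model represents each chromosomal arm as an ordered string of
#' protein-coding genes. Genes are ordered within an arm by the coordinate of
#' their transcription start site; intergenic distances are discarded, so only
#' gene order is retained. Distances between genes are measured in number of
#' intervening genes, and all window queries operate on this ordering.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `tss` (1-based
#'   bp coordinate of the transcription start site) and `strand`; an optional
#'   `arm` column assigns genes to chromosomal arms directly. Without an `arm`
#'   column each chromosome is one arm, unless `centromeres` is given.
#' @param centromeres Optional data frame with columns `chrom` and `pos`
#'   (centromere position in bp). Chromosomes listed here are split into two
#'   arms named `<chrom>L` (tss <= pos) and `<chrom>R` (tss > pos).
#' @return An object of class `genome_model`: gene order per arm plus a
#'   gene -> (arm, rank) index. Ranks are 0-based internally; file writers
#'   report 1-based positions.
#'
#' Ties on identical TSS coordinates are broken by `gene_id` lexicographic
#' order, so the model is a pure function of the set of records (input order
#' never matters).
#' @examples
#' gm <- build_genome_model(tibble::tibble(
#'   gene_id = c("a", "b", "c"), chrom = "1",
#'   tss = c(500, 100, 900), strand = "+"
#' ))
#' tidy(gm)
#' @export
build_genome_model <- function(genes, centromeres = NULL) {
  genes <- as_tibble(genes)
  required <- c("gene_id", "chrom", "tss", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    abort(paste0("`genes` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(genes) == 0) abort("`genes` contains no records.")
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(!is.finite(genes$tss)) || any(genes$tss < 1)) {
    abort("`tss` coordinates must be positive integers.")
  }

  if (!"arm" %in% names(genes) || all(is.na(genes$arm))) {
    genes$arm <- as.character(genes$chrom)
    if (!is.null(centromeres)) {
      centromeres <- as_tibble(centromeres)
      idx <- match(genes$chrom, centromeres$chrom)
      split_here <- !is.na(idx)
      side <- ifelse(genes$tss[split_here] <= centromeres$pos[idx[split_here]], "L", "R")
      genes$arm[split_here] <- paste0(genes$chrom[split_here], side)
    }
  }

  genes <- genes |>
    mutate(arm = as.character(.data$arm), gene_id = as.character(.data$gene_id)) |>
    arrange(.data$arm, .data$tss, .data$gene_id) |>
    group_by(.data$arm) |>
    mutate(rank = row_number() - 1L) |>
    ungroup() |>
    select("gene_id", "arm", "rank", "tss", "strand", "chrom")

  arms <- genes |> count(.data$arm, name = "n_genes")

  structure(
    list(
      genes = genes,
      arms = arms,
      arm_of = setNames(genes$arm, genes$gene_id),
      rank_of = setNames(genes$rank, genes$gene_id)
    ),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d genes on %d arm(s)\n",
    nrow(x$genes), nrow(x$arms)
  ))
  print(x$arms, n = 10)
  invisible(x)
}

#' @describeIn build_genome_model Gene table (one row per gene, 0-based rank).
#' @param x A `genome_model`.
#' @param ... Unused.
#' @export
tidy.genome_model <- function(x, ...) x$genes

#' @describeIn build_genome_model One-row summary (gene and arm counts).
#' @export
glance.genome_model <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_arms = nrow(x$arms),
    largest_arm = max(x$arms$n_genes)
  )
}

genome_genes <- function(model) model$genes$gene_id

check_gene <- function(model, gene) {
  if (!gene %in% names(model$rank_of)) {
    abort(paste0("Unknown gene: ", gene))
  }
  invisible(gene)
}

#' Genes inside a window around a focal gene
#'
#' Returns the genes whose rank lies within `w` positions of the focal gene on
#' the same chromosomal arm. Windows truncate at arm boundaries and never
#' cross arms. By default the focal gene itself is excluded: its own
#' annotation would otherwise leak into its feature vector, and evaluation
#' genes are annotation-masked, so inclusion would shift features between
#' training and evaluation genes.
#'
#' @param model A `genome_model`.
#' @param gene Focal gene id.
#' @param w Window half-width in genes (positive integer).
#' @param include_focal Include the focal gene itself (default `FALSE`).
#' @return Character vector of gene ids ordered by rank.
#' @export
window_members <- function(model, gene, w, include_focal = FALSE) {
  check_gene(model, gene)
  w <- assert_scalar_int(w, "w", min = 1L)
  arm <- model$arm_of[[gene]]
  r <- model$rank_of[[gene]]
  arm_genes <- model$genes$gene_id[model$genes$arm == arm]
  lo <- max(0L, r - w)
  hi <- min(length(arm_genes) - 1L, r + w)
  members <- arm_genes[(lo:hi) + 1L]
  if (!include_focal) members <- members[members != gene]
  members
}

#' Gene-count distance between two genes
#'
#' The distance between two genes is the number of other genes located
#' between them on the same arm: adjacent genes have distance 0. Genes on
#' different arms have no defined distance and return `NA`.
#'
#' @param model A `genome_model`.
#' @param a,b Gene ids.
#' @return Non-negative integer, or `NA_integer_` for genes on different arms.
#' @export
gene_distance <- function(model, a, b) {
  check_gene(model, a)
  check_gene(model, b)
  if (model$arm_of[[a]] != model$arm_of[[b]]) return(NA_integer_)
  if (a == b) return(0L)
  abs(model$rank_of[[a]] - model$rank_of[[b]]) - 1L
}

#' Read a genome model from a plain gene-order TSV
#'
#' The dialect is four tab-separated columns without header:
#' `gene_id`, `chrom`, `tss`, `strand`. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @inheritParams build_genome_model
#' @return A `genome_model`.
#' @export
read_genome_tsv <- function(path, centromeres = NULL) {
  genes <- readr::read_tsv(
    path,
    col_names = c("gene_id", "chrom", "tss", "strand"),
    col_types = readr::cols(
      gene_id = readr::col_character(),
      chrom = readr::col_character(),
      tss = readr::col_double(),
      strand = readr::col_character()
    ),
    comment = "#"
  )
  build_genome_model(genes, centromeres = centromeres)
}

#' Read a genome model from GFF3/GTF
#'
#' Keeps only features of type `gene` whose biotype matches (protein-coding
#' by default — the only elements the genome model considers). The
#' transcription start site is taken strand-aware: feature start on `+`,
#' feature end on `-`.
#'
#' @param path GFF3 or GTF file path.
#' @param biotype Biotype(s) to keep (matched against the `gene_biotype` or
#'   `biotype` attribute; features lacking both attributes are kept only when
#'   `biotype` is `NULL`).
#' @inheritParams build_genome_model
#' @return A `genome_model`.
#' @export
read_genome_gff <- function(path, biotype = "protein_coding", centromeres = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("read_genome_gff() requires the rtracklayer package.")
  }
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[gff$type == "gene", , drop = FALSE]
  bt <- gff[["gene_biotype"]] %||% gff[["biotype"]]
  if (!is.null(biotype)) {
    if (is.null(bt)) abort("No biotype attribute found in GFF/GTF gene features.")
    gff <- gff[!is.na(bt) & bt %in% biotype, , drop = FALSE]
  }
  if (nrow(gff) == 0) abort("No gene records left after biotype filtering.")
  id <- gff[["gene_id"]] %||% gff[["ID"]]
  genes <- tibble(
    gene_id = as.character(id),
    chrom = as.character(gff$seqid),
    tss = ifelse(as.character(gff$strand) == "-", gff$end, gff$start),
    strand = as.character(gff$strand)
  )
  build_genome_model(genes, centromeres = centromeres)
}

#' Read a centromere table
#'
#' Two tab-separated columns without header: `chrom`, `pos` (bp).
#' @param path File path.
#' @return A tibble with columns `chrom` and `pos`.
#' @export
read_centromeres <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("chrom", "pos"),
    col_types = readr::cols(chrom = readr::col_character(), pos = readr::col_double()),
    comment = "#"
  )
}

#' Write gene order for provenance
#'
#' Emits a TSV of `arm`, `position` (1-based) and `gene_id`, with a header
#' comment stating that positions are 1-based.
#'
#' @param model A `genome_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_order <- function(model, path) {
  out <- model$genes |>
    mutate(position = .data$rank + 1L) |>
    select("arm", "position", "gene_id")
  writeLines("# gene order per arm; position is 1-based", path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
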