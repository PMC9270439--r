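# Synthetic genomes and toy ontologies with controllable spatial clustering
# of functionally related genes: the statistical structure the local
# enrichment features exploit, generated at desk scale so every pipeline
# stage can be exercised and signal recovery quantified without downloads.

#' Specification for a synthetic clustered genome
#'
#' @param n_genes Total protein-coding genes.
#' @param n_arms Number of chromosomal arms (genes split evenly).
#' @param mean_terms_per_gene Expected number of leaf-term annotations per
#'   gene; each leaf term draws its gene count from a Poisson with mean
#'   `n_genes * mean_terms_per_gene / n_leaves`.
#' @param cluster_strength Fraction rho in \[0, 1\] of each term's genes
#'   placed in contiguous runs; the remainder is placed uniformly. At 0,
#'   placement is exchangeable with uniform-random assignment.
#' @param cluster_count Number of contiguous runs per term (default 1).
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L, n_arms = 4L,
                           mean_terms_per_gene = 1.5,
                           cluster_strength = 0.8, cluster_count = 1L,
                           seed = 1L) {
  assert_scalar_int(n_genes, "n_genes")
  assert_scalar_int(n_arms, "n_arms")
  if (n_arms > n_genes) abort("`n_arms` cannot exceed `n_genes`.")
  if (cluster_strength < 0 || cluster_strength > 1) {
    abort("`cluster_strength` must lie in [0, 1].")
  }
  structure(
    list(
      n_genes = as.integer(n_genes), n_arms = as.integer(n_arms),
      mean_terms_per_gene = mean_terms_per_gene,
      cluster_strength = cluster_strength,
      cluster_count = as.integer(cluster_count), seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
}

#' Generate a toy ontology
#'
#' A rooted tree with `levels` levels below the root and a fixed branching
#' factor, optionally spiced with random diamond edges (an extra parent
#' drawn from the level above, giving multiple inheritance as in real
#' ontologies). Deterministic given `seed`.
#'
#' @param levels Number of levels below the root (>= 1).
#' @param branching Children per node (>= 1).
#' @param seed Integer seed.
#' @param diamond_rate Probability that a non-root term gains a second
#'   parent from the level above (default 0).
#' @param namespace Namespace label (default `"BP"`).
#' @return An `ontology_graph` with `1 + branching + ... + branching^levels`
#'   terms.
#' @export
make_toy_ontology <- function(levels, branching, seed = 1L,
                              diamond_rate = 0, namespace = "BP") {
  assert_scalar_int(levels, "levels")
  assert_scalar_int(branching, "branching")
  n_total <- sum(branching^(0:levels))
  if (n_total > 10000L) abort("Toy ontology would exceed 10,000 terms.")

  ids <- sprintf("T%04d", seq_len(n_total))
  level_of <- rep(0:levels, times = branching^(0:levels))
  ech <- character(0); epa <- character(0)
  with_seed(derive_seed(seed, "toy-ontology"), {
    for (l in seq_len(levels)) {
      children <- ids[level_of == l]
      parents <- ids[level_of == l - 1L]
      primary <- rep(parents, each = branching)
      ech <- c(ech, children); epa <- c(epa, primary)
      if (diamond_rate > 0 && length(parents) > 1L) {
        extra <- runif(length(children)) < diamond_rate
        for (i in which(extra)) {
          other <- sample(setdiff(parents, primary[[i]]), 1L)
          ech <- c(ech, children[[i]]); epa <- c(epa, other)
        }
      }
    }
  })
  ontology_graph(
    terms = tibble(term_id = ids, namespace = namespace),
    edges = tibble(child = ech, parent = epa, relation = "is_a")
  )
}

#' Generate a genome with spatially clustered annotations
#'
#' Each leaf term of the ontology draws a gene count from a Poisson
#' distribution; a fraction `cluster_strength` of those genes is placed in
#' contiguous runs at random arm locations and the remainder uniformly.
#' Genes may carry several leaf terms. Annotations are generated at the
#' leaves and unpropagated, so downstream code exercises the same
#' propagation path as real data. Gene coordinates are synthesised as
#' `rank * 1000` bp so that file writers round-trip.
#'
#' @param spec A `synthetic_spec`.
#' @param graph An `ontology_graph` (e.g. from [make_toy_ontology()]).
#' @return A list with elements `model` (a `genome_model`) and `store` (a
#'   leaf-level, unpropagated `annotation_store`).
#' @export
make_clustered_genome <- function(spec, graph) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_genes
  arm_sizes <- rep(n %/% spec$n_arms, spec$n_arms)
  if (n %% spec$n_arms > 0) {
    arm_sizes[seq_len(n %% spec$n_arms)] <- arm_sizes[seq_len(n %% spec$n_arms)] + 1L
  }
  arm_ids <- sprintf("arm%02d", seq_len(spec$n_arms))
  genes <- tibble(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = rep(arm_ids, times = arm_sizes),
    arm = rep(arm_ids, times = arm_sizes),
    tss = unlist(lapply(arm_sizes, function(L) seq_len(L) * 1000), use.names = FALSE),
    strand = "+"
  )
  model <- build_genome_model(genes)

  leaves <- graph$terms$term_id[lengths(graph$children[graph$terms$term_id]) == 0L]
  lambda <- n * spec$mean_terms_per_gene / length(leaves)
  arm_offset <- c(0L, cumsum(arm_sizes))[seq_len(spec$n_arms)]

  assoc_gene <- character(0); assoc_term <- character(0)
  with_seed(derive_seed(spec$seed, "clustered-genome"), {
    for (term in leaves) {
      m <- min(rpois(1L, lambda), n)
      if (m == 0L) next
      m_clust <- round(spec$cluster_strength * m)
      carriers <- integer(0)
      if (m_clust > 0L) {
        run_len <- diff(round(seq(0, m_clust, length.out = spec$cluster_count + 1L)))
        for (len in run_len[run_len > 0L]) {
          fits <- arm_sizes >= len
          if (!any(fits)) {
            abort(sprintf("Cluster of %d genes exceeds every arm length.", len))
          }
          cand <- which(fits)
          a <- if (length(cand) == 1L) cand else sample(cand, 1L, prob = arm_sizes[cand])
          start <- sample.int(arm_sizes[[a]] - len + 1L, 1L)
          carriers <- union(carriers, arm_offset[[a]] + start - 1L + seq_len(len))
        }
      }
      n_rest <- m - length(carriers)
      if (n_rest > 0L) {
        pool <- setdiff(seq_len(n), carriers)
        carriers <- c(carriers, sample(pool, min(n_rest, length(pool))))
      }
      assoc_gene <- c(assoc_gene, genes$gene_id[carriers])
      assoc_term <- c(assoc_term, rep(term, length(carriers)))
    }
  })
  if (length(assoc_gene) == 0) abort("Generator produced no annotations; increase `mean_terms_per_gene`.")
  store <- annotation_store(
    tibble(gene_id = assoc_gene, term_id = assoc_term),
    namespace = unique(graph$terms$namespace)[[1L]], propagated = FALSE
  )
  list(model = model, store = store)
}

#' Shuffle annotation sets across gene positions
#'
#' Permutes the assignment of per-gene annotation sets to genome positions
#' uniformly at random. Marginal term frequencies (and co-annotation
#' structure within a gene) are preserved exactly, but all spatial
#' clustering is destroyed — the null genome for "how far from random is
#' the arrangement of functions along the genome".
#'
#' @param model A `genome_model` (defines the gene universe).
#' @param store An `annotation_store`.
#' @param seed Integer seed.
#' @return An `annotation_store` with the same propagation flag.
#' @export
shuffle_annotations <- function(model, store, seed = 1L) {
  genes <- genome_genes(model)
  perm <- with_seed(derive_seed(seed, "shuffle"), sample(genes))
  relabel <- setNames(perm, genes)
  annotation_store(
    store$assoc |> mutate(gene_id = unname(relabel[.data$gene_id])),
    namespace = store$namespace, propagated = store$propagated
  )
}

#' Write an ontology graph as a minimal OBO file
#'
#' Emits `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` and
#' `relationship: part_of` lines — the dialect [parse_obo()] reads back.
#'
#' @param graph An `ontology_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_toy_obo <- function(graph, path) {
  name_of <- setNames(graph$terms$name, graph$terms$term_id)
  ns_of <- setNames(graph$terms$namespace, graph$terms$term_id)
  lines <- c("format-version: 1.2", "")
  for (t in graph$terms$term_id) {
    lines <- c(lines, "[Term]", paste0("id: ", t),
               paste0("name: ", name_of[[t]]),
               paste0("namespace: ", ns_of[[t]]))
    e <- graph$edges[graph$edges$child == t, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      lines <- c(lines, if (e$relation[[i]] == "part_of") {
        paste0("relationship: part_of ", e$parent[[i]])
      } else {
        paste0("is_a: ", e$parent[[i]])
      })
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome model as minimal GFF3
#'
#' One `gene` feature per gene with `gene_biotype=protein_coding`, the
#' dialect [read_genome_gff()] consumes.
#'
#' @param model A `genome_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_gff3 <- function(model, path) {
  g <- model$genes
  lines <- c("##gff-version 3", sprintf(
    "%s\tfunscape\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gene_biotype=protein_coding",
    g$chrom, as.integer(g$tss), as.integer(g$tss) + 500L, g$strand,
    g$gene_id, g$gene_id
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome model as the 4-column gene TSV dialect
#'
#' Columns `gene_id`, `chrom`, `tss`, `strand` (no header), the dialect
#' [read_genome_tsv()] consumes.
#'
#' @param model A `genome_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_tsv <- function(model, path) {
  readr::write_tsv(
    model$genes |> select("gene_id", "chrom", "tss", "strand"),
    path, col_names = FALSE
  )
  invisible(path)
}
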