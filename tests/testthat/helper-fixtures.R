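# Shared fixtures and independent oracles. Everything is built in code; the
# oracles deliberately use naive set/loop arithmetic, independent of the
# package's vectorised implementations.

# chain R -> A -> B (edges child -> parent)
chain_graph <- function() {
  ontology_graph(
    terms = tibble::tibble(term_id = c("R", "A", "B"), namespace = "BP"),
    edges = tibble::tibble(child = c("A", "B"), parent = c("R", "A"))
  )
}

# R with children A, C; A has child B; C has child D
tree_graph <- function() {
  ontology_graph(
    terms = tibble::tibble(term_id = c("R", "A", "B", "C", "D"), namespace = "BP"),
    edges = tibble::tibble(child = c("A", "C", "B", "D"), parent = c("R", "R", "A", "C"))
  )
}

# diamond: R -> {A, C}, {A, C} -> B
diamond_graph <- function() {
  ontology_graph(
    terms = tibble::tibble(term_id = c("R", "A", "B", "C"), namespace = "BP"),
    edges = tibble::tibble(child = c("A", "C", "B", "B"), parent = c("R", "R", "A", "C"))
  )
}

# a genome of consecutive genes split over arms of the given sizes
linear_genome <- function(arm_sizes) {
  arms <- sprintf("arm%d", seq_along(arm_sizes))
  build_genome_model(tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(sum(arm_sizes))),
    chrom = rep(arms, times = arm_sizes),
    tss = unlist(lapply(arm_sizes, function(L) seq_len(L) * 100)),
    strand = "+"
  ))
}

# random single-rooted DAG: term i >= 2 draws 1-2 parents among 1..(i-1)
random_dag <- function(n_terms, seed) {
  ids <- sprintf("D%02d", seq_len(n_terms))
  ch <- character(0); pa <- character(0)
  set.seed(seed)
  for (i in seq(2, n_terms)) {
    k <- sample(1:min(2L, i - 1L), 1L)
    ps <- sample(ids[seq_len(i - 1L)], k)
    ch <- c(ch, rep(ids[[i]], k)); pa <- c(pa, ps)
  }
  ontology_graph(
    terms = tibble::tibble(term_id = ids, namespace = "BP"),
    edges = tibble::tibble(child = ch, parent = pa)
  )
}

# random annotation store over a genome and graph (leaf or any terms)
random_store <- function(model, graph, n_assoc, seed, propagated = FALSE) {
  set.seed(seed)
  genes <- tidy(model)$gene_id
  terms <- setdiff(graph$terms$term_id, unname(graph$roots))
  st <- annotation_store(tibble::tibble(
    gene_id = sample(genes, n_assoc, replace = TRUE),
    term_id = sample(terms, n_assoc, replace = TRUE)
  ), namespace = "BP")
  if (propagated) propagate(st, graph) else st
}

# --- independent oracles -----------------------------------------------

# ancestors as the fixed point of repeated parent expansion on the edge table
oracle_ancestors <- function(graph, term) {
  edges <- graph$edges
  anc <- character(0)
  frontier <- term
  repeat {
    nxt <- setdiff(edges$parent[edges$child %in% frontier], c(anc, term))
    if (length(nxt) == 0) break
    anc <- c(anc, nxt)
    frontier <- nxt
  }
  sort(anc)
}

# shortest depth by breadth-first search from the root downwards
oracle_depth <- function(graph, term) {
  root <- unname(graph$roots[[graph$terms$namespace[graph$terms$term_id == term]]])
  depth <- 0L
  level <- root
  while (!(term %in% level)) {
    level <- unique(graph$edges$child[graph$edges$parent %in% level])
    depth <- depth + 1L
    if (length(level) == 0) stop("term unreachable")
  }
  depth
}

# O(N*w) sliding recount of local enrichment along one arm indicator vector
oracle_arm_enrichment <- function(a, w) {
  L <- length(a)
  M <- sum(a)
  vapply(seq_len(L), function(i) {
    idx <- setdiff(max(1L, i - w):min(L, i + w), i)
    n <- length(idx)
    if (n == 0) return(NA_real_)
    if (M == 0) return(0)
    (sum(a[idx]) / n) / (M / L)
  }, double(1))
}

# brute-force window counts by explicit filtering of the gene table
oracle_window_counts <- function(model, store, term, gene, w) {
  g <- tidy(model)
  arm <- g$arm[g$gene_id == gene]
  armg <- g[g$arm == arm, ]
  ann <- unique(store$assoc$gene_id[store$assoc$term_id == term])
  r <- g$rank[g$gene_id == gene]
  win <- armg$gene_id[abs(armg$rank - r) <= w & armg$gene_id != gene]
  list(
    N = nrow(armg), M = sum(armg$gene_id %in% ann),
    n = length(win), k = sum(win %in% ann)
  )
}

# direct set-arithmetic hierarchical precision/recall/F1; both sides get the
# root added, as the metric definition states
oracle_hprf <- function(truth_sets, pred_sets, root) {
  P <- lapply(pred_sets, function(s) union(s, root))
  Tr <- lapply(truth_sets, function(s) union(s, root))
  tp <- sum(mapply(function(p, t) length(intersect(p, t)), P, Tr))
  prec <- if (sum(lengths(P)) == 0) 0 else tp / sum(lengths(P))
  rec <- if (sum(lengths(Tr)) == 0) 0 else tp / sum(lengths(Tr))
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(hprec = prec, hrec = rec, hf1 = f1)
}

# propagated truth sets for a list of genes, via the oracle ancestor closure
oracle_propagate_sets <- function(store, graph, genes) {
  sets <- gene_sets <- split(store$assoc$term_id, store$assoc$gene_id)
  out <- lapply(genes, function(g) {
    s <- gene_sets[[g]]
    if (is.null(s)) return(character(0))
    sort(unique(c(s, unlist(lapply(s, function(t) oracle_ancestors(graph, t))))))
  })
  names(out) <- genes
  out
}
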