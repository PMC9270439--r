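score_mat <- function(values, genes, terms) {
  m <- matrix(values, length(genes), length(terms), byrow = TRUE,
              dimnames = list(genes, terms))
  class(m) <- c("score_matrix", "matrix", "array")
  m
}

truth_store <- function(sets) {
  annotation_store(tibble::tibble(
    gene_id = rep(names(sets), lengths(sets)),
    term_id = unlist(sets, use.names = FALSE)
  ), namespace = "BP", propagated = TRUE)
}

test_that("the two-gene chain example yields hPrec = hRec = hF1 = 0.8", {
  g <- chain_graph()
  truth <- truth_store(list(g1 = c("R", "A"), g2 = c("R", "A", "B")))
  # predicted: g1 = {R, A, B}, g2 = {R, A} at threshold 0.5
  scores <- score_mat(c(1, 1, 1, 0), c("g1", "g2"), c("A", "B"))
  res <- hierarchical_prf(truth, scores, 0.5, g)
  expect_equal(res$hprec, 0.8)
  expect_equal(res$hrec, 0.8)
  expect_equal(res$hf1, 0.8)
})

test_that("a perfect predictor scores 1 and empty predictions 0 recall", {
  g <- chain_graph()
  truth <- truth_store(list(g1 = c("R", "A"), g2 = c("R", "A", "B")))
  perfect <- score_mat(c(0.9, 0.1, 0.9, 0.9), c("g1", "g2"), c("A", "B"))
  res <- hierarchical_prf(truth, perfect, 0.5, g)
  expect_equal(res$hf1, 1)
  # above every score: P_i = {root}; precision stays 1, recall = root share
  res2 <- hierarchical_prf(truth, perfect, 0.95, g)
  expect_equal(res2$hprec, 1)
  expect_equal(res2$hrec, 2 / 5)
})

test_that("scored genes missing from the truth store are an error", {
  g <- chain_graph()
  truth <- truth_store(list(g1 = c("R", "A")))
  scores <- score_mat(c(1, 1, 1, 0), c("g1", "gX"), c("A", "B"))
  expect_error(hierarchical_prf(truth, scores, 0.5, g), "absent from the truth")
})

test_that("curves match brute-force enumeration and hRec never increases", {
  for (seed in 1:10) {
    g <- random_dag(sample(5:15, 1), seed)
    root <- unname(g$roots)
    terms <- setdiff(g$terms$term_id, root)
    set.seed(seed + 50)
    n_genes <- sample(3:20, 1)
    genes <- paste0("g", seq_len(n_genes))
    raw <- annotation_store(tibble::tibble(
      gene_id = c(genes, sample(genes, 2 * n_genes, replace = TRUE)),
      term_id = sample(terms, 3 * n_genes, replace = TRUE)
    ), namespace = "BP")
    truth <- propagate(raw, g)
    sterms <- sample(terms, min(length(terms), 8))
    scores <- score_mat(runif(n_genes * length(sterms)), genes, sterms)
    grid <- seq(0, 1, 0.1)
    curve <- hf_curve(truth, scores, g, grid)
    truth_sets <- oracle_propagate_sets(raw, g, genes)
    for (j in seq_along(grid)) {
      pred_sets <- lapply(genes, function(gn) sterms[scores[gn, ] >= grid[j]])
      ora <- oracle_hprf(truth_sets, pred_sets, root)
      expect_equal(curve$hprec[j], ora[["hprec"]])
      expect_equal(curve$hrec[j], ora[["hrec"]])
      expect_equal(curve$hf1[j], ora[["hf1"]])
    }
    expect_true(all(diff(curve$hrec) <= 1e-12))
    expect_true(all(curve$hf1 <= attr(curve, "hf_max") + 1e-12))
  }
})

test_that("on a one-level ontology the metrics reduce to micro precision/recall", {
  # root R with leaf children only: hierarchical sets add nothing beyond the
  # root, so the sums reduce to flat TP/(TP+FP) and TP/(TP+FN) with the root
  # as a universally true, universally predicted label
  g <- ontology_graph(
    terms = tibble::tibble(term_id = c("R", "L1", "L2", "L3"), namespace = "BP"),
    edges = tibble::tibble(child = c("L1", "L2", "L3"), parent = "R")
  )
  truth <- truth_store(list(
    g1 = c("R", "L1"), g2 = c("R", "L2", "L3"), g3 = c("R")
  ))
  scores <- score_mat(
    c(0.9, 0.2, 0.8,
      0.1, 0.9, 0.1,
      0.9, 0.9, 0.1),
    c("g1", "g2", "g3"), c("L1", "L2", "L3")
  )
  res <- hierarchical_prf(truth, scores, 0.5, g)
  pred <- scores >= 0.5
  tr <- matrix(c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE),
               3, 3, byrow = TRUE)
  tp <- sum(pred & tr) + 3  # + one root per gene
  expect_equal(res$hprec, tp / (sum(pred) + 3))
  expect_equal(res$hrec, tp / (sum(tr) + 3))
})

test_that("constant scores produce a two-regime curve with hF-max at a tie's smallest threshold", {
  g <- chain_graph()
  truth <- truth_store(list(g1 = c("R", "A", "B")))
  scores <- score_mat(c(0.5, 0.5), "g1", c("A", "B"))
  curve <- hf_curve(truth, scores, g, seq(0, 1, 0.01))
  expect_equal(length(unique(round(curve$hf1, 12))), 2L)
  expect_equal(attr(curve, "threshold_at_max"), 0)
})

test_that("the null model scores every gene at the term's training frequency", {
  g <- chain_graph()
  st <- propagate(annotation_store(tibble::tibble(
    gene_id = sprintf("t%02d", 1:25), term_id = rep(c("B", "A"), c(5, 20))
  )), g)
  train <- sprintf("t%02d", 1:20)  # B on 5/20 = 0.25 of T genes
  sc <- random_scores(st, train, c("e1", "e2"), c("A", "B"))
  expect_equal(unname(sc[, "B"]), c(0.25, 0.25))
  expect_equal(length(unique(sc[, "A"])), 1L)  # constant columns
  # absent term scores 0
  sc2 <- random_scores(st, train, "e1", c("A", "Z"))
  expect_equal(unname(sc2[, "Z"]), 0)
  expect_error(random_scores(st, character(0), "e1", "A"), "non-empty")
})

test_that("ratio curves exclude zero-denominator points from the argmax", {
  base <- tibble::tibble(threshold = c(0, 0.5, 1),
                         hprec = 1, hrec = 1, hf1 = c(0.4, 0.6, 0.2))
  trained <- structure(base, class = c("hf_curve", class(base)))
  rnd <- base
  rnd$hf1 <- c(0.2, 0.3, 0)
  rnd <- structure(rnd, class = c("hf_curve", class(rnd)))
  rc <- ratio_curve(trained, rnd)
  expect_equal(rc$ratio[1:2], c(2, 2))
  expect_true(is.na(rc$ratio[3]))
  expect_equal(attr(rc, "theta_star"), 0)  # tie -> smallest threshold
  expect_equal(attr(rc, "max_ratio"), 2)
  # identical curves give ratio 1 everywhere it is defined
  rc2 <- ratio_curve(trained, trained)
  expect_true(all(rc2$ratio == 1))
  expect_error(
    ratio_curve(trained, structure(base[1:2, ], class = class(trained))),
    "identical threshold grid"
  )
})

test_that("final predictions keep only the most specific term per branch", {
  g <- tree_graph()
  scores <- score_mat(
    c(0.9, 0.8, 0.9, 0.2,
      0.9, 0.2, 0.9, 0.9),
    c("g1", "g2"), c("A", "B", "C", "D")
  )
  consistent <- enforce_hierarchy(scores, g)
  preds <- finalize_predictions(consistent, 0.5, g)
  # g1: kept {A, B, C}; A is ancestral to B -> emit B and C
  expect_setequal(preds$term_id[preds$gene_id == "g1"], c("B", "C"))
  # g2: kept {A, C, D}; C ancestral to D -> emit A and D (two branches)
  expect_setequal(preds$term_id[preds$gene_id == "g2"], c("A", "D"))
  expect_false("R" %in% preds$term_id)
  expect_equal(preds$depth[preds$gene_id == "g1" & preds$term_id == "B"], 2L)
  # no emitted term is an ancestor of another emitted term of the same gene
  for (gn in unique(preds$gene_id)) {
    kept <- preds$term_id[preds$gene_id == gn]
    anc <- unique(unlist(lapply(kept, relatives, graph = g, relation = "ancestors")))
    expect_length(intersect(kept, anc), 0L)
  }
  # threshold above every score: empty set
  expect_equal(nrow(finalize_predictions(consistent, 1.01, g)), 0L)
  # known associations can be excluded
  known <- annotation_store(tibble::tibble(gene_id = "g1", term_id = "B"))
  expect_false("B" %in%
    finalize_predictions(consistent, 0.5, g, known = known)$term_id)
})

test_that("depth histograms conserve counts and include empty depths", {
  g <- tree_graph()
  preds <- structure(
    tibble::tibble(
      gene_id = c("g1", "g2", "g3"), term_id = c("B", "D", "B"),
      score = 1, depth = c(2L, 2L, 2L)
    ),
    class = c("prediction_set", class(tibble::tibble())), threshold = 0.5
  )
  h <- predictions_by_depth(preds, g)
  expect_equal(h$depth, 0:2)
  expect_equal(h$n, c(0L, 0L, 3L))
  expect_equal(sum(h$n), nrow(preds))
  empty <- preds[0, ]
  expect_equal(sum(predictions_by_depth(empty, g)$n), 0L)
})

test_that("curve and prediction writers emit the documented layouts", {
  g <- chain_graph()
  truth <- truth_store(list(g1 = c("R", "A", "B")))
  scores <- score_mat(c(0.8, 0.4), "g1", c("A", "B"))
  tc <- hf_curve(truth, scores, g, seq(0, 1, 0.25))
  nc <- hf_curve(truth, random_scores(truth, "g1", "g1", c("A", "B")), g, seq(0, 1, 0.25))
  rc <- ratio_curve(tc, nc)
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_curve_tsv(tc, rc, cpath)
  out <- readr::read_tsv(cpath, show_col_types = FALSE)
  expect_named(out, c("threshold", "hprec", "hrec", "hf1", "hf1_random", "ratio"))

  preds <- finalize_predictions(scores, 0.3, g)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_predictions_tsv(preds, ppath)
  expect_match(readLines(ppath, n = 1), "threshold=0.3")
})
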