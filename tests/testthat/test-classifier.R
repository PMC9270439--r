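test_that("siblings policy selects the documented positives and negatives", {
  # R -> {A, C}; A -> {B, D}: for target B, sibling D and uncle C supply
  # negatives
  g <- ontology_graph(
    terms = tibble::tibble(term_id = c("R", "A", "B", "C", "D"), namespace = "BP"),
    edges = tibble::tibble(child = c("A", "C", "B", "D"), parent = c("R", "R", "A", "A"))
  )
  st <- annotation_store(tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2", "g2", "g2", "g3", "g3"),
    term_id = c("B", "A", "R", "D", "A", "R", "C", "R")
  ), propagated = TRUE)
  sp <- structure(list(train = c("g1", "g2", "g3"), eval = character(0),
                       fraction = 1, seed = 1), class = "train_eval_split")
  ts <- siblings_training_set(g, st, sp, "B")
  expect_equal(ts$positives, "g1")
  expect_setequal(ts$negatives, c("g2", "g3"))
  expect_false(ts$fallback)

  # a gene annotated with both target and a sibling is a positive only
  st2 <- annotation_store(dplyr::bind_rows(
    st$assoc, tibble::tibble(gene_id = "g1", term_id = "D")
  ), propagated = TRUE)
  ts2 <- siblings_training_set(g, st2, sp, "B")
  expect_equal(ts2$positives, "g1")
  expect_false("g1" %in% ts2$negatives)
})

test_that("targets without sibling/uncle genes fall back to random negatives", {
  g <- chain_graph()  # A has no siblings or uncles
  st <- annotation_store(tibble::tibble(
    gene_id = c("g1", "g1", "g2"), term_id = c("A", "R", "R")
  ), propagated = TRUE)
  sp <- structure(list(train = c("g1", "g2", "g3"), eval = character(0),
                       fraction = 1, seed = 1), class = "train_eval_split")
  expect_message(ts <- siblings_training_set(g, st, sp, "A"), "fallback")
  expect_true(ts$fallback)
  expect_equal(ts$positives, "g1")
  expect_true(all(ts$negatives %in% c("g2", "g3")))
})

separable_data <- function(n = 60, p = 4, seed = 1) {
  set.seed(seed)
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  x[, 1] <- x[, 1] + ifelse(labels, 6, -6)
  list(x = x, y = labels)
}

test_that("random-forest fitting is accurate on separable data and deterministic", {
  d <- separable_data()
  grid <- default_grid(num_trees = 50, max_depth = c(5, 0))
  m1 <- fit_term_model(d$x, d$y, grid = grid, folds = 3, seed = 42, target = "X")
  prob <- predict(m1$fit, data = d$x, num.threads = 1)$predictions[, "pos"]
  expect_equal(prob >= 0.5, d$y)
  expect_gt(m1$cv_f1, 0.95)
  expect_true(m1$params$num_trees %in% grid$num_trees)

  m2 <- fit_term_model(d$x, d$y, grid = grid, folds = 3, seed = 42, target = "X")
  expect_identical(m1$params, m2$params)
  expect_equal(
    prob,
    predict(m2$fit, data = d$x, num.threads = 1)$predictions[, "pos"]
  )

  # single-point grid: that point is chosen, CV is reporting only
  m3 <- fit_term_model(d$x, d$y, grid = default_grid(50, 5), folds = 3, seed = 1)
  expect_equal(m3$params$num_trees, 50L)
  expect_false(is.na(m3$cv_f1))

  expect_error(
    fit_term_model(d$x, rep(TRUE, nrow(d$x)), target = "GO:X"),
    "single class.*|GO:X"
  )
})

test_that("scoring yields probabilities with the trained feature layout", {
  gm <- linear_genome(c(60, 40))
  graph <- tree_graph()
  set.seed(5)
  genes <- tidy(gm)$gene_id
  st <- propagate(annotation_store(tibble::tibble(
    gene_id = sample(genes, 150, replace = TRUE),
    term_id = sample(c("B", "D"), 150, replace = TRUE)
  )), graph)
  sp <- split_train_eval(gm, 0.8, seed = 3)
  masked <- mask_annotations(st, sp$eval)
  models <- train_term_models(
    gm, masked, graph, sp, c("A", "B"),
    grid = default_grid(30, 5), folds = 0, seed = 11,
    half_widths = c(3, 8)
  )
  expect_s3_class(models, "term_model_set")
  expect_equal(models$target, c("A", "B"))
  sc <- score_genes(models, gm, masked, graph, sp$eval)
  expect_equal(dim(sc), c(length(sp$eval), 2L))
  expect_true(all(sc >= 0 & sc <= 1))
  # single gene still yields a 1 x terms matrix
  sc1 <- score_genes(models, gm, masked, graph, sp$eval[1])
  expect_equal(dim(sc1), c(1L, 2L))
  expect_equal(sc1[1, ], sc[1, ])
})

test_that("hierarchy enforcement caps children at their parents' scores", {
  g <- chain_graph()
  s <- matrix(c(0.2, 0.9), 1, 2, dimnames = list("g1", c("A", "B")))
  class(s) <- c("score_matrix", "matrix", "array")
  out <- enforce_hierarchy(s, g)
  expect_equal(out["g1", "B"], 0.2)
  expect_equal(out["g1", "A"], 0.2)
  # already-consistent input is unchanged; idempotence
  expect_equal(unclass(enforce_hierarchy(out, g)), unclass(out))

  # diamond: child capped by the minimum over both parents
  d <- diamond_graph()
  s2 <- matrix(c(0.5, 0.3, 0.4), 1, 3, dimnames = list("g1", c("A", "C", "B")))
  class(s2) <- c("score_matrix", "matrix", "array")
  out2 <- enforce_hierarchy(s2, d)
  expect_equal(out2["g1", "B"], 0.3)
})

test_that("enforcement removes all violations and never raises a score", {
  for (seed in 1:12) {
    g <- random_dag(sample(4:10, 1), seed)
    terms <- setdiff(g$terms$term_id, unname(g$roots))
    set.seed(seed + 100)
    terms <- sample(terms, sample(2:length(terms), 1))
    n_genes <- sample(2:6, 1)
    s <- matrix(runif(n_genes * length(terms)), n_genes, length(terms),
                dimnames = list(paste0("g", seq_len(n_genes)), terms))
    class(s) <- c("score_matrix", "matrix", "array")
    out <- enforce_hierarchy(s, g)
    expect_true(all(out <= s + 1e-12))
    # zero parent-child violations among scored terms
    for (t in terms) {
      for (p in intersect(relatives(g, t, "ancestors"), terms)) {
        expect_true(all(out[, t] <= out[, p] + 1e-12))
      }
    }
    # prediction sets derived from consistent scores are ancestor-closed
    for (theta in c(0.2, 0.5, 0.8)) {
      for (i in seq_len(n_genes)) {
        pset <- terms[out[i, ] >= theta]
        anc <- intersect(
          unique(unlist(lapply(pset, relatives, graph = g, relation = "ancestors"))),
          terms
        )
        expect_true(all(anc %in% pset))
      }
    }
    expect_equal(unclass(enforce_hierarchy(out, g)), unclass(out))
  }
})

test_that("score matrices round-trip through the 3-column TSV", {
  s <- matrix(c(0.1, 0.7, 0.25, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("A", "B")))
  class(s) <- c("score_matrix", "matrix", "array")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores_tsv(s, path)
  back <- read_scores_tsv(path)
  expect_equal(unclass(back), unclass(s))
  long <- tidy(s)
  expect_named(long, c("gene_id", "term_id", "score"))
  expect_equal(nrow(long), 4L)
})
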