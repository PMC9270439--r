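annotate_ranks <- function(model, term, arm, ranks) {
  g <- tidy(model)
  annotation_store(tibble::tibble(
    gene_id = g$gene_id[g$arm == arm & g$rank %in% ranks],
    term_id = term
  ), propagated = TRUE)
}

test_that("window counts match the definition on a worked arm", {
  gm <- linear_genome(12)
  st <- annotate_ranks(gm, "X", "arm1", 3:5)
  focal <- tidy(gm)$gene_id[tidy(gm)$rank == 4]
  wc <- window_counts(gm, st, "X", focal, 2)
  expect_equal(wc$N, 12L)
  expect_equal(wc$M, 3L)
  expect_equal(wc$n, 4L)  # focal excluded
  expect_equal(wc$k, 2L)  # ranks 3 and 5
  ora <- oracle_window_counts(gm, st, "X", focal, 2)
  expect_equal(as.list(wc[c("N", "M", "n", "k")]), ora)

  # unannotated arm
  wc0 <- window_counts(gm, st, "Y", focal, 2)
  expect_equal(wc0$M, 0L)
  expect_equal(wc0$k, 0L)

  # w beyond the arm: n = N - 1 and k = M - [focal annotated]
  wcall <- window_counts(gm, st, "X", focal, 100)
  expect_equal(wcall$n, 11L)
  expect_equal(wcall$k, 2L)
})

test_that("local enrichment follows (k/n)/(M/N) with documented conventions", {
  expect_equal(local_enrichment(tibble::tibble(N = 100, M = 10, n = 20, k = 2)), 1.0)
  expect_equal(local_enrichment(tibble::tibble(N = 100, M = 10, n = 20, k = 5)), 2.5)
  expect_equal(local_enrichment(tibble::tibble(N = 100, M = 10, n = 20, k = 0)), 0)
  expect_equal(local_enrichment(tibble::tibble(N = 100, M = 0, n = 20, k = 0)), 0)
  expect_warning(
    out <- local_enrichment(tibble::tibble(N = 1, M = 0, n = 0, k = 0)),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("enrichment maps match the sliding recount oracle exactly", {
  set.seed(42)
  for (rep in 1:5) {
    arm_sizes <- sample(20:120, sample(1:2, 1))
    gm <- linear_genome(arm_sizes)
    genes <- tidy(gm)
    terms <- sprintf("X%d", 1:3)
    st <- annotation_store(tibble::tibble(
      gene_id = sample(genes$gene_id, 60, replace = TRUE),
      term_id = sample(terms, 60, replace = TRUE)
    ), propagated = TRUE)
    map <- enrichment_map(gm, st, terms, half_widths = c(2, 5, 10), min_annotated = 0)
    for (term in terms) {
      for (arm in unique(genes$arm)) {
        a <- genes$gene_id[genes$arm == arm] %in%
          st$assoc$gene_id[st$assoc$term_id == term]
        for (w in c(2, 5, 10)) {
          got <- map$enrichment[map$term_id == term & map$arm == arm & map$w == w]
          expect_equal(got, oracle_arm_enrichment(a, w), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("uniformly spread annotations give enrichment near 1", {
  gm <- linear_genome(1000)
  st <- annotate_ranks(gm, "X", "arm1", seq(0, 999, by = 10))
  map <- enrichment_map(gm, st, "X", half_widths = 50, min_annotated = 0)
  expect_lt(abs(mean(map$enrichment) - 1), 0.1)
})

test_that("a contiguous cluster peaks near N/M at its centre", {
  gm <- linear_genome(400)
  st <- annotate_ranks(gm, "X", "arm1", 190:209)  # M = 20 contiguous
  map <- enrichment_map(gm, st, "X", half_widths = 10, min_annotated = 0)
  centre <- map$enrichment[map$position == 200]
  # the 20-gene window at the cluster centre holds 19 carriers (focal
  # excluded): E = (19/20)/(20/400) = 19, close to the N/M = 20 ceiling
  expect_equal(centre, 19)
  expect_equal(max(map$enrichment), centre)
})

test_that("map mode floor skips sparse terms with a notice", {
  gm <- linear_genome(50)
  st <- annotate_ranks(gm, "X", "arm1", 1:5)
  expect_message(map <- enrichment_map(gm, st, "X", min_annotated = 20), "floor")
  expect_equal(nrow(map), 0L)
  map2 <- enrichment_map(gm, st, "X", min_annotated = 0)
  expect_equal(nrow(map2), 50L * 5L)
})

test_that("masking a gene never increases any window count", {
  gm <- linear_genome(c(40, 30))
  set.seed(7)
  genes <- tidy(gm)$gene_id
  st <- annotation_store(tibble::tibble(
    gene_id = sample(genes, 50, replace = TRUE), term_id = "X"
  ), propagated = TRUE)
  masked <- mask_annotations(st, sample(genes, 10))
  for (g in sample(genes, 8)) {
    for (w in c(3, 10)) {
      before <- window_counts(gm, st, "X", g, w)
      after <- window_counts(gm, masked, "X", g, w)
      expect_lte(after$k, before$k)
      expect_lte(after$M, before$M)
      expect_equal(after$n, before$n)  # masked genes keep their positions
      expect_equal(after$N, before$N)
    }
  }
})

test_that("k/n equals M/N everywhere once the window swallows the arm", {
  gm <- linear_genome(30)
  st <- annotate_ranks(gm, "X", "arm1", c(2, 9, 17, 25))
  map <- enrichment_map(gm, st, "X", half_widths = 30, min_annotated = 0)
  # every window holds all carriers except possibly the focal gene itself
  g <- tidy(gm)
  carriers <- g$rank[g$gene_id %in% st$assoc$gene_id]
  expected <- ifelse(g$rank %in% carriers, (3 / 29) / (4 / 30), (4 / 29) / (4 / 30))
  expect_equal(map$enrichment[order(map$position)], expected[order(g$rank)])
})

test_that("map TSV and bedGraph writers emit the documented layouts", {
  gm <- linear_genome(25)
  st <- annotate_ranks(gm, "X", "arm1", 5:9)
  map <- enrichment_map(gm, st, "X", half_widths = c(3, 6), min_annotated = 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_map(map, path)
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  expect_equal(nrow(out), 50L)
  expect_named(out, c("term_id", "arm", "position", "gene_id", "w", "enrichment"))

  bg <- withr::local_tempfile(fileext = ".bedGraph")
  write_enrichment_bedgraph(map, gm, "X", 3, bg)
  expect_match(readLines(bg, n = 1), "bedGraph")
  bed <- readr::read_tsv(bg, skip = 1, col_names = FALSE, show_col_types = FALSE)
  expect_equal(nrow(bed), 25L)
  expect_equal(bed$X3 - bed$X2, rep(1L, 25))
})
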