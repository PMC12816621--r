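test_that("log-normalization matches hand arithmetic and guards zero columns", {
  m <- matrix(c(30, 70), 2, 1, dimnames = list(c("A", "B"), "s1"))
  out <- log_normalize(m, scale = 100, log_base = 2)
  expect_equal(unclass(out)[, 1], c(A = log2(31), B = log2(71)))

  # one gene holding the whole library, natural log: log(1 + scale)
  one <- matrix(50, 1, 1, dimnames = list("G", "s"))
  expect_equal(unname(unclass(log_normalize(one, scale = 7,
                                            log_base = exp(1)))[1, 1]),
               log(1 + 7))

  bad <- matrix(c(1, 2, 0, 0), 2, 2,
                dimnames = list(c("A", "B"), c("ok", "empty")))
  expect_error(log_normalize(bad), "empty")
})

test_that("signature scores are per-sample means over present genes only", {
  expr <- toy_expr(c(1, 2, 6, 2, 2, 2), c("GA", "GB", "GC"), c("s1", "s2"))
  sig <- gene_set("toy", c("GA", "GB", "GC"))
  sc <- signature_score(expr, sig)
  expect_equal(sc$scores, c(3, 2))
  expect_equal(sc$genes_used, c("GA", "GB", "GC"))

  # one-gene signature reproduces that gene's row
  sc1 <- signature_score(expr, gene_set("one", "GB"))
  expect_equal(sc1$scores, unname(unclass(expr)["GB", ]))

  # invariance to gene order and to genes outside the signature
  shuffled <- toy_expr(c(6, 1, 2, 9, 2, 2, 2, 0), c("GC", "GA", "GB", "XX"),
                       c("s1", "s2"))
  expect_equal(signature_score(shuffled, sig)$scores, sc$scores)

  # missing genes are reported and trip the coverage threshold
  small <- toy_expr(c(1, 2), "GA", c("s1", "s2"))
  expect_warning(res <- signature_score(small, gene_set("m", c("GA", "GB")),
                                        min_fraction = 0.5),
                 "absent")
  expect_equal(res$genes_missing, "GB")
  expect_error(signature_score(small, gene_set("m", c("GA", "GB", "GC")),
                               min_fraction = 0.8),
               "coverage")
})

test_that("symbol reconciliation maps PKM2 onto PKM case-insensitively", {
  expr <- toy_expr(c(5, 1), c("PKM", "HK1"), "s1")
  sig <- gene_set("g", c("pkm2", " HK1"))
  expect_equal(sig$genes, c("PKM", "HK1"))
  expect_equal(signature_score(expr, sig)$scores, 3)
  expect_equal(length(glycolytic_signature()), 14L)
})

test_that("median split labels only strict exceedances High", {
  mk <- function(x) signature_score(
    toy_expr(x, "G", paste0("s", seq_along(x))), gene_set("g", "G"))
  g <- stratify_by_median(mk(c(1, 2, 3, 4)))
  expect_equal(as.character(g$labels), c("Low", "Low", "High", "High"))
  expect_equal(g$thresholds, 2.5)

  # odd n: only the maximum strictly exceeds the median
  g3 <- stratify_by_median(mk(c(1, 2, 3)))
  expect_equal(as.character(g3$labels), c("Low", "Low", "High"))

  # all tied: nothing exceeds the median
  gt <- stratify_by_median(mk(rep(2, 5)))
  expect_true(all(gt$labels == "Low"))

  expect_error(stratify_by_median(mk(1)), "at least 2")
})

test_that("tertile split matches an independent sort-and-cut oracle", {
  mk <- function(x) signature_score(
    toy_expr(x, "G", paste0("s", seq_along(x))), gene_set("g", "G"))
  g9 <- stratify_by_tertiles(mk(1:9))
  expect_equal(unname(table(g9$labels)), rep(3L, 3), ignore_attr = TRUE)

  for (x in list(1:10, c(5, 1, 9, 2, 8, 3, 7, 4, 6, 10),
                 rnorm(17), runif(30))) {
    g <- stratify_by_tertiles(mk(x))
    expect_equal(as.character(g$labels), oracle_tertiles(x))
  }

  # degenerate distribution: equal thresholds put everything in Low
  gt <- stratify_by_tertiles(mk(rep(1.5, 6)))
  expect_true(all(gt$labels == "Low"))
  expect_error(stratify_by_tertiles(mk(c(1, 2))), "at least 3")
})

test_that("stratifiers are rank-determined: monotone transforms preserve labels", {
  set.seed(42)
  x <- rnorm(12)
  mk <- function(v) signature_score(
    toy_expr(v, "G", paste0("s", seq_along(v))), gene_set("g", "G"))
  med1 <- stratify_by_median(mk(x))$labels
  ter1 <- stratify_by_tertiles(mk(x))$labels
  for (f in list(function(v) 3 * v + 7, function(v) exp(v),
                 function(v) rank(v))) {
    expect_equal(stratify_by_median(mk(f(x)))$labels, med1)
    expect_equal(stratify_by_tertiles(mk(f(x)))$labels, ter1)
  }
})

test_that("hypoxia signature construction is a guarded, commutative intersection", {
  a <- gene_set("up", c("A", "B", "C"))
  b <- gene_set("hif", c("B", "C", "D"))
  expect_equal(build_hypoxia_signature(a, b)$genes, c("B", "C"))
  expect_setequal(build_hypoxia_signature(b, a)$genes,
                  build_hypoxia_signature(a, b)$genes)
  # idempotence: intersecting a set with itself returns it
  expect_equal(build_hypoxia_signature(a, a)$genes, a$genes)
  expect_error(build_hypoxia_signature(a, gene_set("d", c("X", "Y"))),
               "no genes")
})

test_that("hypoxia scores are per-sample medians", {
  expr <- toy_expr(c(1, 5, 9, 1, 2, 8), c("GA", "GB", "GC"), c("s1", "s2"))
  sig <- gene_set("h", c("GA", "GB", "GC"))
  expect_equal(hypoxia_score(expr, sig)$scores, c(5, 2))

  # even-count median: midpoint of the two central order statistics
  e4 <- toy_expr(c(1, 2, 8, 9), paste0("G", 1:4), "s1")
  expect_equal(hypoxia_score(e4, gene_set("h4", paste0("G", 1:4)))$scores, 5)

  # brute-force sort-and-pick oracle on a random 7-gene sample
  set.seed(7)
  v <- rnorm(7)
  e7 <- toy_expr(v, paste0("G", 1:7), "s1")
  srt <- sort(v)
  expect_equal(hypoxia_score(e7, gene_set("h7", paste0("G", 1:7)))$scores,
               srt[4])
})

test_that("subtype calls take the argmax of signature means, ties to Classical", {
  basal <- gene_set("basal", c("BA", "BB"))
  classical <- gene_set("classical", c("CA", "CB"))
  expr <- toy_expr(c(2, 2, 1, 1,   0, 0, 3, 3,   1, 1, 1, 1),
                   c("BA", "BB", "CA", "CB"), c("s1", "s2", "s3"))
  expect_warning(g <- call_subtype(expr, basal, classical), "tied")
  expect_equal(as.character(g$labels),
               c("Basal-like", "Classical", "Classical"))

  # brute-force two-mean comparison on a random matrix
  set.seed(3)
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(c("BA", "BB", "CA", "CB"), paste0("s", 1:10)))
  g2 <- call_subtype(expression_matrix(vals), basal, classical)
  manual <- ifelse(colMeans(vals[1:2, ]) > colMeans(vals[3:4, ]),
                   "Basal-like", "Classical")
  expect_equal(as.character(g2$labels), unname(manual))
})

test_that("purity bins use <50 / 50-75 / >75 with closed middle boundaries", {
  g <- bin_purity(c(a = 49.9, b = 50, c = 75, d = 75.1, e = 60))
  expect_equal(as.character(g$labels), c("low", "mid", "mid", "high", "mid"))
  expect_true(all(bin_purity(rep(60, 4))$labels == "mid"))
  expect_error(bin_purity(c(10, 101)), "\\[0, 100\\]")
  expect_error(bin_purity(c(-0.1, 50)), "\\[0, 100\\]")
})

test_that("median split over signature scores recovers planted patient labels", {
  for (s in 1:50) {
    sim <- gen_single_cell(sim_config(n_patients = 6, cells_per_patient = 12,
                                      n_genes = 30, glyco_shift = 3,
                                      noise_sd = 0.5, seed = s))
    sc <- signature_score(sim$expr, glycolytic_signature())
    by_patient <- tapply(sc$scores, sim$cells$patient_id, mean)
    psv <- score_vector(names(by_patient), as.vector(by_patient),
                        "glycolytic")
    g <- stratify_by_median(psv)
    called <- ifelse(g$labels == "High", "high", "low")
    expect_equal(unname(called), unname(sim$truth[g$sample_ids]))
  }
})
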