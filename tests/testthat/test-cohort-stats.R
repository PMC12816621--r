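make_cohort <- function(group, ...) {
  vars <- list(...)
  df <- data.frame(sample_id = paste0("s", seq_along(group)),
                   group = factor(group), stringsAsFactors = FALSE)
  for (nm in names(vars)) df[[nm]] <- vars[[nm]]
  df
}

test_that("contingency tables tally the cohort and exclude missing values", {
  co <- make_cohort(c("High", "High", "Low", "Low"),
                    kras = c("mutant", "wildtype", "mutant", "wildtype"))
  tab <- contingency(co, "kras")
  expect_equal(as.vector(tab), rep(1L, 4))

  co2 <- make_cohort(rep(c("High", "Low"), 5),
                     kras = c(NA, "mutant", "wildtype", "mutant", "wildtype",
                              "mutant", "wildtype", NA, "mutant", "wildtype"))
  tab2 <- contingency(co2, "kras")
  expect_equal(sum(tab2), 8)
  expect_equal(attr(tab2, "n_excluded"), 2L)

  # brute-force nested-loop tally on a random cohort
  set.seed(31)
  co3 <- make_cohort(sample(c("High", "Low"), 60, TRUE),
                     stage = sample(c("T2", "T3"), 60, TRUE))
  tab3 <- contingency(co3, "stage")
  for (g in rownames(tab3)) {
    for (v in colnames(tab3)) {
      n <- 0
      for (i in seq_len(nrow(co3))) {
        if (co3$group[i] == g && co3$stage[i] == v) n <- n + 1
      }
      expect_equal(unname(tab3[g, v]), n)
    }
  }

  expect_error(contingency(co, "nope"), "not found")
  expect_error(contingency(make_cohort(rep("High", 4),
                                       kras = rep("mutant", 4)), "kras"),
               "degenerate")
})

test_that("association test matches the hypergeometric oracle and chooser rule", {
  tab <- matrix(c(8, 1, 2, 9), 2, 2)
  res <- association_test(tab)
  expect_equal(res$p_fisher, oracle_fisher_2x2(tab), tolerance = 1e-10)
  # n = 20 < 40 for a 2x2 table, so Fisher is primary
  expect_equal(res$method, "fisher")
  expect_equal(res$p_primary, round(res$p_fisher, 4))
  expect_true(res$significant)

  # perfect independence: chi-square statistic 0, p = 1
  flat <- association_test(matrix(5, 2, 2))
  expect_equal(flat$p_chisq, 1)
  expect_false(flat$significant)

  # extreme diagonal table: both tests < 1e-4, reported primary rounds to 0
  diag <- association_test(matrix(c(50, 0, 0, 50), 2, 2))
  expect_equal(diag$p_primary, 0)
  expect_lt(diag$p_exact, 1e-4)
  expect_lt(oracle_fisher_2x2(matrix(c(50, 0, 0, 50), 2, 2)), 1e-4)

  # large balanced table with ample expected counts: chi-square is primary
  big <- association_test(matrix(c(70, 50, 55, 75), 2, 2))
  expect_equal(big$method, "chisq")

  expect_error(association_test(matrix(c(1.5, 2, 3, 4), 2, 2)),
               "non-negative integers")
  expect_error(association_test(matrix(c(-1L, 2L, 3L, 4L), 2, 2)),
               "non-negative integers")
})

test_that("Fisher and chi-square agree on large 2x2 tables in the decision-relevant regime", {
  # The two tests can disagree by up to ~0.09 at mid-range p even with all
  # expected counts >= 20; where the decision is clear-cut — strongly
  # associated tables and (near-)independent ones — they agree closely.
  clear_cut <- list(matrix(c(95, 45, 55, 105), 2, 2),   # strong association
                    matrix(c(100, 48, 52, 100), 2, 2),  # strong association
                    matrix(c(75, 75, 75, 75), 2, 2),    # exact independence
                    matrix(c(76, 74, 74, 76), 2, 2))    # near independence
  for (tab in clear_cut) {
    res <- association_test(tab)
    expect_lt(abs(res$p_fisher - res$p_chisq), 0.02)
  }
})

test_that("ranked association report orders variables by primary p", {
  co <- gen_cohort(cohort_sim_config(n_samples = 150, seed = 44))
  out <- rank_associations(co)
  expect_equal(out$rank, seq_len(nrow(out)))
  expect_false(is.unsorted(out$p_primary))
  expect_equal(out$significant, out$p_primary < 0.05)
  # reported p values carry exactly four decimals
  expect_equal(out$p_primary, round(out$p_primary, 4))
})

test_that("BH adjustment matches the step-up hand oracle and its invariants", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))

  set.seed(23)
  p <- runif(25)
  adj <- bh_adjust(p)
  expect_equal(adj, oracle_bh(p))
  expect_true(all(adj >= p))
  expect_equal(bh_adjust(adj), adj)  # idempotent on monotone inputs

  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log-rank statistic matches the hand observed-minus-expected oracle", {
  co <- make_cohort(rep(c("A", "B"), each = 4),
                    time = c(1, 2, 3, 4, 2, 4, 5, 6),
                    event = c(1, 1, 0, 1, 0, 1, 1, 0))
  fit <- km_fit(co, horizon = 36)
  chisq <- oracle_logrank_chisq(c(1, 2, 3, 4), c(1, 1, 0, 1),
                                c(2, 4, 5, 6), c(0, 1, 1, 0))
  expect_equal(fit$logrank_chisq, chisq, tolerance = 1e-8)
  expect_equal(fit$logrank_p, pchisq(chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("KM curves start at 1, respect the horizon, and handle no events", {
  co <- gen_cohort(cohort_sim_config(n_samples = 120, seed = 2))
  fit <- km_fit(co, horizon = 36)
  for (g in unique(fit$curves$group)) {
    est <- fit$curves$estimate[fit$curves$group == g]
    expect_true(all(diff(est) <= 1e-12))
    expect_lte(est[1], 1)
  }
  expect_lte(max(fit$curves$time), 36)

  # identical time/event vectors in both groups: no separation
  co2 <- make_cohort(rep(c("A", "B"), each = 3),
                     time = rep(c(2, 5, 9), 2), event = rep(c(1, 1, 0), 2))
  fit2 <- km_fit(co2)
  expect_equal(fit2$logrank_chisq, 0, tolerance = 1e-12)
  expect_equal(fit2$logrank_p, 1)

  # zero events: flat curves, absent tests
  co3 <- make_cohort(rep(c("A", "B"), each = 3),
                     time = rep(10, 6), event = rep(0, 6))
  fit3 <- km_fit(co3)
  expect_true(all(fit3$curves$estimate == 1))
  expect_true(is.na(fit3$logrank_p))
  expect_true(is.na(fit3$trend_p))
})

test_that("events beyond the horizon are administratively censored", {
  co <- make_cohort(rep(c("A", "B"), each = 3),
                    time = c(10, 40, 50, 20, 45, 60),
                    event = c(1, 1, 1, 1, 1, 1))
  fit <- km_fit(co, horizon = 36)
  expect_equal(fit$n_events, 2)          # only the two pre-horizon events
  expect_lte(max(fit$curves$time), 36)
})

test_that("trend test responds to an ordered hazard gradient", {
  co <- gen_cohort(cohort_sim_config(n_samples = 240,
                                     hazard_ratio_high_vs_low = 3, seed = 6))
  fit <- km_fit(co)
  expect_lt(fit$trend_p, 0.01)
  expect_lt(fit$logrank_p, 0.01)
})

test_that("log-rank has power against hazard ratio 3 at n = 300", {
  rejections <- vapply(1:100, function(s) {
    co <- gen_cohort(cohort_sim_config(n_samples = 300,
                                       hazard_ratio_high_vs_low = 3,
                                       seed = s))
    km_fit(co)$logrank_p < 0.05
  }, TRUE)
  expect_gte(mean(rejections), 0.95)
})
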