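test_that("QQ summary uses Beta order-statistic medians and bands", {
  # n = 1: the single order statistic is uniform, so the 95% band endpoints
  # are the 0.025 and 0.975 uniform quantiles
  qq1 <- qq_summary(0.5, band_level = 0.95)
  expect_equal(qq1$expected, -log10(0.5))
  expect_equal(qq1$band_lower, -log10(0.975))
  expect_equal(qq1$band_upper, -log10(0.025))

  set.seed(1)
  p <- runif(500)
  qq <- qq_summary(p)
  expect_equal(attr(qq, "n_tests"), 500L)
  # observed quantiles are a sorted permutation of -log10 of the input
  expect_equal(sort(qq$observed), sort(-log10(p)))
  # monotone in rank, band brackets the expected curve at every rank
  expect_false(is.unsorted(qq$expected))
  expect_false(is.unsorted(qq$observed))
  expect_true(all(qq$band_lower <= qq$expected & qq$expected <= qq$band_upper))
  # uniform input: the vast majority of ranks sit inside the 95% band
  inside <- qq$observed >= qq$band_lower & qq$observed <= qq$band_upper
  expect_gte(mean(inside), 0.93)

  expect_error(qq_summary(numeric(0)), "no p-values")
  # p = 0 is floored, not -Inf
  expect_true(is.finite(qq_summary(c(0, 0.5))$observed[2]))
})

test_that("rejection-rate estimates carry exact binomial intervals", {
  expect_equal(estimate_rate(rep(1, 50))$rate, 0)
  set.seed(2)
  est <- estimate_rate(runif(10000), alpha = 0.05)
  expect_gt(est$rate, 0.04); expect_lt(est$rate, 0.06)
  ref <- binom.test(est$n_rejections, est$n_tests)$conf.int
  expect_equal(c(est$ci_low, est$ci_high), as.numeric(ref))
  expect_error(estimate_rate(numeric(0)), "no p-values")
})

test_that("run_experiment reproduces bit-identically from its seed and calibrates at the null", {
  panel <- sample_panel(150, variants_per_gene = 15, seed = 1)
  conditions <- list(
    null = error_spec(2, 0),
    sc2_r10 = error_spec(2, 0.10)
  )
  exp1 <- run_experiment(panel, conditions, n_trios = 80, n_replicates = 4,
                         seed = 42)
  exp2 <- run_experiment(panel, conditions, n_trios = 80, n_replicates = 4,
                         seed = 42)
  expect_identical(exp1$results, exp2$results)

  null_res <- exp1$results$null
  P <- null_res$totals[["P"]]; Q <- null_res$totals[["Q"]]
  expect_lt(abs(P / (P + Q) - 0.5), 3 * sqrt(0.25 / (P + Q)))
  expect_true(null_res$rate$ci_low <= 0.05 + 0.02)

  # offspring het loss shifts the tally toward non-transmission
  err_res <- exp1$results$sc2_r10
  expect_lt(err_res$totals[["P"]] / sum(err_res$totals), P / (P + Q))
  expect_match(null_res$tally_text[["transmitted"]], "\\(\\d+%\\)")
})

test_that("under-transmission dominates the top genes when offspring errors act on a null cohort", {
  panel <- sample_panel(300, variants_per_gene = 20, seed = 3)
  coh <- simulate_trios(panel, 100, seed = 4)
  inj <- inject_errors(coh, error_spec(2, 0.10), seed = 5)
  genes <- gene_tdt(tally(inj), panel)
  top <- genes[order(genes$p_value), ][1:20, ]
  # the diagnostic the analyst is told to check: top-ranked genes skewed to Q > P
  expect_gt(mean(top$Q_g > top$P_g), 0.5)
})
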