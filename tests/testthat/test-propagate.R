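test_that("percent_transmitted rounds to nearest with ties away from zero", {
  expect_equal(percent_transmitted(374502, 427972), 47L)
  expect_equal(percent_transmitted(17225, 11112), 61L)
  expect_equal(percent_transmitted(1, 1), 50L)
  expect_equal(percent_transmitted(905, 1095), 45L)  # 45.25 down
  expect_equal(percent_transmitted(91, 109), 46L)    # 45.5 ties up
  expect_error(percent_transmitted(0, 0), "positive")
})

test_that("propagation formulas follow each scenario's mechanism", {
  T0 <- 1000; U0 <- 1200

  s1 <- propagate(T0, U0, error_spec(1, 0.10))
  expect_equal(s1$T_out, 0.9 * T0)
  expect_equal(s1$U_out, 0.9 * U0)
  # proportional thinning leaves the percentage invariant at any rate
  for (r in c(0.01, 0.05, 0.10, 0.5)) {
    expect_equal(propagate(T0, U0, error_spec(1, r))$pct_transmitted,
                 percent_transmitted(T0, U0))
  }

  s2 <- propagate(T0, U0, error_spec(2, 0.10))
  expect_equal(s2$T_out, 0.9 * T0)
  expect_equal(s2$U_out, U0 + 0.1 * T0)
  expect_equal(s2$T_out + s2$U_out, T0 + U0) # event transfer conserves totals

  s3 <- propagate(T0, U0, error_spec(3, 0.01), homref_exposures = 50000)
  expect_equal(s3$T_out, T0) # false hets add only non-transmissions
  expect_equal(s3$U_out, U0 + 0.01 * 50000)
  expect_error(propagate(T0, U0, error_spec(3, 0.01)), "homref_exposures")

  s4 <- propagate(T0, U0, error_spec(4, 0.01))
  expect_equal(s4$T_out, T0 + 0.01 * U0)
  expect_equal(s4$U_out, 0.99 * U0)
  expect_equal(s4$T_out + s4$U_out, T0 + U0)

  # zero rates are the identity under every scenario
  for (sc in 1:4) {
    id <- propagate(T0, U0, error_spec(sc, 0),
                    homref_exposures = if (sc == 3) 1000 else NULL)
    expect_equal(id$T_out, T0)
    expect_equal(id$U_out, U0)
  }
})

test_that("exact expected tallies match injection simulations on a small cohort", {
  panel <- sample_panel(50, variants_per_gene = 20, seed = 1)
  coh <- simulate_trios(panel, 100, seed = 2)
  for (case in list(c(2, 0.10), c(3, 0.01))) {
    spec <- error_spec(case[1], case[2])
    pred <- expected_tally(coh, spec)
    sims <- sapply(1:20, function(r) {
      tt <- tally(inject_errors(coh, spec, seed = 100 * case[1] + r))$totals
      c(tt[["P"]], tt[["Q"]])
    })
    for (row in 1:2) {
      target <- c(pred$T_out, pred$U_out)[row]
      se <- max(stats::sd(sims[row, ]) / sqrt(ncol(sims)), 1e-9)
      expect_lt(abs(target - mean(sims[row, ])), 4 * se)
    }
  }
})

test_that("first-order propagation agrees with the exact expectation at low rates", {
  panel <- sample_panel(50, variants_per_gene = 20, seed = 3)
  coh <- simulate_trios(panel, 100, seed = 4)
  tc <- tally(coh, layer = "true")
  T0 <- tc$totals[["P"]]; U0 <- tc$totals[["Q"]]
  for (sc in 1:4) {
    rate <- if (sc <= 2) 0.01 else 0.001
    spec <- error_spec(sc, rate)
    first <- propagate(T0, U0, spec,
                       homref_exposures = count_homref_exposures(coh, spec))
    exact <- expected_tally(coh, spec)
    expect_equal(first$T_out, exact$T_out, tolerance = 2e-3)
    expect_equal(first$U_out, exact$U_out, tolerance = 2e-3)
  }
})

test_that("scenario-3 exposures count hom-ref targeted-parent cells", {
  coh <- manual_cohort(
    father = rbind(c(0L, 1L), c(0L, 0L)),
    mother = rbind(c(0L, 0L), c(2L, 0L)),
    child  = rbind(c(0L, 1L), c(1L, 0L))
  )
  spec <- error_spec(3, 0.01)
  expect_equal(count_homref_exposures(coh, spec), 3 + 3)
  expect_equal(count_homref_exposures(coh, error_spec(4, 0.01)), 2)
})
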