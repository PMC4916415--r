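test_that("consistency and transmission counts match the brute-force oracle on all 27 triples", {
  grid <- oracle_triples()
  got_ok <- mendelian_consistent(grid$f, grid$m, grid$c)
  expect_identical(unname(got_ok), grid$consistent)

  consistent <- grid[grid$consistent, ]
  tu <- count_transmissions(consistent$f, consistent$m, consistent$c)
  expect_identical(unname(tu[, "t"]), consistent$t)
  expect_identical(unname(tu[, "u"]), consistent$u)

  # spot checks from first principles
  expect_identical(count_transmissions(1, 0, 0),
                   cbind(t = 0L, u = 1L))
  expect_identical(count_transmissions(0, 0, 0),
                   cbind(t = 0L, u = 0L))
  expect_identical(count_transmissions(1, 1, 1),
                   cbind(t = 1L, u = 1L))
  # symmetric in parents
  expect_identical(count_transmissions(grid$m[grid$consistent],
                                       grid$f[grid$consistent],
                                       grid$c[grid$consistent]),
                   tu)
  expect_error(count_transmissions(0, 0, 1), "inconsistent")
  expect_error(count_transmissions(NA, 0, 0), "missing")
})

test_that("tally screens Mendelian errors per trio-variant cell and drops missing cells", {
  # trio 1 informative, trio 2 inconsistent at v1 only, trio 3 missing at v1
  coh <- manual_cohort(
    father = rbind(c(1L, 1L), c(0L, 1L), c(1L, 0L)),
    mother = rbind(c(0L, 0L), c(0L, 0L), c(0L, 0L)),
    child  = rbind(c(1L, 0L), c(1L, 1L), c(NA, 0L))
  )
  tc <- tally(coh)
  # v1: (1,0,1) -> (1,0); (0,0,1) inconsistent, excluded; (1,0,NA) dropped
  # v2: (1,0,0) -> (0,1); (1,0,1) -> (1,0); (0,0,0) -> (0,0)
  expect_equal(tc$per_variant$p, c(1L, 1L))
  expect_equal(tc$per_variant$q, c(0L, 1L))
  expect_equal(tc$per_variant$n_excluded, c(1L, 0L))
  expect_equal(unname(tc$totals), c(2, 1))
  expect_equal(tc$n_excluded, 1)

  # all hom-ref: every count zero
  z <- manual_cohort(matrix(0L, 2, 3), matrix(0L, 2, 3), matrix(0L, 2, 3))
  expect_equal(unname(tally(z)$totals), c(0, 0))
})

test_that("tally agrees with the recorded transmissions of the simulator", {
  panel <- sample_panel(20, variants_per_gene = 10, seed = 1)
  coh <- simulate_trios(panel, 200, seed = 2)
  tc <- tally(coh, layer = "true")
  # independent accounting: per parent, an event is recorded iff the parent
  # is het; transmitted when the recorded allele is the rare one
  het_f <- coh$true$father == 1L
  het_m <- coh$true$mother == 1L
  t_direct <- sum(coh$transmitted$father[het_f]) + sum(coh$transmitted$mother[het_m])
  u_direct <- sum(het_f) + sum(het_m) - t_direct
  expect_equal(tc$totals[["P"]], t_direct)
  expect_equal(tc$totals[["Q"]], u_direct)
})

test_that("TDT statistic follows the (p-q)^2/(p+q) form with chi-square tail", {
  expect_equal(tdt_test(5, 5)$statistic, 0)
  expect_equal(tdt_test(5, 5)$p_value, 1)
  expect_equal(tdt_test(10, 0)$statistic, 10)
  expect_equal(tdt_test(10, 0)$p_value, pchisq(10, 1, lower.tail = FALSE))
  expect_equal(tdt_test(3, 8)$statistic, tdt_test(8, 3)$statistic)
  uninformative <- tdt_test(0, 0)
  expect_true(is.na(uninformative$statistic))
  expect_equal(uninformative$p_value, 1)
  expect_error(tdt_test(-1, 2), "non-negative")
})

test_that("null per-variant transmissions are fair coin flips, calibrating the TDT", {
  # frequencies high enough that most variants clear p + q >= 10
  panel <- sample_panel(75, variants_per_gene = 100,
                        maf_spectrum = maf_spectrum_table(seq(0.025, 0.05, by = 0.005)),
                        maf_cap = 0.05, seed = 3)
  coh <- simulate_trios(panel, 200, seed = 4)
  res <- tdt_results(tally(coh, layer = "true"))
  res <- res[res$p + res$q >= 10, ]
  expect_gte(nrow(res), 5000)

  # exact form of the null: p ~ Binomial(p + q, 1/2) per variant. The
  # randomized probability integral transform of that law is exactly
  # uniform, so KS applies without the atoms the chi-square p-values carry.
  set.seed(5)
  pit <- pbinom(res$p - 1L, res$p + res$q, 0.5) +
    runif(nrow(res)) * dbinom(res$p, res$p + res$q, 0.5)
  ks <- ks.test(pit, "punif")
  expect_gt(ks$p.value, 0.01)

  # and the chi-square TDT p-values calibrate at conventional levels
  for (a in c(0.10, 0.05, 0.01)) {
    expect_lt(abs(mean(res$p_value < a) - a),
              3 * sqrt(a * (1 - a) / nrow(res)) + 0.005)
  }
})
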