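test_that("error_spec encodes the four canonical scenarios", {
  s1 <- error_spec(1, 0.05)
  expect_equal(s1$r1, 0.05); expect_equal(s1$r2, 0)
  expect_setequal(s1$targets, c("father", "mother"))
  s4 <- error_spec(4, 0.01)
  expect_equal(s4$r1, 0); expect_equal(s4$r2, 0.01)
  expect_equal(s4$targets, "child")
  expect_error(error_spec(5, 0.1))
  expect_error(error_spec(2, 1.5))
})

test_that("boundary rates: r1 = 1 flips every child het, zero rates are the identity", {
  panel <- sample_panel(5, variants_per_gene = 10,
                        maf_spectrum = maf_spectrum_fixed(0.2), maf_cap = 0.5,
                        seed = 1)
  coh <- simulate_trios(panel, 50, seed = 2)

  all_flip <- inject_errors(coh, error_spec(2, 1), seed = 3)
  expect_true(all(all_flip$observed$child[coh$true$child == 1L] == 0L))
  expect_identical(all_flip$observed$father, coh$true$father)
  expect_identical(all_flip$observed$mother, coh$true$mother)
  expect_identical(all_flip$true, coh$true)

  none <- inject_errors(coh, error_spec(2, 0), seed = 4)
  expect_identical(none$observed, coh$true)
  expect_true(none$perturbed)
})

test_that("flip fractions match the specified binomial rate and hom-alt calls are untouched", {
  panel <- sample_panel(10, variants_per_gene = 50,
                        maf_spectrum = maf_spectrum_fixed(0.3), maf_cap = 0.5,
                        seed = 5)
  coh <- simulate_trios(panel, 200, seed = 6)

  # scenario 3: hom-ref parents called het at r2
  r2 <- 0.01
  inj <- inject_errors(coh, error_spec(3, r2), seed = 7)
  homref <- sum(coh$true$father == 0L) + sum(coh$true$mother == 0L)
  flipped <- sum(inj$observed$father[coh$true$father == 0L] == 1L) +
    sum(inj$observed$mother[coh$true$mother == 0L] == 1L)
  expect_lt(abs(flipped - r2 * homref), 3 * sqrt(r2 * (1 - r2) * homref))
  # non-targeted member bit-identical; hom-alt never altered
  expect_identical(inj$observed$child, coh$true$child)
  expect_true(all(inj$observed$father[coh$true$father == 2L] == 2L))

  # scenario 2: child hets lost at r1
  r1 <- 0.05
  inj2 <- inject_errors(coh, error_spec(2, r1), seed = 8)
  hets <- sum(coh$true$child == 1L)
  flips <- sum(inj2$observed$child[coh$true$child == 1L] == 0L)
  expect_lt(abs(flips - r1 * hets), 3 * sqrt(r1 * (1 - r1) * hets))
  expect_true(all(inj2$observed$child[coh$true$child == 2L] == 2L))

  log <- flip_log(inj2)
  expect_equal(nrow(log), flips)
  expect_true(all(log$member == "child"))
  expect_true(all(log$true_dosage == 1L & log$observed_dosage == 0L))
})

test_that("a second injection onto a perturbed cohort is rejected and seeds reproduce flips", {
  panel <- sample_panel(4, variants_per_gene = 5, seed = 9)
  coh <- simulate_trios(panel, 30, seed = 10)
  inj <- inject_errors(coh, error_spec(1, 0.1), seed = 11)
  expect_error(inject_errors(inj, error_spec(2, 0.1), seed = 12),
               "already perturbed")
  again <- inject_errors(coh, error_spec(1, 0.1), seed = 11)
  expect_identical(inj$observed, again$observed)
})
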