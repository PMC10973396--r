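test_that("scalar heterosis formulas reproduce published spot values", {
  # flowering-time cross with strong negative vigor
  expect_equal(round(mid_parent_heterosis(45, 48.5, 55), 2), -13.04)
  # top seed-yield cross
  expect_equal(round(mid_parent_heterosis(99.45, 56.85, 27.9), 2), 134.69)
  expect_equal(round(better_parent_heterosis(99.45, 56.85, 27.9), 2), 74.93)
  expect_equal(round(better_parent_heterosis(45, 46.5, 56.5), 2), -20.35)
  # exact nulls
  expect_equal(mid_parent_heterosis(51.75, 48.5, 55), 0)
  expect_equal(better_parent_heterosis(55, 48.5, 55), 0)
  expect_error(mid_parent_heterosis(1, 2, -2), "undefined")
  expect_error(better_parent_heterosis(1, 0, 0), "undefined")
  # symmetric in the two parents
  expect_equal(mid_parent_heterosis(80, 60, 40), mid_parent_heterosis(80, 40, 60))
  expect_equal(better_parent_heterosis(80, 60, 40),
               better_parent_heterosis(80, 40, 60))
})

test_that("heterosis_table matches the scalar formulas cross by cross", {
  fx <- sunflower_fixture()
  ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
  expect_equal(nrow(ht), 36 * 9)
  expect_s3_class(ht, "heterosis_tbl")
  withr::with_seed(41, {
    for (i in sample(nrow(ht), 25)) {
      row <- ht[i, ]
      expect_equal(row$mph,
                   mid_parent_heterosis(row$f1, row$p_line, row$p_tester))
      expect_equal(row$bph,
                   better_parent_heterosis(row$f1, row$p_line, row$p_tester))
    }
  })
  # hybrids set to mid-parent values: all MPH exactly zero
  mp_hyb <- ht |>
    dplyr::select(line, tester, trait, mp) |>
    tidyr::pivot_wider(names_from = trait, values_from = mp)
  ht0 <- heterosis_table(fx$parents, mp_hyb)
  expect_equal(ht0$mph, rep(0, nrow(ht0)))

  expect_error(
    heterosis_table(fx$parents,
                    tibble::tibble(line = "NOPE", tester = "RHP-68", SYP = 1)),
    "unknown parents")
})

test_that("BPH never exceeds MPH for positive parent means", {
  fx <- sunflower_fixture()
  ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
  expect_true(all(ht$bph <= ht$mph + 1e-12))
})

test_that("significance annotation follows the t formulas and its limits", {
  fx <- sunflower_fixture()
  ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
  expect_warning(out <- heterosis_significance(ht, NULL, 3, 70), "skipped")
  expect_identical(out, ht)

  ann <- heterosis_significance(ht, mse = 4, r = 3, error_df = 70)
  expect_equal(ann$t_mph, (ann$f1 - ann$mp) / sqrt(3 * 4 / 6))
  expect_equal(ann$t_bph, (ann$f1 - ann$bp) / sqrt(2 * 4 / 3))
  # a null cross is ns; a huge deviation at tiny mse is **
  z <- heterosis_significance(
    heterosis_table(tibble::tibble(parent = c("P1", "P2"), SYP = c(10, 20)),
                    tibble::tibble(line = "P1", tester = "P2", SYP = 15)),
    mse = 1, r = 3, error_df = 10)
  expect_equal(z$sig_mph, "ns")
  z2 <- heterosis_significance(
    heterosis_table(tibble::tibble(parent = c("P1", "P2"), SYP = c(10, 20)),
                    tibble::tibble(line = "P1", tester = "P2", SYP = 25)),
    mse = 1e-6, r = 3, error_df = 10)
  expect_equal(z2$sig_mph, "**")
  expect_equal(z2$sig_bph, "**")
})

test_that("the mid-parent t-test is calibrated under the null", {
  # no heterosis, known sigma^2, r = 3; empirical type-I error near 0.05
  rate <- null_mph_rejection_rate(n_rep = 10000, sigma = 4, r = 3, seed = 42)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("wide report layout rounds to two decimals", {
  fx <- sunflower_fixture()
  ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
  w <- heterosis_wide(ht)
  expect_equal(nrow(w), 36)
  expect_equal(ncol(w), 1 + 18)
  expect_equal(
    w$SYP_mph[w$cross == "RHP-41 × CMS-HAP-111"], 134.69)
})
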