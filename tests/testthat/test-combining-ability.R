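make_trial <- function(truth, r = 2, seed = 51) {
  generate_lxt_trial(truth, r = r, trait = "SYP", seed = seed)
}

test_that("cross means average replications and match direct averaging", {
  truth <- random_trial_truth(l = 3, t = 2, sigma = 2, seed = 50)
  tr <- make_trial(truth, r = 2)
  cm <- cross_means(tr, "SYP")
  df <- tibble::as_tibble(tr)
  for (i in rownames(cm$matrix)) {
    for (j in colnames(cm$matrix)) {
      expect_equal(cm$matrix[i, j],
                   mean(df$value[df$line == i & df$tester == j]))
    }
  }
  expect_equal(cm$line_means, rowMeans(cm$matrix))
  expect_equal(cm$tester_means, colMeans(cm$matrix))
  expect_equal(cm$grand_mean, mean(df$value))
  expect_equal(cm$r, 2L)

  # r = 1: cell means equal the raw observations
  tr1 <- make_trial(random_trial_truth(l = 2, t = 2, sigma = 1, seed = 52),
                    r = 1)
  cm1 <- cross_means(tr1, "SYP")
  df1 <- dplyr::arrange(tibble::as_tibble(tr1), line, tester)
  expect_equal(as.vector(t(cm1$matrix)), df1$value)
})

test_that("GCA/SCA match hand computations and algebraic identities", {
  cm <- cross_means(tibble::tibble(line = rep(c("L1", "L2"), each = 2),
                                   tester = rep(c("T1", "T2"), 2),
                                   value = c(10, 12, 14, 16)))
  g <- gca_effects(cm)
  expect_equal(g$gca[g$role == "line"], c(-2, 2))
  expect_equal(g$gca[g$role == "tester"], c(-1, 1))
  expect_equal(sca_effects(cm)$sca, rep(0, 4))  # purely additive table

  cm2 <- cross_means(tibble::tibble(line = rep(c("L1", "L2"), each = 2),
                                    tester = rep(c("T1", "T2"), 2),
                                    value = c(10, 12, 14, 12)))
  s2 <- sca_effects(cm2)
  expect_equal(s2$sca, c(-1, 1, 1, -1))

  withr::with_seed(53, {
    for (i in 1:10) {
      l <- sample(2:6, 1); t <- sample(2:6, 1)
      tb <- tidyr::expand_grid(line = sprintf("L%d", 1:l),
                               tester = sprintf("T%d", 1:t))
      tb$value <- rnorm(nrow(tb), 50, 10)
      cmr <- cross_means(tb)
      gr <- gca_effects(cmr)
      sr <- sca_effects(cmr)
      expect_equal(sum(gr$gca[gr$role == "line"]), 0, tolerance = 1e-9)
      expect_equal(sum(gr$gca[gr$role == "tester"]), 0, tolerance = 1e-9)
      sm <- tidyr::pivot_wider(sr, names_from = tester, values_from = sca)
      smat <- as.matrix(sm[-1])
      expect_equal(unname(rowSums(smat)), rep(0, l), tolerance = 1e-9)
      expect_equal(unname(colSums(smat)), rep(0, t), tolerance = 1e-9)
      # reconstruction: cell mean = grand + g_line + g_tester + sca, exactly
      gl <- setNames(gr$gca[gr$role == "line"],
                     gr$parent[gr$role == "line"])
      gt <- setNames(gr$gca[gr$role == "tester"],
                     gr$parent[gr$role == "tester"])
      rebuilt <- cmr$grand_mean + outer(gl[rownames(cmr$matrix)],
                                        gt[colnames(cmr$matrix)], "+") +
        smat[match(rownames(cmr$matrix), sm$line),
             match(colnames(cmr$matrix), colnames(sm)[-1]) , drop = FALSE]
      expect_equal(unname(rebuilt), unname(cmr$matrix), tolerance = 1e-9)
    }
  })
})

test_that("the ANOVA partition matches the definition-level oracle and aov", {
  withr::with_seed(54, {
    for (i in 1:5) {
      truth <- random_trial_truth(l = 3, t = 3, sigma = 4, seed = 100 + i)
      tr <- make_trial(truth, r = 2, seed = 200 + i)
      an <- lxt_anova(tr, "SYP")
      df <- tibble::as_tibble(tr)
      oracle <- oracle_lxt_ss(df)
      expect_equal(an$sumsq[an$term == "replications"], oracle$rep,
                   tolerance = 1e-9)
      expect_equal(an$sumsq[an$term == "crosses"], oracle$crosses,
                   tolerance = 1e-9)
      expect_equal(an$sumsq[an$term == "lines"], oracle$lines,
                   tolerance = 1e-9)
      expect_equal(an$sumsq[an$term == "testers"], oracle$testers,
                   tolerance = 1e-9)
      expect_equal(an$sumsq[an$term == "line_x_tester"], oracle$lxt,
                   tolerance = 1e-9)
      expect_equal(an$sumsq[an$term == "error"], oracle$error,
                   tolerance = 1e-9)
      expect_equal(an$df, c(1, 8, 2, 2, 4, 8))
      # independent reference fit
      ref <- stats::anova(stats::aov(
        value ~ factor(rep) + line * tester, data = df))
      expect_equal(an$sumsq[an$term == "lines"], ref["line", "Sum Sq"])
      expect_equal(an$sumsq[an$term == "line_x_tester"],
                   ref["line:tester", "Sum Sq"])
      expect_equal(an$sumsq[an$term == "error"], ref["Residuals", "Sum Sq"])
    }
  })
  # degenerate cases
  truth0 <- trial_truth(mu = 5, g_line = c(0, 0), g_tester = c(0, 0),
                        s = matrix(0, 2, 2), rep_sd = 0, sigma = 0)
  tr0 <- make_trial(truth0, r = 2, seed = 1)
  an0 <- lxt_anova(tr0, "SYP")
  expect_equal(an0$sumsq, rep(0, 6))
  tr1 <- make_trial(truth0, r = 1, seed = 1)
  expect_error(lxt_anova(tr1), "r >= 2")
})

test_that("standard errors follow the line x tester formulas", {
  se <- effect_standard_errors(36, l = 6, t = 6, r = 6)
  expect_equal(se$se[se$effect == "gca_line"], 1)
  expect_equal(se$se[se$effect == "sca"], sqrt(6))
  expect_equal(se$se_diff, sqrt(2) * se$se)
  expect_equal(effect_standard_errors(0, 2, 2, 2)$se, rep(0, 3))
})

test_that("noiseless trials recover the generating effects exactly", {
  truth <- random_trial_truth(l = 4, t = 3, gca_sd = 5, sca_sd = 2,
                              rep_sd = 0, sigma = 0, seed = 55)
  tr <- make_trial(truth, r = 2, seed = 56)
  fit <- combining_ability(tr, "SYP")
  g <- fit$gca
  expect_equal(setNames(g$gca[g$role == "line"], g$parent[g$role == "line"]),
               truth$g_line)
  expect_equal(setNames(g$gca[g$role == "tester"],
                        g$parent[g$role == "tester"]),
               truth$g_tester)
  smat <- tidyr::pivot_wider(fit$sca, names_from = tester,
                             values_from = sca, id_cols = line)
  expect_equal(unname(as.matrix(smat[-1])), unname(truth$s))
  expect_equal(fit$cross_means$grand_mean, truth$mu)
})

test_that("effect estimates are unbiased and stars track planted effects", {
  truth <- random_trial_truth(l = 6, t = 6, gca_sd = 5, sca_sd = 3,
                              rep_sd = 2, sigma = 5, seed = 57)
  n_sim <- 120
  ests <- sapply(seq_len(n_sim), function(s) {
    tr <- make_trial(truth, r = 3, seed = 1000 + s)
    g <- combining_ability(tr, "SYP")$gca
    g$gca[g$role == "line"]
  })
  bias <- rowMeans(ests) - unname(truth$g_line)
  mc_se <- apply(ests, 1, sd) / sqrt(n_sim)
  expect_true(all(abs(bias) < 3 * mc_se + 1e-12))

  # large planted effects come out significant; null effects mostly do not
  big <- trial_truth(mu = 60, g_line = c(-20, 0, 20), g_tester = c(-15, 15),
                     s = matrix(0, 3, 2), rep_sd = 1, sigma = 2)
  fitb <- combining_ability(make_trial(big, r = 4, seed = 58), "SYP")
  gb <- fitb$gca
  expect_equal(gb$significance[gb$role == "line"][c(1, 3)], c("**", "**"))
})

test_that("means-only input yields effects with significance unavailable", {
  fx <- sunflower_fixture()
  ht <- heterosis_table(fx$parents, fx$hybrids, fx$design)
  sub <- ht[ht$trait == "SYP", c("line", "tester", "f1")]
  fit <- combining_ability(setNames(sub, c("line", "tester", "value")))
  expect_null(fit$anova)
  expect_true(all(fit$gca$significance == "unavailable"))
  expect_true(all(is.na(fit$gca$se)))
  expect_equal(sum(fit$gca$gca), 0, tolerance = 1e-9)
  expect_s3_class(glance(fit), "tbl_df")
  expect_true(is.na(glance(fit)$mse))
})
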