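test_that("Benjamini-Hochberg reproduces the hand-computed step-up and edge cases", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2, 0.5, 0.9)
  bh <- benjamini_hochberg(p, alpha = 0.05)
  expect_equal(bh$n_rejected, 3L)
  expect_equal(bh$table$reject, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(bh$critical_level, 3 * 0.05 / 7, tolerance = 1e-12)

  expect_equal(benjamini_hochberg(rep(1, 5))$n_rejected, 0L)
  expect_equal(benjamini_hochberg(rep(1, 5))$critical_level, 0)
  one <- benjamini_hochberg(0.03)
  expect_equal(one$n_rejected, 1L)
  expect_equal(one$critical_level, 0.05)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "domain")
})

test_that("BH decisions agree with p.adjust and are monotone in alpha", {
  set.seed(42)
  for (i in 1:30) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    for (alpha in c(0.01, 0.05, 0.1)) {
      bh <- benjamini_hochberg(p, alpha)
      # oracle: BH-adjusted p-values from stats::p.adjust
      expect_identical(bh$table$reject, p.adjust(p, "BH") <= alpha)
      expect_lte(bh$critical_level, alpha)
      # step-up shape: everything below a rejected p is rejected
      if (bh$n_rejected > 0) {
        expect_true(all(bh$table$reject[p <= max(p[bh$table$reject])]))
      }
    }
    # monotone in alpha
    n_rej <- sapply(c(0.01, 0.02, 0.05, 0.1, 0.2),
                    function(a) benjamini_hochberg(p, a)$n_rejected)
    expect_true(all(diff(n_rej) >= 0))
  }
})

test_that("the lobe x PEEP model recovers its design: type-III tests and LS-means", {
  co <- generate_cohort(cohort_config(), seed = 8, trees = FALSE)
  fit <- fit_lobe_peep_model(strain_table(co), "strain")
  expect_s3_class(fit, "fri_lmm")
  t3 <- type3_tests(fit)
  expect_setequal(t3$term, c("lobe", "peep", "lobe:peep"))
  expect_true(all(t3$p_value >= 0 & t3$p_value <= 1))
  # the generator's PEEP effect on strain is strong
  expect_lt(t3$p_value[t3$term == "peep"], 0.001)

  tk <- tukey_kramer(fit, "peep")
  expect_equal(nrow(tk$comparisons), 3)
  # adjusted >= raw where both are numerically resolvable (ptukey loses
  # absolute accuracy in the far tail)
  cmp <- tk$comparisons
  meaningful <- cmp$p_value > 1e-8
  expect_true(all(cmp$p_adjusted[meaningful] >= cmp$p_value[meaningful] - 1e-12))
  # LS-means decrease with PEEP
  ls <- tk$lsmeans[match(c("0", "5", "10"), tk$lsmeans$level), ]
  expect_true(all(diff(ls$lsmean) < 0))

  # under a null generator the p-values are moderate and the adjusted
  # value dominates the raw one for every pair of both factors
  null_cfg <- cohort_config(effects = list(peep_volume_effect = FALSE,
                                           elastance_step_at_peep10 = FALSE,
                                           airway_dilation_with_peep = FALSE))
  co0 <- generate_cohort(null_cfg, seed = 77, trees = FALSE)
  fit0 <- fit_lobe_peep_model(strain_table(co0), "strain")
  cmp0 <- tukey_kramer(fit0, "peep")$comparisons
  expect_true(all(cmp0$p_adjusted >= cmp0$p_value - 1e-12))
  expect_true(all(cmp0$p_adjusted > 0.05))  # no spurious PEEP differences

  # broom-style accessors
  expect_true(all(c("term", "estimate", "p_value") %in% names(tidy(fit))))
  g <- glance(fit)
  expect_equal(g$nobs, 105)
  expect_true(g$var_pig >= 0 && g$var_residual > 0)

  expect_error(tukey_kramer(fit, "nonfactor"))
  tot <- fit_lobe_peep_model(
    dplyr::mutate(strain_table(co), scope = "total"), "strain", scope = "total")
  expect_error(tukey_kramer(tot, "lobe"), "not in the model")
})

test_that("with one PEEP level the lobe F-test equals classical one-way mixed ANOVA", {
  co <- generate_cohort(cohort_config(), seed = 13, trees = FALSE)
  # elastance carries a real pig component, keeping the fit off the
  # variance boundary where the classical equivalence holds
  tab <- dplyr::filter(elastance_table(co), peep_cmH2O == 5)
  fit <- fit_lobe_peep_model(tab, "elastance")
  expect_false(fit$singular)
  f_lmm <- fit$type3$f_statistic[fit$type3$term == "lobe"]
  df2 <- fit$type3$df2[fit$type3$term == "lobe"]
  # oracle: randomized-complete-block ANOVA (pig as block)
  a <- summary(stats::aov(elastance_cmH2O_L ~ lobe + Error(factor(pig_id)),
                          data = dplyr::mutate(tab, lobe = factor(scope))))
  f_aov <- a[["Error: Within"]][[1]]["lobe", "F value"]
  expect_equal(f_lmm, f_aov, tolerance = 1e-6)
  expect_equal(df2, a[["Error: Within"]][[1]]["Residuals", "Df"],
               tolerance = 1e-6)
})

test_that("Tukey-Kramer with two levels collapses to the unadjusted t-test", {
  co <- generate_cohort(cohort_config(peep_levels = c(0, 10)), seed = 30,
                        trees = FALSE)
  fit <- fit_lobe_peep_model(strain_table(co), "strain")
  tk <- tukey_kramer(fit, "peep")
  expect_equal(tk$comparisons$p_adjusted, tk$comparisons$p_value,
               tolerance = 1e-6)
})

test_that("tau ~ strain models hit their limiting pseudo-R2 values", {
  # exact linear relation, no noise: R2 -> 1
  d <- make_lmm_data(6, 10, slope = 2, sd_pig = 0, sd_res = 0, seed = 1)
  f <- suppressWarnings(fit_tau_strain_model(d, "X"))  # exact fit: boundary
  expect_gte(f$marginal_r2, 0.999)

  # zero slope in truth: R2 near 0 (median over replicates)
  r2_null <- sapply(1:20, function(s) {
    d <- make_lmm_data(6, 10, slope = 0, sd_pig = 0.5, sd_res = 1, seed = 100 + s)
    suppressWarnings(fit_tau_strain_model(d, "X")$marginal_r2)
  })
  expect_lt(median(r2_null), 0.05)

  # degenerate strain: flagged, not an error
  d0 <- make_lmm_data(4, 5, 1, 0.1, 0.1, seed = 3)
  d0$strain <- 0.2
  f0 <- fit_tau_strain_model(d0, "X")
  expect_true(f0$flagged)
  expect_true(is.na(f0$marginal_r2))
})

test_that("marginal pseudo-R2 matches its variance decomposition and OLS limit", {
  # sigma2_f = 4, sigma2_pig = 1, sigma2_res = 1 -> R2 = 4/6
  d <- make_lmm_data(25, 20, slope = 2, sd_pig = 1, sd_res = 1, seed = 7)
  f <- fit_tau_strain_model(d, "X")
  expect_lt(abs(f$marginal_r2 - 4 / 6), 0.05)

  # no pig variance: agrees with ordinary R squared
  d2 <- make_lmm_data(10, 20, slope = 1, sd_pig = 0, sd_res = 0.8, seed = 9)
  f2 <- fit_tau_strain_model(d2, "X")
  ols <- summary(lm(tau_s ~ strain, data = d2))$r.squared
  expect_equal(f2$marginal_r2, ols, tolerance = 0.02)

  # invariant to affine rescaling of the response
  d3 <- dplyr::mutate(d2, tau_s = 3.7 * tau_s - 11)
  f3 <- fit_tau_strain_model(d3, "X")
  expect_equal(f3$marginal_r2, f2$marginal_r2, tolerance = 1e-6)
})

test_that("singular and degenerate designs are flagged, never raised", {
  # zero pig SD: the pig variance component should be (near) zero and the
  # fit flagged as singular rather than erroring
  d <- make_lmm_data(5, 21, slope = 1, sd_pig = 0, sd_res = 1, seed = 17)
  f <- fit_tau_strain_model(d, "X")
  expect_s3_class(f, "fri_lmm")
  expect_lt(f$varcomp[["pig"]], 0.1 * f$varcomp[["residual"]])
  # with < 2 pigs both model kinds degrade to flagged fits with a warning
  d1 <- d[d$pig_id == "pig1", ]
  expect_warning(f1 <- fit_lobe_peep_model(d1, "tau"), "2 pigs")
  expect_true(f1$flagged)
  expect_equal(f1$varcomp[["pig"]], 0)
  expect_true(fit_tau_strain_model(d1, "X")$flagged)
})

test_that("run_statistics assembles the full report with 8 tau-strain entries", {
  co <- generate_cohort(cohort_config(n_pigs = 3), seed = 5)
  mech <- compute_fri_table(co)
  rep <- run_statistics(mech)
  expect_s3_class(rep, "fri_stats_report")
  expect_named(rep$lobar_models, c("strain", "resistance", "elastance", "tau"))
  expect_equal(nrow(rep$tau_strain), 8)
  expect_equal(sum(rep$tau_strain$scope == "total"), 1)
  expect_true(all(rep$tau_strain$marginal_r2 >= 0 &
                    rep$tau_strain$marginal_r2 <= 1, na.rm = TRUE))
  expect_identical(rep$tau_strain$reject, rep$bh$table$reject)

  txt <- render_report(rep)
  expect_true(any(grepl("LS-means by peep", txt)))
  expect_equal(sum(grepl("R2\\(marginal\\)", txt)), 8)
})
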