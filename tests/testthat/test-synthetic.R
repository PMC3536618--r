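test_that("generators are pure functions of config and seed", {
  cfg <- panel_config(seed = 5)
  a <- generate_cell_line_panel(cfg)
  b <- generate_cell_line_panel(cfg)
  expect_identical(a, b)

  p1 <- generate_dose_response_plate("CL1", 4.2, seed = 3)
  p2 <- generate_dose_response_plate("CL1", 4.2, seed = 3)
  expect_identical(p1, p2)

  coh1 <- generate_patient_cohort(cohort_config(seed = 4), a$truth)
  coh2 <- generate_patient_cohort(cohort_config(seed = 4), a$truth)
  expect_identical(coh1, coh2)
  # generators do not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(generate_cell_line_panel(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("dose-response plates recover their target AUC", {
  # boundaries
  p10 <- generate_dose_response_plate("CL1", 10, seed = 1)
  expect_lt(abs(compute_auc(compute_survival_fractions(p10)) - 10), 0.3)
  p0 <- generate_dose_response_plate("CL0", 0, seed = 1)
  expect_true(all(p0$treated$count == 0))
  expect_equal(compute_auc(compute_survival_fractions(p0)), 0)
  expect_error(generate_dose_response_plate("CLx", 12, seed = 1), "\\[0, 10\\]")

  # Monte-Carlo check of the stated tolerance: 200 seeded plates
  set.seed(123)
  targets <- runif(200, 1, 9)
  err <- vapply(seq_along(targets), function(i) {
    p <- generate_dose_response_plate("CL", targets[i], seed = 1000 + i)
    abs(compute_auc(compute_survival_fractions(p)) - targets[i])
  }, numeric(1))
  expect_lt(mean(err), 0.15)
  expect_gte(mean(err < 0.3), 0.95)
})

test_that("a null-effect panel gives screening scores matching the global null", {
  # with effect_beta = 0 the AUC is independent of every probe, so the
  # screening p-values are uniform; KS should not reject at alpha = 0.01
  rejections <- 0L
  for (sd in 1:20) {
    sim <- generate_cell_line_panel(panel_config(effect_beta = 0, seed = sd))
    x <- standardize_samples(filter_probes(sim$expression)$matrix)
    scr <- screen_features(x, sim$auc)
    ks <- suppressWarnings(ks.test(scr$p_value, "punif"))
    if (ks$p.value < 0.01) rejections <- rejections + 1L
  }
  expect_lte(rejections, 2)   # ~0.2 expected under the null across 20 seeds
})

test_that("planted-probe correlation matches the closed-form attenuation", {
  cfg <- panel_config(n_cell_lines = 400, seed = 17)
  sim <- generate_cell_line_panel(cfg)
  obs <- mean(abs(cor(t(sim$expression[sim$planted, ]), sim$auc)))
  # cor(x_j, auc) = beta*auc_sd / sqrt((beta^2+sigma^2)(auc_sd^2+tau^2))
  expected <- cfg$effect_beta * cfg$auc_sd /
    sqrt((cfg$effect_beta^2 + cfg$noise_sd^2) *
           (cfg$auc_sd^2 + cfg$auc_noise_sd^2))
  expect_lt(abs(obs - expected), 0.05)
})

test_that("cohort outcomes follow the latent logistic model", {
  sim <- generate_cell_line_panel(panel_config(seed = 21))

  # empirical pCR fraction within 3 binomial SEs of the analytic mean
  cfg <- cohort_config(n_patients = 1000, seed = 22)
  coh <- generate_patient_cohort(cfg, sim$truth)
  u <- coh$latent
  p_model <- plogis(cfg$pcr_intercept + cfg$pcr_slope * u)
  frac <- mean(coh$cohort$response == "pCR")
  se <- sqrt(mean(p_model) * (1 - mean(p_model)) / 1000)
  expect_lt(abs(frac - mean(p_model)), 3 * se + 1e-9)

  # regression of outcome on the returned latent recovers the slope
  cfg2 <- cohort_config(n_patients = 2000, seed = 23)
  coh2 <- generate_patient_cohort(cfg2, sim$truth)
  g <- glm((coh2$cohort$response == "pCR") ~ coh2$latent, family = binomial())
  est <- coef(summary(g))[2, ]
  expect_lt(abs(est["Estimate"] - cfg2$pcr_slope), 2 * est["Std. Error"] + 0.05)

  # platform restriction really drops probes
  expect_equal(nrow(coh$expression),
               round(0.9 * nrow(sim$expression)))
})

test_that("a zero-slope cohort carries no score signal", {
  sim <- generate_cell_line_panel(panel_config(seed = 31))
  fit <- mgp_fit(sim$expression, sim$auc, threshold = 4, seed = 31)
  covered <- 0L
  for (sd in 1:10) {
    coh <- generate_patient_cohort(
      cohort_config(pcr_slope = 0, pcr_intercept = -0.4, seed = 100 + sd),
      sim$truth)
    sc <- suppressWarnings(predict(fit, coh$expression))
    r <- delong_ci(sc[coh$cohort$sample_id], coh$cohort$response == "pCR")
    if (r$ci_low <= 0.5 && 0.5 <= r$ci_high) covered <- covered + 1L
  }
  expect_gte(covered, 8)   # nominal 95% coverage of AUC = 0.5
})

test_that("clinical tables round-trip through CSV with unknown literals", {
  sim <- generate_cell_line_panel(panel_config(seed = 41))
  coh <- generate_patient_cohort(cohort_config(n_patients = 30, seed = 42),
                                 sim$truth)
  path <- withr::local_tempfile(fileext = ".csv")
  write_clinical_table(coh$cohort, path)
  back <- load_clinical_table(path)
  expect_identical(back$sample_id, coh$cohort$sample_id)
  expect_identical(back$response, coh$cohort$response)
  expect_identical(back$nodal, coh$cohort$nodal)

  bad <- coh$cohort; bad$response[1] <- "unknown"
  write_clinical_table(bad, path)
  expect_error(load_clinical_table(path), "pCR or RD")
})
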