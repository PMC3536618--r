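make_panel <- function(seed = 1) {
  sim <- generate_cell_line_panel(panel_config(seed = seed))
  x <- standardize_samples(filter_probes(sim$expression)$matrix)
  list(sim = sim, x = x, y = sim$auc)
}

test_that("first-component loadings match a full decomposition oracle", {
  p <- make_panel(seed = 101)
  fit <- fit_supervised_pc(p$x, p$y, threshold = 0)   # keep every probe
  # oracle: prcomp on samples x probes
  pr <- prcomp(t(p$x), center = TRUE, scale. = FALSE)
  v <- pr$rotation[, 1]
  s <- sign(sum(v * fit$loadings))
  expect_equal(unname(fit$loadings), unname(s * v), tolerance = 1e-8)
  expect_gte(fit$slope, 0)
  expect_equal(sqrt(sum(fit$loadings^2)), 1, tolerance = 1e-9)

  # a tighter threshold on a seeded 100 x 30 panel, again vs prcomp
  x2 <- random_matrix(100, 30, seed = 33, mean = 0, sd = 1)
  set.seed(34)
  y2 <- setNames(rnorm(30), colnames(x2))
  x2[1:10, ] <- x2[1:10, ] + 2 * matrix(y2, 10, 30, byrow = TRUE)
  scr <- screen_features(x2, y2)
  thr <- sort(abs(scr$score), decreasing = TRUE)[10]
  fit2 <- fit_supervised_pc(x2, y2, thr)
  sel <- fit2$selected_probe_ids
  pr2 <- prcomp(t(x2[sel, ]), center = TRUE, scale. = FALSE)
  v2 <- pr2$rotation[, 1]
  s2 <- sign(sum(v2 * fit2$loadings))
  expect_equal(unname(fit2$loadings), unname(s2 * v2), tolerance = 1e-8)
})

test_that("a single selected probe reduces to the univariate regression", {
  x <- random_matrix(50, 25, seed = 41)
  set.seed(42)
  y <- setNames(rnorm(25, 5), colnames(x))
  x["P0007", ] <- 3 * y + rnorm(25, 0, 0.1)
  scr <- screen_features(x, y)
  thr <- max(abs(scr$score)) - 1e-9
  fit <- fit_supervised_pc(x, y, thr)
  expect_identical(fit$selected_probe_ids, "P0007")
  # loadings are +-1; the component is the centered probe up to positive scale
  expect_equal(abs(unname(fit$loadings)), 1)
  uni <- lm(y ~ x["P0007", ])
  expect_equal(unname(fit$fitted), unname(fitted(uni)), tolerance = 1e-9)
  expect_error(fit_supervised_pc(x, y, 1e6), "max observed")
})

test_that("cross-validated threshold selection is deterministic and sane", {
  p <- make_panel(seed = 55)
  one <- cv_select_threshold(p$x, p$y, candidate_thresholds = 3.3, seed = 9)
  expect_equal(one$threshold, 3.3)

  a <- cv_select_threshold(p$x, p$y, k = 5, seed = 7)
  b <- cv_select_threshold(p$x, p$y, k = 5, seed = 7)
  expect_identical(a, b)
  expect_true(all(diff(a$curve$threshold) > 0))
  expect_true(all(a$curve$mean_stat >= 0 & a$curve$mean_stat <= 1))
})

test_that("the CV-chosen model recovers the planted probes on a default panel", {
  sim <- generate_cell_line_panel(panel_config(seed = 77))
  fit <- mgp_fit(sim$expression, sim$auc, seed = 77)
  recall <- mean(sim$planted %in% fit$selected_probe_ids)
  false_frac <- mean(!fit$selected_probe_ids %in% sim$planted)
  expect_gte(recall, 0.9)
  expect_lte(false_frac, 0.1)

  # end-to-end determinism
  fit2 <- mgp_fit(sim$expression, sim$auc, seed = 77)
  expect_equal(fit$loadings, fit2$loadings)
  expect_equal(fit$threshold, fit2$threshold)
})

test_that("prediction reproduces fitted values and is invariant to column order", {
  sim <- generate_cell_line_panel(panel_config(seed = 88))
  fit <- mgp_fit(sim$expression, sim$auc, threshold = 4, seed = 88)
  sc <- predict(fit, sim$expression)
  expect_equal(sc, fitted(fit), tolerance = 1e-9)
  expect_equal(unname(residuals(fit)), unname(fit$y - fitted(fit)))

  set.seed(1)
  perm <- sample(ncol(sim$expression))
  sc2 <- predict(fit, sim$expression[, perm])
  expect_equal(sc2[names(sc)], sc, tolerance = 1e-12)
})

test_that("missing model probes are tolerated to 50% with renormalized loadings", {
  sim <- generate_cell_line_panel(panel_config(seed = 99))
  fit <- mgp_fit(sim$expression, sim$auc, threshold = 4, seed = 99)
  sel <- fit$selected_probe_ids
  drop_few <- sel[seq_len(ceiling(0.2 * length(sel)))]
  xnew <- sim$expression[setdiff(rownames(sim$expression), drop_few), ]
  expect_warning(sc <- predict(fit, xnew), "restricted and renormalized")
  expect_true(all(is.finite(sc)))

  drop_most <- sel[seq_len(ceiling(0.6 * length(sel)))]
  xbad <- sim$expression[setdiff(rownames(sim$expression), drop_most), ]
  expect_error(predict(fit, xbad), "missing from newdata")
})

test_that("scores on a synthetic cohort track the latent sensitivity", {
  sim <- generate_cell_line_panel(panel_config(seed = 7))
  fit <- mgp_fit(sim$expression, sim$auc, seed = 7)
  coh <- generate_patient_cohort(cohort_config(seed = 11), sim$truth)
  sc <- suppressWarnings(predict(fit, coh$expression))
  expect_gt(cor(sc, coh$latent[names(sc)], method = "spearman"), 0.8)
})

test_that("model JSON round-trips to identical predictions", {
  sim <- generate_cell_line_panel(panel_config(seed = 13))
  fit <- mgp_fit(sim$expression, sim$auc, threshold = 4, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_mgp(fit, path)
  back <- read_mgp(path)
  expect_identical(back$selected_probe_ids, fit$selected_probe_ids)
  expect_identical(back$loadings, fit$loadings)
  expect_identical(back$intercept, fit$intercept)
  coh <- generate_patient_cohort(cohort_config(n_patients = 10, seed = 14),
                                 sim$truth)
  expect_equal(suppressWarnings(predict(back, coh$expression)),
               suppressWarnings(predict(fit, coh$expression)),
               tolerance = 1e-12)
})
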