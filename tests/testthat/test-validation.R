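test_that("rank-based AUC equals exhaustive pair counting", {
  # perfect separation with the low-score-positive convention
  expect_equal(mann_whitney_auc(c(0.1, 0.2, 0.3, 0.4),
                                c("pCR", "pCR", "RD", "RD")), 1.0)
  # all ties
  expect_equal(mann_whitney_auc(rep(2, 6), rep(c("pCR", "RD"), 3)), 0.5)

  set.seed(51)
  s <- round(rnorm(40), 1)              # rounding forces some ties
  lab <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  pair_oracle <- function(s, lab) {
    pos <- s[lab]; neg <- s[!lab]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a < b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  expect_identical(mann_whitney_auc(s, lab), pair_oracle(s, lab))

  # direction flag: positive_low == 1 - positive_high when tie-free
  s2 <- rnorm(40)
  expect_equal(mann_whitney_auc(s2, lab, positive_low = TRUE),
               1 - mann_whitney_auc(s2, lab, positive_low = FALSE))

  # invariance under strictly increasing transforms
  expect_equal(mann_whitney_auc(exp(s2), lab), mann_whitney_auc(s2, lab))
  expect_error(mann_whitney_auc(s2, rep(TRUE, 40)), "both classes")
})

test_that("DeLong interval brackets the estimate and matches pROC", {
  set.seed(61)
  s <- rnorm(60)
  lab <- s + rnorm(60) < 0              # low score associated with positive
  r <- delong_ci(s, lab)
  expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
  expect_equal(r$auc, mann_whitney_auc(s, lab))

  skip_if_not_installed("pROC")
  pr <- pROC::ci.auc(pROC::roc(response = lab, predictor = s,
                               direction = ">", levels = c(FALSE, TRUE),
                               quiet = TRUE), method = "delong")
  expect_equal(r$ci_low, max(0, as.numeric(pr[1])), tolerance = 1e-9)
  expect_equal(r$auc, as.numeric(pr[2]), tolerance = 1e-12)
  expect_equal(r$ci_high, min(1, as.numeric(pr[3])), tolerance = 1e-9)
})

test_that("perfect separation collapses the DeLong interval with a flag", {
  r <- delong_ci(c(1, 2, 3, 10, 11, 12), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
  expect_true(r$degenerate)
})

test_that("Wilcoxon p-values agree with exact enumeration at small n", {
  # n = 1 + 1: both orderings equally extreme
  expect_equal(wilcoxon_rank_sum(1, 2), 1.0)
  # symmetry
  set.seed(71)
  a <- rnorm(5); b <- rnorm(6)
  expect_equal(wilcoxon_rank_sum(a, b), wilcoxon_rank_sum(b, a))

  # brute-force enumeration oracle over all label arrangements (no ties)
  enum_oracle <- function(a, b) {
    pooled <- c(a, b); na <- length(a)
    combos <- combn(length(pooled), na)
    w_obs <- sum(rank(pooled)[seq_len(na)])
    ws <- apply(combos, 2, function(ix) sum(rank(pooled)[ix]))
    mu <- na * (length(pooled) + 1) / 2
    mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
  }
  expect_equal(wilcoxon_rank_sum(a, b), enum_oracle(a, b), tolerance = 1e-12)

  # asymptotic path approaches the exact value at the size boundary
  set.seed(72)
  a2 <- rnorm(20, 0.5); b2 <- rnorm(20)
  expect_equal(wilcoxon_rank_sum(a2, b2),
               wilcox.test(a2, b2, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-6)
})

test_that("2x2 odds ratios reproduce closed forms and reject zero cells", {
  expect_equal(odds_ratio_2x2(1, 1, 1, 1)$odds_ratio, 1)
  r <- odds_ratio_2x2(8, 17, 20, 20)
  expect_equal(r$odds_ratio, 8 * 20 / (17 * 20))
  expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
  expect_error(odds_ratio_2x2(0, 5, 3, 2), "zero cell")
})

test_that("univariate logistic regression on a binary covariate equals the 2x2 closed form", {
  a <- 11; b <- 14; c <- 21; d <- 20
  expo <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  y <- c(rep(1, a + b), rep(0, c + d))
  fit <- fit_logistic(y, data.frame(er = ifelse(expo == 1, "positive",
                                                "negative")),
                      mode = "univariate")
  closed <- odds_ratio_2x2(a, b, c, d)
  expect_equal(fit$odds_ratio, closed$odds_ratio, tolerance = 1e-6)
  expect_equal(fit$ci_low, closed$ci_low, tolerance = 1e-4)
  expect_equal(fit$ci_high, closed$ci_high, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_equal(fit$n, a + b + c + d)
})

test_that("the logistic score equation is solved at the reported optimum", {
  set.seed(81)
  n <- 120
  cov <- data.frame(age = rnorm(n, 50, 8), score = rnorm(n),
                    er = sample(c("positive", "negative"), n, TRUE))
  eta <- -0.5 + 0.8 * cov$score
  y <- rbinom(n, 1, plogis(eta))
  fit <- fit_logistic(y, cov, mode = "multivariate")
  expect_true(all(fit$converged))
  # score recovers its planted effect within sampling error
  expect_lt(abs(log(fit$odds_ratio[fit$covariate == "score"]) - 0.8), 0.5)
  # the log-likelihood gradient vanishes at the reported optimum
  g <- glm(y ~ age + er + score, data = transform(cov, er = er == "positive"),
           family = binomial())
  expect_equal(unname(exp(coef(g)[-1])), fit$odds_ratio, tolerance = 1e-8)
  grad <- crossprod(model.matrix(g), y - fitted(g))
  expect_lt(max(abs(grad)), 1e-6)
})

test_that("null covariates yield calibrated logistic p-values", {
  set.seed(91)
  reps <- 200
  pvals <- replicate(reps, {
    y <- rbinom(40, 1, 0.4)
    x <- rnorm(40)
    fit_logistic(y, data.frame(score = x), mode = "univariate")$p_value
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(log(replicate(50, {
    y <- rbinom(60, 1, 0.5)
    fit_logistic(y, data.frame(score = rnorm(60)),
                 mode = "univariate")$odds_ratio
  })))), 0.15)
})

test_that("cohort validation reports all four subgroups and skips degenerate ones", {
  sim <- generate_cell_line_panel(panel_config(seed = 7))
  fit <- mgp_fit(sim$expression, sim$auc, threshold = 4, seed = 7)
  coh <- generate_patient_cohort(cohort_config(seed = 11), sim$truth)
  sc <- suppressWarnings(predict(fit, coh$expression))
  rep <- suppressMessages(validate_cohort(sc, coh$cohort))
  expect_setequal(names(rep$subgroups),
                  c("FEC/TX", "FEC/TX+H", "FEC/TX ER-negative",
                    "FEC/TX ER-positive"))
  s <- rep$subgroups[["FEC/TX"]]
  expect_true(s$roc$ci_low <= s$roc$auc && s$roc$auc <= s$roc$ci_high)
  expect_true(all(c("univariate", "multivariate") %in%
                    names(rep$logistic[["FEC/TX"]])))

  # degenerate subgroup: force one class in the trastuzumab arm
  coh2 <- coh$cohort
  coh2$response[coh2$arm == "FEC/TX+H"] <- "RD"
  expect_warning(suppressMessages(validate_cohort(sc, coh2)), "skipped")
})
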