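# Agreement, comparison, collinearity, selection, ROC, calibration, DCA.

test_that("ICC(2,1) behaves at its anchors", {
  set.seed(30)
  x <- rnorm(50)
  expect_equal(icc_agreement(x, x), 1.0)
  expect_error(icc_agreement(1:3, 1:3), "at least 5")
  expect_error(icc_agreement(rep(1, 10), rep(1, 10)), "zero total variance")

  # both readers carry independent noise with variance 9x the subject
  # variance: true ICC = 1 / (1 + 9) = 0.1
  set.seed(31)
  s <- rnorm(20000, sd = 1)
  a <- s + rnorm(20000, sd = 3)
  b <- s + rnorm(20000, sd = 3)
  expect_lt(abs(icc_agreement(a, b) - 0.1), 0.02)

  # asymmetric design checked against the ANOVA expectation
  # a = s, b = s + e: ICC(2,1) -> sigma_s^2 / (sigma_s^2 + sigma_e^2 / 2)
  set.seed(32)
  s <- rnorm(20000); e <- rnorm(20000, sd = 3)
  expect_lt(abs(icc_agreement(s, s + e) - 1 / (1 + 9 / 2)), 0.02)
})

test_that("data-frame ICC returns one value per shared feature", {
  set.seed(33)
  fa <- data.frame(u = rnorm(30), v = rnorm(30))
  fb <- fa + rnorm(30, sd = 0.1)
  icc <- icc_agreement(fa, fb)
  expect_named(icc, c("u", "v"))
  expect_true(all(icc > 0.9))
})

test_that("group comparison gates on normality and handles edge cases", {
  set.seed(34)
  v <- rnorm(100); lab <- rep(c(0, 1), 50)
  g_eq <- compare_feature(rep(1:10, 2), rep(c(0, 1), each = 10))
  expect_equal(g_eq$p_value, 1.0)
  strong <- compare_feature(c(rnorm(50), rnorm(50, 2)),
                            rep(c(0, 1), each = 50))
  expect_identical(strong$test, "t-test")
  expect_lt(strong$p_value, 1e-6)
  skewed <- compare_feature(c(rlnorm(50, sdlog = 1.5), rlnorm(50, 1, 1.5)),
                            rep(c(0, 1), each = 50))
  expect_identical(skewed$test, "rank-sum")
  expect_identical(skewed$summaries$style[1], "median ± IQR")
  expect_error(compare_feature(v, rep(1, 100)), "two non-empty")
  expect_error(compare_feature(rep(2, 20), rep(c(0, 1), 10)), "constant")
})

test_that("categorical comparison picks chi-square or Fisher correctly", {
  tab <- afp_ki67_table()
  cmp <- compare_categorical(tab)
  expect_identical(cmp$test, "chi-square")
  expect_lt(cmp$p_value, 0.01)
  expect_equal(cmp$p_value, stats::chisq.test(tab, correct = FALSE)$p.value)
  expect_equal(compare_categorical(matrix(10, 2, 2))$p_value, 1.0)
  small <- compare_categorical(matrix(c(2, 1, 1, 2), 2))
  expect_identical(small$test, "Fisher")
  expect_error(compare_categorical(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("VIF matches its closed form and flags collinearity", {
  # orthogonal predictors
  x <- data.frame(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5))
  v <- vif_screen(x)
  expect_equal(v$vif, c(1, 1))
  expect_false(any(v$flagged))
  # empirical correlation exactly 0.9 -> VIF = 1/(1 - 0.81)
  set.seed(36)
  u1 <- scale(rnorm(200))[, 1]
  e <- residuals(lm(rnorm(200) ~ u1)); e <- scale(e)[, 1]
  x2 <- data.frame(p = u1, q = 0.9 * u1 + sqrt(1 - 0.81) * e)
  v2 <- vif_screen(x2)
  expect_equal(v2$vif, rep(1 / (1 - 0.81), 2), tolerance = 1e-10)
  expect_true(all(v2$flagged))
  # duplicated column: infinite VIF flagged, no crash
  v3 <- vif_screen(data.frame(a = 1:10 + 0.5, b = 1:10 + 0.5))
  expect_true(all(!is.finite(v3$vif)))
  expect_true(all(v3$flagged))
  expect_error(vif_screen(data.frame(a = 1:3)), "at least 2")
})

test_that("forward selection obeys its entry-threshold extremes", {
  set.seed(37)
  x <- data.frame(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  y <- rbinom(60, 1, 0.5)
  expect_setequal(forward_logistic(x, y, entry_p = 1)$selected,
                  c("a", "b", "c"))
  expect_length(forward_logistic(x, y, entry_p = 0)$selected, 0)
  expect_error(forward_logistic(x, rep(1, 60)), "constant")
})

test_that("forward selection recovers a strong predictor among noise", {
  hits <- first <- 0
  for (r in 1:20) {
    set.seed(400 + r)
    x <- as.data.frame(matrix(rnorm(200 * 5), 200))
    names(x) <- c("strong", paste0("noise", 1:4))
    y <- rbinom(200, 1, plogis(2 * x$strong))
    fl <- forward_logistic(x, y)
    hits <- hits + ("strong" %in% fl$selected)
    first <- first + identical(fl$selected[1], "strong")
  }
  expect_equal(hits, 20)
  expect_equal(first, 20)
})

test_that("a perfectly separating predictor raises a named error", {
  x <- data.frame(sep = c(rep(0, 20), rep(1, 20)), other = rnorm(40))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(forward_logistic(x, y), "sep")
  expect_error(forward_logistic(x, y), "separation")
})

test_that("odds ratios are the exponentiated coefficients", {
  set.seed(38)
  x <- data.frame(a = rnorm(150))
  y <- rbinom(150, 1, plogis(x$a))
  fl <- forward_logistic(x, y, entry_p = 1)
  expect_equal(fl$coefficients$odds_ratio, exp(fl$coefficients$estimate))
  expect_true(all(fl$fitted_probabilities > 0 & fl$fitted_probabilities < 1))
})

test_that("the AFP marker reproduces its contingency-table diagnostics", {
  tab <- afp_ki67_table()
  scores <- c(rep(1, tab["high", "afp_high"]), rep(0, tab["high", "afp_low"]),
              rep(1, tab["low", "afp_high"]), rep(0, tab["low", "afp_low"]))
  labels <- rep(c(1, 0), times = rowSums(tab))
  r <- roc_analysis(scores, labels)
  expect_equal(round(r$auc, 3), 0.673)
  expect_equal(round(r$sensitivity_pct, 1), 52.2)
  expect_equal(round(r$specificity_pct, 1), 82.4)
  # binary-marker identity: AUC = (sens + spec) / 2
  expect_equal(r$auc, (r$sensitivity_pct + r$specificity_pct) / 200)
})

test_that("ROC is invariant under monotone transforms and orientation", {
  set.seed(39)
  s <- rlnorm(80); y <- rbinom(80, 1, plogis(log(s)))
  r1 <- roc_analysis(s, y)
  r2 <- roc_analysis(log(s), y)
  expect_equal(r1$auc, r2$auc)
  expect_equal(r1$sensitivity_pct, r2$sensitivity_pct)
  r3 <- roc_analysis(-s, y)  # reversed orientation is auto-detected
  expect_equal(r3$auc, r1$auc)
  expect_identical(r3$direction, "<=")
})

test_that("ROC agrees with the pROC reference implementation", {
  set.seed(40)
  s <- rnorm(120); y <- rbinom(120, 1, plogis(1.5 * s))
  r <- roc_analysis(s, y)
  ref <- pROC::roc(y, s, direction = "<", quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
})

test_that("separable and degenerate score patterns behave as specified", {
  r <- roc_analysis(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(r$sensitivity_pct, 100)
  expect_equal(r$specificity_pct, 100)
  expect_true(r$cutoff > 0.2 && r$cutoff <= 0.8)
  expect_equal(r$youden, 1)
  expect_warning(rc <- roc_analysis(rep(1, 20), rep(c(0, 1), 10)),
                 "constant")
  expect_equal(rc$auc, 0.5)
})

test_that("DeLong intervals contain the AUC and tighten with n", {
  widths <- vapply(c(60, 240), function(n) {
    set.seed(41)
    s <- rnorm(n); y <- rbinom(n, 1, plogis(s))
    r <- roc_analysis(s, y)
    expect_gte(r$auc, r$ci[1]); expect_lte(r$auc, r$ci[2])
    r$ci[2] - r$ci[1]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("Hosmer-Lemeshow handles its degenerate anchors", {
  hl <- suppressWarnings(hosmer_lemeshow(rep(0.5, 40),
                                         rep(c(0, 1), 20)))
  expect_equal(hl$statistic, 0)
  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), n_groups = 10),
               "at least 2")
  set.seed(43)
  p <- runif(400); y <- rbinom(400, 1, p)
  hl2 <- hosmer_lemeshow(p, y)
  expect_equal(hl2$df, 8)
  expect_true(hl2$p_value > 0 && hl2$p_value <= 1)
})

test_that("calibration curve matches a hand-computed three-bin example", {
  p <- c(0.1, 0.15, 0.2, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9)
  y <- c(0, 0, 1, 0, 1, 1, 1, 1, 0)
  cal <- calibration_curve(p, y, n_bins = 3)
  expect_equal(cal$curve$predicted, c(0.15, 0.5, 0.8))
  expect_equal(cal$curve$observed, c(1 / 3, 2 / 3, 2 / 3))
  expect_equal(cal$mae,
               mean(abs(c(0.15, 0.5, 0.8) - c(1 / 3, 2 / 3, 2 / 3))))
  # bounds: total miscalibration and consistency
  expect_equal(suppressWarnings(
    calibration_curve(rep(1, 20), rep(0, 20), n_bins = 10))$mae, 1)
  set.seed(44)
  pp <- runif(5000); yy <- rbinom(5000, 1, pp)
  expect_lt(calibration_curve(pp, yy)$mae, 0.05)
})

test_that("decision curves satisfy their closed-form references", {
  set.seed(45)
  p <- runif(500); y <- rbinom(500, 1, p)
  dc <- decision_curve(p, y, thresholds = seq(0.05, 0.95, 0.05))
  expect_true(all(dc$treat_none == 0))
  prev <- mean(y)
  expect_equal(dc$treat_all,
               prev - (1 - prev) * dc$threshold / (1 - dc$threshold))
  # a calibrated model is at least as good as treat-all at the prevalence
  pt <- dc$threshold[which.min(abs(dc$threshold - prev))]
  expect_gte(dc$net_benefit[dc$threshold == pt] + 1e-9,
             dc$treat_all[dc$threshold == pt])
  expect_warning(decision_curve(p, y, thresholds = c(0.5, 1)), "excluded")
})
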