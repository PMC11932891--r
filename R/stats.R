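# Agreement, group comparison, collinearity, forward logistic modelling,
# ROC, calibration and decision-curve analysis.

#' Inter-reader agreement (ICC)
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation (ICC(2,1)) between two readers, computed from the two-way
#' ANOVA mean squares. Values above 0.75 are conventionally read as good
#' agreement.
#'
#' @param a,b paired numeric vectors (one value per subject), or data
#'   frames of features with matching numeric columns (one ICC per
#'   column).
#' @return a single ICC, or a named vector of ICCs for data-frame input.
#' @export
icc_agreement <- function(a, b) {
  if (is.data.frame(a) && is.data.frame(b)) {
    common <- intersect(names(a), names(b))
    common <- common[vapply(a[common], is.numeric, logical(1))]
    if (!length(common)) stop("no shared numeric features", call. = FALSE)
    return(vapply(common, function(cn) icc_agreement(a[[cn]], b[[cn]]),
                  numeric(1)))
  }
  if (length(a) != length(b)) stop("unpaired observations", call. = FALSE)
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 5) stop("ICC needs at least 5 paired observations", call. = FALSE)
  dat <- cbind(a, b)
  k <- 2
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  if (sum((dat - grand)^2) < .Machine$double.eps * n)
    stop("zero total variance; ICC undefined", call. = FALSE)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  mse <- sum((dat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2) / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
}

#' Normality-gated two-group comparison of a continuous feature
#'
#' Shapiro-Wilk at 0.05 in each group decides the test: both normal gives
#' the independent two-sample t-test (pooled variance), otherwise the
#' Mann-Whitney rank-sum test. Group summaries follow the matching
#' convention: mean +/- SD when normal, median +/- IQR otherwise.
#'
#' @param values numeric vector.
#' @param labels binary group labels (two non-empty groups).
#' @return list of class `"group_comparison"`: `test`, `statistic`,
#'   `p_value`, `normal`, and a `summaries` data frame.
#' @export
compare_feature <- function(values, labels) {
  g <- split(values, labels)
  if (length(g) != 2 || any(lengths(g) == 0))
    stop("need exactly two non-empty groups", call. = FALSE)
  if (all(vapply(g, function(x) isTRUE(stats::var(x) == 0), logical(1))))
    stop("values are constant in both groups", call. = FALSE)
  normal_p <- vapply(g, function(x) {
    if (length(x) < 3 || length(x) > 5000 || isTRUE(stats::var(x) == 0))
      return(0)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  normal <- all(normal_p > 0.05)
  if (normal) {
    ht <- stats::t.test(g[[1]], g[[2]], var.equal = TRUE)
    summ <- data.frame(group = names(g), n = lengths(g),
                       location = vapply(g, mean, numeric(1)),
                       spread = vapply(g, stats::sd, numeric(1)),
                       style = "mean ± SD")
  } else {
    ht <- stats::wilcox.test(g[[1]], g[[2]], exact = FALSE, correct = FALSE)
    summ <- data.frame(group = names(g), n = lengths(g),
                       location = vapply(g, stats::median, numeric(1)),
                       spread = vapply(g, stats::IQR, numeric(1)),
                       style = "median ± IQR")
  }
  structure(list(test = if (normal) "t-test" else "rank-sum",
                 statistic = unname(ht$statistic), p_value = ht$p.value,
                 normal = normal, shapiro_p = normal_p, summaries = summ),
            class = "group_comparison")
}

#' Two-group comparison of a categorical covariate
#'
#' Chi-squared test (without Yates continuity correction by default) when
#' all expected cell counts are at least 5, Fisher's exact test otherwise.
#'
#' @param tab 2x2 table of non-negative integer counts (groups x levels).
#' @param correct apply the continuity correction in the chi-squared
#'   branch.
#' @return a `"group_comparison"` list with `test`, `statistic`,
#'   `p_value`, `table` and `expected`.
#' @export
compare_categorical <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("'tab' must be a 2x2 table of non-negative integer counts",
         call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("empty table margin", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ht <- stats::chisq.test(tab, correct = correct)
    test <- "chi-square"
  } else {
    ht <- stats::fisher.test(tab)
    test <- "Fisher"
  }
  structure(list(test = test,
                 statistic = if (test == "chi-square")
                   unname(ht$statistic) else NA_real_,
                 p_value = ht$p.value, table = tab, expected = expected),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: p = %.4g\n", x$test, x$p_value))
  if (!is.null(x$summaries)) print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors; values above the threshold (default 5) flag collinearity.
#' A perfectly collinear column yields an infinite VIF (flagged, not an
#' error).
#'
#' @param x numeric matrix or data frame of predictors (>= 2 columns,
#'   more rows than columns).
#' @param threshold flagging threshold.
#' @return data frame with `predictor`, `vif`, `flagged`.
#' @export
vif_screen <- function(x, threshold = 5) {
  x <- as.data.frame(x)
  if (ncol(x) < 2) stop("need at least 2 predictors", call. = FALSE)
  if (nrow(x) <= ncol(x))
    stop("need more observations than predictors", call. = FALSE)
  vifs <- vapply(seq_along(x), function(j) {
    fit <- stats::lm(x[[j]] ~ ., data = x[-j])
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = names(x), vif = vifs,
             flagged = !is.finite(vifs) | vifs > threshold)
}

# separation / non-convergence check on a fitted binomial glm; coefficients
# are judged on the per-SD scale so small-unit predictors are not misflagged
.check_separation <- function(fit, context = "model") {
  cf <- stats::coef(fit)[-1]
  if (!length(cf)) return(invisible(fit))
  mf <- stats::model.frame(fit)[-1]
  sds <- vapply(names(cf), function(nm)
    if (nm %in% names(mf)) stats::sd(mf[[nm]]) else 1, numeric(1))
  scaled <- abs(cf) * sds
  if (!fit$converged || any(scaled > 15, na.rm = TRUE)) {
    worst <- names(cf)[which.max(scaled)]
    stop(sprintf("separation detected in %s: predictor '%s' perfectly splits the classes",
                 context, worst), call. = FALSE)
  }
  invisible(fit)
}

#' Forward stepwise logistic regression (likelihood-ratio entry)
#'
#' Iterative forward selection: at each step the candidate whose addition
#' gives the smallest likelihood-ratio test p-value enters if that p-value
#' is below `entry_p`; ties break by candidate order. Maximum-likelihood
#' fit via [stats::glm()]. Deterministic given the inputs.
#'
#' @param x data frame of candidate predictors (numeric or 0/1).
#' @param y binary outcome vector.
#' @param entry_p likelihood-ratio entry threshold (default 0.05); 1
#'   admits every candidate, 0 none.
#' @return list of class `"forward_logit"`: `selected`, `coefficients`
#'   (estimate, odds ratio, Wald p), `fitted_probabilities`, the `glm`
#'   object, and the selection `trace`.
#' @export
forward_logistic <- function(x, y, entry_p = 0.05) {
  x <- as.data.frame(x)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("outcome labels are constant", call. = FALSE)
  dat <- cbind(x, .y = y)
  selected <- character(0)
  trace <- list()
  fit0 <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  repeat {
    remaining <- setdiff(names(x), selected)
    if (!length(remaining)) break
    dev0 <- fit0$deviance
    ps <- vapply(remaining, function(cand) {
      fml <- stats::as.formula(paste(".y ~",
                                     paste(c(selected, cand), collapse = "+")))
      fit1 <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                          data = dat))
      sep <- inherits(tryCatch(.check_separation(fit1), error = identity),
                      "error")
      if (sep && !length(selected))
        stop(sprintf("separation detected in forward logistic regression: predictor '%s' perfectly splits the classes",
                     cand), call. = FALSE)
      if (sep) return(Inf)  # adding this term destabilizes the MLE: skip
      stats::pchisq(dev0 - fit1$deviance, df = 1, lower.tail = FALSE)
    }, numeric(1))
    best <- which.min(ps)
    if (!is.finite(ps[best])) break
    if (!(ps[best] < entry_p || entry_p >= 1)) break
    selected <- c(selected, remaining[best])
    trace[[length(trace) + 1L]] <- data.frame(step = length(selected),
                                              entered = remaining[best],
                                              lrt_p = unname(ps[best]))
    fit0 <- suppressWarnings(stats::glm(
      stats::as.formula(paste(".y ~", paste(selected, collapse = "+"))),
      family = stats::binomial(), data = dat))
  }
  .check_separation(fit0, "forward logistic regression")
  cf <- summary(fit0)$coefficients
  coefs <- data.frame(term = rownames(cf), estimate = cf[, 1],
                      odds_ratio = exp(cf[, 1]), p_value = cf[, 4],
                      row.names = NULL)
  structure(list(selected = selected, coefficients = coefs,
                 intercept = unname(stats::coef(fit0)[1]),
                 fitted_probabilities = stats::fitted(fit0),
                 model = fit0, entry_p = entry_p,
                 trace = if (length(trace)) do.call(rbind, trace) else NULL),
            class = "forward_logit")
}

#' @export
print.forward_logit <- function(x, ...) {
  if (!length(x$selected)) {
    cat("forward logistic regression: intercept-only model\n")
  } else {
    cat("forward logistic regression, selected:",
        paste(x$selected, collapse = ", "), "\n")
    print(transform(x$coefficients, estimate = round(estimate, 4),
                    odds_ratio = signif(odds_ratio, 4),
                    p_value = signif(p_value, 3)), row.names = FALSE)
  }
  invisible(x)
}

#' @export
predict.forward_logit <- function(object, newdata = NULL,
                                  type = "response", ...) {
  if (is.null(newdata)) return(object$fitted_probabilities)
  stats::predict(object$model, newdata = newdata, type = type)
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Empirical ROC by threshold sweep over the observed score values; AUC by
#' the rank (Mann-Whitney) statistic, identical to trapezoidal integration
#' of the empirical curve; optimal cutoff maximizing Youden's J
#' (sensitivity + specificity - 1), ties broken toward higher specificity;
#' DeLong confidence interval for the AUC. Scores are auto-oriented so the
#' AUC is at least 0.5 (the orientation is reported).
#'
#' @param scores numeric marker values.
#' @param labels binary outcome (1 = positive class).
#' @param conf_level confidence level of the DeLong interval.
#' @return list of class `"roc_result"`: `auc`, `ci`, `cutoff`,
#'   `sensitivity_pct`, `specificity_pct`, `youden`, `direction`,
#'   the sweep `coords`, and class sizes.
#' @export
roc_analysis <- function(scores, labels, conf_level = 0.95) {
  y <- as.integer(labels)
  if (length(unique(y[!is.na(y)])) < 2)
    stop("both classes must be present", call. = FALSE)
  keep <- is.finite(scores) & !is.na(y)
  scores <- scores[keep]; y <- y[keep]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (stats::var(scores) == 0) {
    warning("constant scores: AUC 0.5, no cutoff", call. = FALSE)
    return(structure(list(auc = 0.5, ci = c(NA_real_, NA_real_),
                          cutoff = NA_real_, sensitivity_pct = NA_real_,
                          specificity_pct = NA_real_, youden = NA_real_,
                          direction = ">=", coords = NULL,
                          n_pos = n_pos, n_neg = n_neg),
                     class = "roc_result"))
  }
  # rank AUC for "higher score = positive"
  r <- rank(scores)
  auc_up <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  flip <- auc_up < 0.5
  s <- if (flip) -scores else scores
  auc <- if (flip) 1 - auc_up else auc_up

  thr <- sort(unique(s))
  coords <- data.frame(threshold = thr,
                       sensitivity = vapply(thr, function(t)
                         sum(s >= t & y == 1) / n_pos, numeric(1)),
                       specificity = vapply(thr, function(t)
                         sum(s < t & y == 0) / n_neg, numeric(1)))
  coords$youden <- coords$sensitivity + coords$specificity - 1
  best_j <- max(coords$youden)
  cand <- coords[coords$youden >= best_j - 1e-12, , drop = FALSE]
  best <- cand[which.max(cand$specificity)[1], ]
  if (flip) coords$threshold <- -coords$threshold

  lv <- c(0, 1)
  proc_obj <- pROC::roc(response = y, predictor = scores, levels = lv,
                        direction = if (flip) ">" else "<", quiet = TRUE)
  ci <- as.numeric(suppressWarnings(
    pROC::ci.auc(proc_obj, conf.level = conf_level,
                 method = "delong")))[c(1, 3)]

  structure(list(auc = auc, ci = ci,
                 cutoff = if (flip) -best$threshold else best$threshold,
                 sensitivity_pct = 100 * best$sensitivity,
                 specificity_pct = 100 * best$specificity,
                 youden = best$youden,
                 direction = if (flip) "<=" else ">=",
                 coords = coords, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f); cutoff %s %.4g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$auc, x$ci[1], x$ci[2], x$direction, x$cutoff,
              x$sensitivity_pct, x$specificity_pct))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  if (is.null(x$coords)) stop("degenerate ROC has no curve", call. = FALSE)
  o <- order(1 - x$coords$specificity, x$coords$sensitivity)
  graphics::plot(c(1, 1 - x$coords$specificity[o], 0),
                 c(1, x$coords$sensitivity[o], 0), type = "l",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping of the predicted probabilities; chi-squared
#' statistic on observed vs expected event counts with `n_groups - 2`
#' degrees of freedom. Tied probabilities that collapse group boundaries
#' reduce the number of groups with a warning.
#'
#' @param probabilities predicted event probabilities.
#' @param labels observed binary outcomes.
#' @param n_groups number of risk groups (default 10).
#' @return list with `statistic`, `df`, `p_value`, `n_groups` and the
#'   per-group `table`.
#' @export
hosmer_lemeshow <- function(probabilities, labels, n_groups = 10) {
  p <- probabilities; y <- as.numeric(labels)
  n <- length(p)
  if (n < 2 * n_groups)
    stop("need at least 2 observations per risk group", call. = FALSE)
  breaks <- unique(stats::quantile(p, seq(0, 1, length.out = n_groups + 1)))
  if (length(breaks) < 2) {  # all probabilities identical: one group
    g <- factor(rep(1, n))
  } else {
    if (length(breaks) < n_groups + 1)
      warning("tied probabilities collapsed risk groups", call. = FALSE)
    g <- cut(p, breaks, include.lowest = TRUE)
  }
  obs <- tapply(y, g, sum)
  npt <- tapply(y, g, length)
  expct <- tapply(p, g, sum)
  pbar <- expct / npt
  denom <- npt * pbar * (1 - pbar)
  term <- (obs - expct)^2 / ifelse(denom > 0, denom, NA)
  stat <- sum(term[denom > 0])
  df <- length(obs) - 2
  p_value <- if (df >= 1) stats::pchisq(stat, df, lower.tail = FALSE) else NA_real_
  list(statistic = stat, df = df, p_value = p_value,
       n_groups = length(levels(g)),
       table = data.frame(group = names(obs), n = as.vector(npt),
                          observed = as.vector(obs),
                          expected = as.vector(expct)))
}

#' Calibration curve and mean absolute error
#'
#' Bins predictions into equal-width probability bins, compares mean
#' predicted probability with observed event frequency per bin, and
#' reports the mean absolute error across non-empty bins. Empty bins are
#' dropped with a warning.
#'
#' @inheritParams hosmer_lemeshow
#' @param n_bins number of equal-width bins over \[0, 1\].
#' @return list with `curve` (bin, n, predicted, observed) and `mae`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10) {
  p <- probabilities; y <- as.numeric(labels)
  if (length(p) < n_bins)
    stop("need at least as many observations as bins", call. = FALSE)
  breaks <- seq(0, 1, length.out = n_bins + 1)
  g <- cut(p, breaks, include.lowest = TRUE)
  counts <- table(g)
  if (any(counts == 0))
    warning(sprintf("%d empty calibration bin(s) dropped", sum(counts == 0)),
            call. = FALSE)
  keep <- levels(g)[counts > 0]
  pred <- tapply(p, g, mean)[keep]
  obs <- tapply(y, g, mean)[keep]
  curve <- data.frame(bin = keep, n = as.vector(counts[keep]),
                      predicted = as.vector(pred), observed = as.vector(obs))
  list(curve = curve, mae = mean(abs(curve$predicted - curve$observed)))
}

#' Decision-curve analysis
#'
#' Net benefit of treating at each threshold probability pt:
#' `NB(pt) = TP/n - FP/n * pt / (1 - pt)`, classifying predicted
#' probability >= pt as positive, together with the treat-all and
#' treat-none reference policies. Thresholds at or above 1 are excluded.
#'
#' @inheritParams hosmer_lemeshow
#' @param thresholds threshold probabilities in (0, 1).
#' @return data frame: `threshold`, `net_benefit`, `treat_all`,
#'   `treat_none`.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  bad <- thresholds <= 0 | thresholds >= 1
  if (any(bad)) {
    warning("thresholds outside (0, 1) excluded", call. = FALSE)
    thresholds <- thresholds[!bad]
  }
  if (!length(thresholds)) stop("no valid thresholds", call. = FALSE)
  p <- probabilities; y <- as.numeric(labels)
  n <- length(y)
  prev <- mean(y)
  w <- thresholds / (1 - thresholds)
  nb <- vapply(seq_along(thresholds), function(i) {
    pos <- p >= thresholds[i]
    sum(pos & y == 1) / n - sum(pos & y == 0) / n * w[i]
  }, numeric(1))
  data.frame(threshold = thresholds, net_benefit = nb,
             treat_all = prev - (1 - prev) * w, treat_none = 0)
}
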