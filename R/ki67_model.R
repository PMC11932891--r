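# Combined diagnostic model for dichotomized Ki-67 expression:
# univariate screening -> collinearity check -> forward-LR logistic
# regression -> ROC / calibration / decision-curve assessment.

#' Fit the Ki-67 diagnostic model
#'
#' Runs the full statistical modelling chain on a per-subject feature
#' table: each candidate is screened univariately (normality-gated t /
#' rank-sum test for continuous features, chi-squared / Fisher for binary
#' ones) at `screen_p`; screened candidates are checked for collinearity
#' (predictors with VIF above `vif_threshold` are dropped, highest first);
#' the survivors enter forward likelihood-ratio logistic regression at
#' `entry_p`; the selected model is assessed by ROC with Youden cutoff,
#' the Hosmer-Lemeshow test, a calibration curve with its mean absolute
#' error, and decision-curve analysis.
#'
#' @param data data frame with the binary outcome column and candidate
#'   columns.
#' @param outcome name of the binary outcome column (default
#'   `"ki67_high"`).
#' @param candidates candidate column names; defaults to every numeric
#'   column except the outcome and identifier columns.
#' @param binary names of candidates to treat as categorical in the
#'   univariate screen (default `"afp_high"`).
#' @param screen_p univariate entry threshold (default 0.05).
#' @param entry_p forward-selection likelihood-ratio threshold.
#' @param vif_threshold collinearity threshold (default 5).
#' @param vif_action `"report"` (default) computes and flags VIFs of the
#'   screened candidates without removing any, matching the convention of
#'   treating VIF > threshold as indicating collinearity; `"drop"`
#'   iteratively removes the highest-VIF predictor until none is flagged.
#' @return object of class `"ki67_model"` with the screening table, VIF
#'   table, the `forward_logit` fit, `roc`, `hosmer_lemeshow`,
#'   `calibration` and `decision_curve` components.
#' @seealso [generate_feature_cohort()] for synthetic input,
#'   [predict.ki67_model()] for test-set evaluation.
#' @export
ki67_model <- function(data, outcome = "ki67_high", candidates = NULL,
                       binary = "afp_high", screen_p = 0.05,
                       entry_p = 0.05, vif_threshold = 5,
                       vif_action = c("report", "drop")) {
  vif_action <- match.arg(vif_action)
  if (!outcome %in% names(data)) stop("outcome column not found", call. = FALSE)
  y <- data[[outcome]]
  if (length(unique(y)) != 2 || !all(y %in% c(0, 1)))
    stop("outcome must be binary 0/1 with both classes present", call. = FALSE)
  if (is.null(candidates)) {
    candidates <- names(data)[vapply(data, is.numeric, logical(1))]
    candidates <- setdiff(candidates, c(outcome, "subject", "id"))
  }
  binary <- intersect(binary, candidates)

  screen <- lapply(candidates, function(v) {
    x <- data[[v]]
    if (isTRUE(stats::var(x) == 0))
      return(data.frame(candidate = v, test = "skipped (constant)",
                        p_value = NA_real_, screened = FALSE))
    cmp <- if (v %in% binary)
      compare_categorical(table(factor(y, levels = c(1, 0)),
                                factor(x, levels = sort(unique(x)))))
    else compare_feature(x, y)
    data.frame(candidate = v, test = cmp$test, p_value = cmp$p_value,
               screened = cmp$p_value < screen_p)
  })
  screen <- do.call(rbind, screen)
  kept <- screen$candidate[which(screen$screened)]

  vif_tab <- NULL
  if (length(kept) >= 2) {
    repeat {
      vif_tab <- vif_screen(data[kept], threshold = vif_threshold)
      if (vif_action == "report" || !any(vif_tab$flagged) ||
          length(kept) <= 2) break
      kept <- setdiff(kept, vif_tab$predictor[which.max(vif_tab$vif)])
    }
  }

  fl <- forward_logistic(data[kept], y, entry_p = entry_p)
  probs <- fl$fitted_probabilities
  roc <- if (length(fl$selected)) roc_analysis(probs, y) else NULL
  hl <- tryCatch(hosmer_lemeshow(probs, y), error = function(e) NULL)
  cal <- tryCatch(suppressWarnings(calibration_curve(probs, y)),
                  error = function(e) NULL)
  dca <- decision_curve(probs, y)

  structure(list(call = match.call(), outcome = outcome,
                 candidates = candidates, screening = screen,
                 vif = vif_tab, selected = fl$selected, forward = fl,
                 roc = roc, hosmer_lemeshow = hl, calibration = cal,
                 decision_curve = dca, n = length(y),
                 prevalence = mean(y)),
            class = "ki67_model")
}

#' @export
print.ki67_model <- function(x, ...) {
  cat(sprintf("Ki-67 diagnostic model (n = %d, prevalence %.2f)\n", x$n,
              x$prevalence))
  cat(sprintf("screened %d/%d candidates; selected: %s\n",
              sum(x$screening$screened, na.rm = TRUE),
              nrow(x$screening),
              if (length(x$selected)) paste(x$selected, collapse = ", ")
              else "(none - intercept only)"))
  if (!is.null(x$roc))
    cat(sprintf("training AUC %.3f (95%% CI %.3f-%.3f)\n", x$roc$auc,
                x$roc$ci[1], x$roc$ci[2]))
  invisible(x)
}

#' @export
summary.ki67_model <- function(object, ...) {
  print(object)
  cat("\nUnivariate screening:\n")
  print(transform(object$screening, p_value = signif(p_value, 3)),
        row.names = FALSE)
  if (!is.null(object$vif)) {
    cat("\nCollinearity (VIF):\n")
    print(object$vif, row.names = FALSE)
  }
  if (length(object$selected)) {
    cat("\nMultivariable model:\n")
    print(object$forward)
  }
  if (!is.null(object$hosmer_lemeshow))
    cat(sprintf("\nHosmer-Lemeshow: chi2 = %.3f (df %d), p = %.3f\n",
                object$hosmer_lemeshow$statistic, object$hosmer_lemeshow$df,
                object$hosmer_lemeshow$p_value))
  if (!is.null(object$calibration))
    cat(sprintf("Calibration MAE: %.4f\n", object$calibration$mae))
  invisible(object)
}

#' @export
coef.ki67_model <- function(object, ...) stats::coef(object$forward$model)

#' @export
residuals.ki67_model <- function(object, ...)
  stats::residuals(object$forward$model, ...)

#' Predict Ki-67 class probabilities
#'
#' @param object a fitted [ki67_model()].
#' @param newdata data frame containing the selected predictor columns;
#'   omit for training-set fitted probabilities.
#' @param type passed to [predict.glm()] (default `"response"`).
#' @param ... unused.
#' @return numeric vector of predicted probabilities of the high class.
#' @export
predict.ki67_model <- function(object, newdata = NULL, type = "response",
                               ...) {
  predict(object$forward, newdata = newdata, type = type)
}

#' @export
plot.ki67_model <- function(x, which = c("roc", "calibration", "dca"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    if (is.null(x$roc)) stop("intercept-only model has no ROC", call. = FALSE)
    plot(x$roc, ...)
  } else if (which == "calibration") {
    cc <- x$calibration$curve
    graphics::plot(cc$predicted, cc$observed, xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "predicted probability", ylab = "observed frequency",
                   main = sprintf("Calibration (MAE %.3f)", x$calibration$mae),
                   ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    dc <- x$decision_curve
    graphics::plot(dc$threshold, dc$net_benefit, type = "l",
                   ylim = range(c(dc$net_benefit, dc$treat_all, 0)),
                   xlab = "threshold probability", ylab = "net benefit",
                   main = "Decision curve", ...)
    graphics::lines(dc$threshold, dc$treat_all, lty = 2)
    graphics::abline(h = 0, lty = 3)
    graphics::legend("topright", c("model", "treat all", "treat none"),
                     lty = 1:3, bty = "n")
  }
  invisible(x)
}

#' Evaluate a fitted model on a held-out set
#'
#' @param object a `ki67_model`.
#' @param newdata test-set data frame containing the outcome and selected
#'   predictors.
#' @return list with `roc`, `calibration` and `decision_curve` on the test
#'   set.
#' @export
evaluate_ki67_model <- function(object, newdata) {
  y <- newdata[[object$outcome]]
  p <- predict(object, newdata)
  list(roc = roc_analysis(p, y),
       calibration = tryCatch(suppressWarnings(calibration_curve(p, y,
                                n_bins = min(10, max(2, length(y) %/% 4)))),
                              error = function(e) NULL),
       decision_curve = decision_curve(p, y))
}
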