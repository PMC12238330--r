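# Evaluation metrics (MAE, MSE, RMSE), signed percent error, and the
# normality-gated paired comparison used for external validation.

#' Regression error metrics
#'
#' MAE = mean |y - yhat|, MSE = mean (y - yhat)^2, RMSE = sqrt(MSE).
#' Always RMSE^2 = MSE and MAE <= RMSE (power-mean inequality).
#'
#' @param y observed (reference) doses.
#' @param yhat predicted doses, same length.
#' @return named numeric: mse, mae, rmse.
#' @export
error_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("error_metrics: length mismatch")
  if (length(y) == 0) stop("error_metrics: empty input")
  e <- y - yhat
  mse <- mean(e^2)
  c(mse = mse, mae = mean(abs(e)), rmse = sqrt(mse))
}

#' Evaluate a dose model on a test cohort
#'
#' Overall and per-organ MAE / MSE / RMSE of the model predictions
#' against the reference target doses.
#'
#' @param model a `dose_model`.
#' @param test preprocessed test data.frame with `target_dose_Gy`.
#' @return an object of class `metric_report` with `$mse`, `$mae`,
#'   `$rmse`, `$per_organ` (data.frame), `$n`.
#' @export
evaluate_dose_model <- function(model, test) {
  if (nrow(test) == 0) stop("evaluate_dose_model: empty test set")
  pred <- predict(model, test)
  y <- test$target_dose_Gy
  overall <- error_metrics(y, pred)
  per_organ <- NULL
  if ("organ" %in% names(test)) {
    per_organ <- do.call(rbind, lapply(sort(unique(test$organ)), function(o) {
      i <- test$organ == o
      m <- error_metrics(y[i], pred[i])
      data.frame(organ = o, n = sum(i), mse = m["mse"], mae = m["mae"],
                 rmse = m["rmse"], row.names = NULL)
    }))
  }
  structure(list(mse = unname(overall["mse"]), mae = unname(overall["mae"]),
                 rmse = unname(overall["rmse"]), per_organ = per_organ,
                 n = length(y), family = model$family),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s, n = %d: MSE %.4g, MAE %.4g, RMSE %.4g\n",
              x$family %||% "model", x$n, x$mse, x$mae, x$rmse))
  if (!is.null(x$per_organ)) {
    cat("  per organ:\n")
    print(x$per_organ, row.names = FALSE)
  }
  invisible(x)
}

#' Signed percent error of a prediction against a reference
#'
#' (pred - ref) / ref x 100; positive when the prediction overestimates.
#'
#' @param pred_dose predicted dose(s).
#' @param ref_dose reference dose(s); must be nonzero.
#' @return signed percent error(s).
#' @export
percent_error <- function(pred_dose, ref_dose) {
  if (any(ref_dose == 0)) stop("percent_error: reference dose is zero")
  (pred_dose - ref_dose) / ref_dose * 100
}

#' Normality-gated paired comparison of two dose sets
#'
#' Checks the normality of the paired differences with a Shapiro-Wilk
#' test at level `alpha`; if normality is not rejected a paired t-test is
#' run, otherwise a Wilcoxon signed-rank test. Identical vectors are a
#' degenerate case returned with p = 1 and a flag.
#'
#' @param doses_a,doses_b paired dose vectors, equal length >= 3
#'   (`doses_b` is the reference for the percent error).
#' @param alpha significance level for both the normality gate and the
#'   comparison (default 0.05).
#' @return list: `test` ("paired_t", "wilcoxon" or "degenerate"),
#'   `p_value`, `mean_percent_error`, `shapiro_p`, `significant`,
#'   `degenerate`.
#' @export
paired_comparison <- function(doses_a, doses_b, alpha = 0.05) {
  if (length(doses_a) != length(doses_b))
    stop("paired_comparison: length mismatch")
  if (length(doses_a) < 3) stop("paired_comparison: need >= 3 pairs")
  d <- doses_a - doses_b
  mpe <- mean(percent_error(doses_a, doses_b))
  if (all(d == 0))
    return(list(test = "degenerate", p_value = 1,
                mean_percent_error = 0, shapiro_p = NA_real_,
                significant = FALSE, degenerate = TRUE))
  sw <- stats::shapiro.test(d)
  if (sw$p.value > alpha) {
    ht <- stats::t.test(doses_a, doses_b, paired = TRUE)
    test <- "paired_t"
  } else {
    ht <- stats::wilcox.test(doses_a, doses_b, paired = TRUE, exact = FALSE)
    test <- "wilcoxon"
  }
  list(test = test, p_value = unname(ht$p.value),
       mean_percent_error = mpe, shapiro_p = unname(sw$p.value),
       significant = ht$p.value < alpha, degenerate = FALSE)
}
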