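check_metric_input <- function(y_act, y_pred, n_min = 1L) {
  stopifnot(is.numeric(y_act), is.numeric(y_pred))
  if (length(y_act) != length(y_pred)) {
    stop("y_act and y_pred must have equal length", call. = FALSE)
  }
  if (length(y_act) < n_min) {
    stop("metric needs at least ", n_min, " observations", call. = FALSE)
  }
  if (any(!is.finite(y_act)) || any(!is.finite(y_pred))) {
    stop("metric inputs must be finite", call. = FALSE)
  }
  invisible(NULL)
}

#' Pearson correlation between actual and predicted affinities
#'
#' @param y_act,y_pred Actual and predicted pKd values.
#' @return The product-moment correlation coefficient.
#' @export
pearson_r <- function(y_act, y_pred) {
  check_metric_input(y_act, y_pred, n_min = 2L)
  if (sd(y_act) == 0 || sd(y_pred) == 0) {
    stop("Pearson R undefined: zero variance input", call. = FALSE)
  }
  num <- sum((y_act - mean(y_act)) * (y_pred - mean(y_pred)))
  num / (sqrt(sum((y_act - mean(y_act))^2)) * sqrt(sum((y_pred - mean(y_pred))^2)))
}

#' Root mean squared error
#' @inheritParams pearson_r
#' @return RMSE on the pKd scale.
#' @export
rmse <- function(y_act, y_pred) {
  check_metric_input(y_act, y_pred)
  sqrt(mean((y_pred - y_act)^2))
}

#' Mean absolute error
#' @inheritParams pearson_r
#' @return MAE on the pKd scale.
#' @export
mae <- function(y_act, y_pred) {
  check_metric_input(y_act, y_pred)
  mean(abs(y_pred - y_act))
}

#' Regression-corrected standard deviation
#'
#' Fits `y_act ~ a * y_pred + b` by least squares and returns the sample
#' standard deviation (divisor N-1) of the fitted-minus-actual residuals.
#' A perfect linear relationship of any slope therefore scores 0.
#'
#' @inheritParams pearson_r
#' @return SD of the regression residuals.
#' @export
sd_corrected <- function(y_act, y_pred) {
  check_metric_input(y_act, y_pred, n_min = 3L)
  if (sd(y_pred) == 0) {
    stop("SD undefined: constant predictions", call. = FALSE)
  }
  fit <- lm(y_act ~ y_pred)
  a <- coef(fit)[["y_pred"]]
  b <- coef(fit)[["(Intercept)"]]
  sqrt(sum(((a * y_pred + b) - y_act)^2) / (length(y_act) - 1L))
}

#' Concordance index
#'
#' Over all pairs with differing actual values, the fraction ranked in the
#' same order by the predictions; prediction ties contribute 0.5. Computed
#' with an O(N^2) pair count, exact for the N of typical benchmark sets.
#'
#' @inheritParams pearson_r
#' @return CI in `[0, 1]`.
#' @export
concordance_index <- function(y_act, y_pred) {
  check_metric_input(y_act, y_pred, n_min = 2L)
  da <- outer(y_act, y_act, "-")
  dp <- outer(y_pred, y_pred, "-")
  gt <- da > 0
  z <- sum(gt)
  if (z == 0) {
    stop("concordance index undefined: all actual values tied", call. = FALSE)
  }
  h <- (dp > 0) + 0.5 * (dp == 0)
  sum(h[gt]) / z
}

#' Evaluate a table of affinity predictions
#'
#' Computes the five regression metrics (R, RMSE, MAE, SD, CI) from a
#' data.frame of actual and predicted pKd values.
#'
#' @param data A data.frame containing the two columns named below.
#' @param actual,predicted Column names (default `"y_act"`, `"y_pred"`).
#' @return A `metrics_report`: one-row data.frame with columns `n`, `r`,
#'   `rmse`, `mae`, `sd`, `ci`.
#' @export
evaluate_predictions <- function(data, actual = "y_act", predicted = "y_pred") {
  stopifnot(is.data.frame(data), actual %in% names(data),
            predicted %in% names(data))
  ya <- data[[actual]]
  yp <- data[[predicted]]
  out <- data.frame(
    n = length(ya),
    r = pearson_r(ya, yp),
    rmse = rmse(ya, yp),
    mae = mae(ya, yp),
    sd = sd_corrected(ya, yp),
    ci = concordance_index(ya, yp)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat("Affinity prediction metrics (n = ", x$n, "):\n", sep = "")
  cat(sprintf(
    "  R %.*f | RMSE %.*f | MAE %.*f | SD %.*f | CI %.*f\n",
    digits, x$r, digits, x$rmse, digits, x$mae, digits, x$sd, digits, x$ci
  ))
  invisible(x)
}

check_screen_input <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels),
            all(is.finite(scores)))
  if (all(labels) || !any(labels)) {
    stop("screening metrics need both actives and decoys", call. = FALSE)
  }
  labels
}

#' ROC area under the curve for a virtual screen
#'
#' Actives are the positive class; a higher score means more likely
#' active. Computed from the rank statistic with average ranks for ties
#' (equivalent to the Mann-Whitney U), so an uninformative constant score
#' yields 0.5.
#'
#' @param scores Predicted affinities (or any ranking score).
#' @param labels Logical (or 0/1) vector, `TRUE` for actives.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_screen_input(scores, labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Enrichment factor at a top fraction
#'
#' `EF(x)` is the active hit-rate among the top `ceiling(x * N)` scored
#' compounds divided by the overall active rate; ties are broken by a
#' stable sort on input order. `EF(1) = 1` by construction.
#'
#' @inheritParams roc_auc
#' @param fraction Top fraction(s) in `(0, 1]`, e.g. `0.01` for the top 1%.
#' @return Numeric vector of EF values, one per fraction.
#' @export
enrichment_factor <- function(scores, labels, fraction = 0.01) {
  labels <- check_screen_input(scores, labels)
  stopifnot(all(fraction > 0), all(fraction <= 1))
  n <- length(scores)
  ord <- order(-scores) # stable: ties keep input order
  rate_all <- sum(labels) / n
  vapply(fraction, function(x) {
    k <- ceiling(x * n)
    sum(labels[ord[seq_len(k)]]) / k / rate_all
  }, 1.0)
}

#' Screening report over the standard top fractions
#'
#' @inheritParams roc_auc
#' @param fractions Top fractions to report EF at (default 1%..10%).
#' @return A `screening_report` list: `auc`, `ef` (named vector),
#'   `n_actives`, `n_decoys`.
#' @export
screening_report <- function(scores, labels, fractions = seq(0.01, 0.10, 0.01)) {
  labels <- check_screen_input(scores, labels)
  ef <- enrichment_factor(scores, labels, fractions)
  names(ef) <- sprintf("EF%g%%", 100 * fractions)
  structure(
    list(
      auc = roc_auc(scores, labels), ef = ef,
      n_actives = sum(labels), n_decoys = sum(!labels)
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, digits = 3, ...) {
  cat(
    "Virtual screening report: ", x$n_actives, " actives / ",
    x$n_decoys, " decoys\n  AUC ", round(x$auc, digits), "\n", sep = ""
  )
  cat("  ", paste(names(x$ef), round(x$ef, 2), sep = " = ", collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}
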