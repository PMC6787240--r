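#' Pooled-variance two-sample comparison of a metric between groups
#'
#' Student's independent-samples t-test (pooled variance) of recurrence
#' versus post-treatment values, reported as mean difference +/- its
#' standard error with a two-sided p-value — the "MD +/- SE" layout used
#' in clinical group comparisons. Welch's unpooled variant is available
#' behind `var_equal = FALSE`.
#'
#' @param values_rec,values_ptre Numeric samples (each n >= 2).
#' @param metric Optional metric name carried into the result.
#' @param var_equal Pool the variances (default TRUE).
#' @return An object of class `group_comparison`: `mean_rec`, `mean_ptre`,
#'   `md` (REC minus PTRE), `se`, `t`, `df`, `p_value`.
#' @export
independent_t_test <- function(values_rec, values_ptre, metric = NULL,
                               var_equal = TRUE) {
  if (length(values_rec) < 2 || length(values_ptre) < 2)
    stop("each sample must contain at least 2 values")
  ht <- stats::t.test(values_rec, values_ptre, var.equal = var_equal)
  md <- mean(values_rec) - mean(values_ptre)
  se <- unname(ht$stderr)
  structure(
    list(metric = metric,
         mean_rec = mean(values_rec), mean_ptre = mean(values_ptre),
         md = md, se = se, t = unname(ht$statistic),
         df = unname(ht$parameter), p_value = ht$p.value,
         var_equal = var_equal),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %.4g (REC) vs %.4g (PTRE), MD +/- SE, %.4g +/- %.3g, p = %.3g\n",
              if (is.null(x$metric)) "" else paste0(" ", x$metric, ":"),
              x$mean_rec, x$mean_ptre, x$md, x$se, x$p_value))
  invisible(x)
}

#' Step-wise biparametric classification rule
#'
#' The binary decision rule of the biparametric analysis: each parameter
#' is evaluated separately against its threshold and one parameter above
#' threshold classifies the lesion as recurrence (strict inequalities).
#' Defaults are the clinically established TBRmax > 2 and the
#' cohort-derived ADCmean > 1254 (10^-6 mm^2/s).
#'
#' @param theta_tbr TBRmax threshold (default 2).
#' @param theta_adc ADCmean threshold (default 1254).
#' @param combination `"or_rule"` (either marker fires), `"tbr_only"`, or
#'   `"adc_only"`.
#' @return An object of class `classifier_rule`.
#' @export
classifier_rule <- function(theta_tbr = 2, theta_adc = 1254,
                            combination = c("or_rule", "tbr_only", "adc_only")) {
  combination <- match.arg(combination)
  if (!is.finite(theta_tbr) || !is.finite(theta_adc))
    stop("thresholds must be finite")
  structure(list(theta_tbr = theta_tbr, theta_adc = theta_adc,
                 combination = combination),
            class = "classifier_rule")
}

#' @export
print.classifier_rule <- function(x, ...) {
  cat(sprintf("<classifier_rule> %s: TBRmax > %.3g%sADCmean > %.4g\n",
              x$combination,
              x$theta_tbr,
              switch(x$combination, or_rule = "  OR  ",
                     tbr_only = "  (ignoring ", adc_only = "  (only "),
              x$theta_adc))
  invisible(x)
}

#' Classify a lesion by the step-wise biparametric rule
#'
#' @param metrics A `lesion_metrics` object from [compute_metrics()], or
#'   any list/row with `tbr_max` and `adc_mean` fields.
#' @param rule A [classifier_rule()].
#' @return `"REC"` or `"PTRE"`.
#' @examples
#' classify_biparametric(list(tbr_max = 1.82, adc_mean = 1133)) # "PTRE"
#' classify_biparametric(list(tbr_max = 1.73, adc_mean = 1362)) # "REC"
#' @export
classify_biparametric <- function(metrics, rule = classifier_rule()) {
  stopifnot(inherits(rule, "classifier_rule"))
  tbr_fires <- metrics$tbr_max > rule$theta_tbr
  adc_fires <- metrics$adc_mean > rule$theta_adc
  fired <- switch(rule$combination,
                  or_rule = tbr_fires | adc_fires,
                  tbr_only = tbr_fires,
                  adc_only = adc_fires)
  if (fired) "REC" else "PTRE"
}

#' Diagnostic measures of a fixed classification rule
#'
#' Confusion counts and the derived proportions. Ratios with a zero
#' denominator are reported as `NA`, not as 0.
#'
#' @param predictions Predicted labels.
#' @param labels True labels (same length).
#' @param positive Positive-class label (default `"REC"`).
#' @return An object of class `diagnostic_measures`: `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @export
diagnostic_measures <- function(predictions, labels, positive = "REC") {
  if (length(predictions) != length(labels))
    stop("`predictions` and `labels` must have the same length")
  pp <- predictions == positive
  tl <- labels == positive
  tp <- sum(pp & tl); fp <- sum(pp & !tl)
  tn <- sum(!pp & !tl); fn <- sum(!pp & tl)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = ratio(tp, tp + fn),
         specificity = ratio(tn, tn + fp),
         ppv = ratio(tp, tp + fp),
         npv = ratio(tn, tn + fn),
         accuracy = ratio(tp + tn, length(labels))),
    class = "diagnostic_measures")
}

#' @export
print.diagnostic_measures <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("<diagnostic_measures> sens %s / spec %s, PPV %s / NPV %s  (tp %d fp %d tn %d fn %d)\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv), pct(x$npv),
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}
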