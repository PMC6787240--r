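# Empirical ROC analysis with DeLong variance, Youden cutoffs and the
# two-threshold OR-rule envelope used by the biparametric classifier.

# orient scores so larger values indicate the positive (REC) class
orient_scores <- function(scores, direction) {
  if (direction == "larger") scores else -scores
}

# structural components (Sen 1960 / DeLong): per-subject placement values
# x = positive-class scores, y = negative-class scores, ties counted 1/2
structural_components <- function(x, y) {
  V10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  V01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

# sample variance; a single-subject class contributes none (matches the
# grouped jackknife, whose (m-1)/m factor vanishes at m = 1)
var0 <- function(v) if (length(v) < 2) 0 else stats::var(v)

#' Empirical ROC curve with DeLong variance
#'
#' Computes the full empirical ROC of a continuous marker against binary
#' group labels. The AUC equals the normalised Mann-Whitney statistic
#' (ties counted 1/2); its standard error comes from the DeLong
#' structural-components estimator (identical to the grouped delete-one
#' jackknife); the 95% CI is computed on the logit scale for boundary
#' safety and clipped to the unit interval; the p-value tests AUC = 0.5
#' by normal approximation.
#'
#' @param scores Numeric marker values.
#' @param labels Group labels; `positive` marks the positive (recurrence)
#'   class. Both classes must be present.
#' @param direction `"larger"` if larger scores indicate the positive
#'   class (e.g. TBRmax, ADCmean here), `"smaller"` otherwise.
#' @param positive Label of the positive class (default `"REC"`).
#' @param metric Optional marker name carried into the result.
#' @return An object of class `roc_result`: `thresholds`,
#'   `sensitivities`, `specificities` (matched sequences over all
#'   distinct cutoffs), `auc`, `auc_se`, `ci95`, `p_value`, `direction`,
#'   plus the oriented scores and labels for downstream comparison.
#' @export
empirical_roc <- function(scores, labels, direction = c("larger", "smaller"),
                          positive = "REC", metric = NULL) {
  direction <- match.arg(direction)
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present to form a ROC curve")
  s <- orient_scores(scores, direction)
  x <- s[pos]; y <- s[!pos]
  sc <- structural_components(x, y)
  auc <- sc$auc
  var_auc <- var0(sc$V10) / length(x) + var0(sc$V01) / length(y)
  se <- sqrt(max(var_auc, 0))

  # curve over all distinct cutoffs (rule: score > t -> positive)
  thr <- c(-Inf, sort(unique(s)))
  sens <- vapply(thr, function(t) mean(x > t), numeric(1))
  spec <- vapply(thr, function(t) mean(y <= t), numeric(1))

  ci <- if (se == 0 || auc %in% c(0, 1)) {
    c(auc, auc)
  } else {
    lg <- stats::qlogis(auc)
    se_lg <- se / (auc * (1 - auc))
    stats::plogis(lg + c(-1, 1) * stats::qnorm(0.975) * se_lg)
  }
  ci <- pmin(pmax(ci, 0), 1)
  p <- if (se == 0) as.numeric(auc == 0.5) else
    2 * stats::pnorm(-abs(auc - 0.5) / se)

  structure(
    list(metric = metric, direction = direction,
         thresholds = if (direction == "larger") thr else -thr,
         sensitivities = sens, specificities = spec,
         auc = auc, auc_se = se, ci95 = ci, p_value = min(p, 1),
         n_pos = length(x), n_neg = length(y),
         scores_oriented = s, positive = pos),
    class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>%s AUC = %.3f +/- %.3f (95%% CI %.3f-%.3f), p = %.3g  [n = %d/%d]\n",
              if (is.null(x$metric)) "" else paste0(" ", x$metric, ":"),
              x$auc, x$auc_se, x$ci95[1], x$ci95[2], x$p_value,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, col = 1, lwd = 2, ...) {
  fpr <- 1 - x$specificities
  ord <- order(fpr, x$sensitivities)
  if (!add) {
    graphics::plot(fpr[ord], x$sensitivities[ord], type = "s",
                   xlim = c(0, 1), ylim = c(0, 1), col = col, lwd = lwd,
                   xlab = "1 - specificity", ylab = "sensitivity", ...)
    graphics::abline(0, 1, lty = 3, col = "grey50")
  } else {
    graphics::lines(fpr[ord], x$sensitivities[ord], type = "s",
                    col = col, lwd = lwd, ...)
  }
  invisible(x)
}

#' Compare two ROC curves (DeLong test)
#'
#' Non-parametric comparison of two AUCs. In paired mode (same subjects
#' scored by two markers) the covariance of the structural components
#' enters the variance of the difference; in unpaired mode the variances
#' add. Two-sided p by normal approximation.
#'
#' @param roc_a,roc_b `roc_result` objects from [empirical_roc()].
#' @param paired TRUE when both curves score the same subjects (the
#'   label vectors must then agree elementwise).
#' @return List with `auc_diff`, `se`, `ci95`, `p_value`, `paired`.
#' @export
compare_roc <- function(roc_a, roc_b, paired = TRUE) {
  stopifnot(inherits(roc_a, "roc_result"), inherits(roc_b, "roc_result"))
  if (paired) {
    if (length(roc_a$positive) != length(roc_b$positive) ||
        !all(roc_a$positive == roc_b$positive))
      stop("paired comparison requires identical subjects and labels")
    pos <- roc_a$positive
    a <- structural_components(roc_a$scores_oriented[pos],
                               roc_a$scores_oriented[!pos])
    b <- structural_components(roc_b$scores_oriented[pos],
                               roc_b$scores_oriented[!pos])
    m <- sum(pos); n <- sum(!pos)
    var_diff <- var0(a$V10 - b$V10) / m + var0(a$V01 - b$V01) / n
  } else {
    var_diff <- roc_a$auc_se^2 + roc_b$auc_se^2
  }
  d <- roc_a$auc - roc_b$auc
  se <- sqrt(max(var_diff, 0))
  p <- if (se == 0) as.numeric(d != 0) else 2 * stats::pnorm(-abs(d) / se)
  if (se == 0 && d == 0) p <- 1
  list(auc_diff = d, se = se,
       ci95 = d + c(-1, 1) * stats::qnorm(0.975) * se,
       p_value = p, paired = paired)
}

#' Youden-optimal cutoff of a ROC curve
#'
#' Maximises J = sensitivity + specificity - 1 over candidate cutoffs
#' (midpoints of consecutive sorted unique scores, plus one candidate
#' below the minimum and one above the maximum). Ties are broken toward
#' higher specificity, then toward the larger cutoff. The cutoff is
#' reported on the original score scale with the rule "score beyond
#' cutoff indicates the positive class".
#'
#' @param roc A `roc_result` from [empirical_roc()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `J`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  s <- roc$scores_oriented
  pos <- roc$positive
  u <- sort(unique(s))
  cand <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            u[length(u)] + 1)
  sens <- vapply(cand, function(t) mean(s[pos] > t), numeric(1))
  spec <- vapply(cand, function(t) mean(s[!pos] <= t), numeric(1))
  J <- sens + spec - 1
  ord <- order(-J, -spec, -cand)
  i <- ord[1]
  cutoff <- if (roc$direction == "larger") cand[i] else -cand[i]
  list(cutoff = cutoff, sensitivity = sens[i], specificity = spec[i],
       J = J[i])
}

#' ROC envelope of the two-threshold OR rule
#'
#' For two markers combined by the step-wise rule "positive when either
#' marker exceeds its threshold", sweeps all pairs of candidate
#' thresholds, collects the achievable (1 - specificity, sensitivity)
#' operating points, and takes their upper-left staircase envelope
#' `f(u) = max (sensitivity achievable at 1 - specificity <= u)`; the AUC
#' is the area under that staircase. For tie-free scores with a
#' non-informative second marker this reduces exactly to the univariate
#' Mann-Whitney AUC of the first marker. The standard error comes from a
#' seeded bootstrap over subjects, stratified by group.
#'
#' @param scores_a,scores_b The two markers (same subjects; larger values
#'   must indicate the positive class — orient beforehand if needed).
#' @param labels Group labels.
#' @param positive Label of the positive class.
#' @param boot Number of bootstrap resamples for the SE (default 2000;
#'   0 disables).
#' @param boot_seed Seed for the bootstrap.
#' @return An object of class `roc_envelope`: `fpr`, `tpr` (envelope
#'   corners), `auc`, `auc_se`, `ci95` (bootstrap percentile).
#' @export
bivariate_roc <- function(scores_a, scores_b, labels, positive = "REC",
                          boot = 2000, boot_seed = 1L) {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(labels))
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("both classes must be present")
  auc <- or_envelope_auc(scores_a, scores_b, pos, keep_curve = TRUE)
  se <- NA_real_; ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(as.integer(boot_seed))
    ip <- which(pos); im <- which(!pos)
    stats_b <- vapply(seq_len(boot), function(b) {
      ii <- c(sample(ip, length(ip), replace = TRUE),
              sample(im, length(im), replace = TRUE))
      or_envelope_auc(scores_a[ii], scores_b[ii], pos[ii])
    }, numeric(1))
    se <- stats::sd(stats_b)
    ci <- unname(stats::quantile(stats_b, c(0.025, 0.975)))
  }
  structure(
    list(fpr = attr(auc, "fpr"), tpr = attr(auc, "tpr"),
         auc = as.numeric(auc), auc_se = se, ci95 = ci,
         n_pos = sum(pos), n_neg = sum(!pos), boot = boot),
    class = "roc_envelope")
}

#' @export
print.roc_envelope <- function(x, ...) {
  cat(sprintf("<roc_envelope> OR-rule envelope AUC = %.3f%s  [n = %d/%d]\n",
              x$auc,
              if (is.na(x$auc_se)) "" else
                sprintf(" +/- %.3f (bootstrap 95%% CI %.3f-%.3f)",
                        x$auc_se, x$ci95[1], x$ci95[2]),
              x$n_pos, x$n_neg))
  invisible(x)
}

# AUC of the upper-left envelope over all OR-rule threshold pairs.
# Counting trick: a subject is negative-called at (t1, t2) iff
# s_a <= t1 AND s_b <= t2, so per-class counts over the threshold grid are
# 2D cumulative sums of the rank-binned contingency table.
or_envelope_auc <- function(sa, sb, pos, keep_curve = FALSE) {
  ua <- c(sort(unique(sa)), Inf)  # thresholds: just-below-each-value + none
  ub <- c(sort(unique(sb)), Inf)
  ia <- findInterval(sa, ua)      # number of ua values <= sa  (bin index)
  ib <- findInterval(sb, ub)
  npos <- sum(pos); nneg <- sum(!pos)
  tab_pos <- matrix(0, length(ua), length(ub))
  tab_neg <- matrix(0, length(ua), length(ub))
  for (i in seq_along(sa)) { # bin counts; (ia, ib) in 1..length(u*)
    if (pos[i]) tab_pos[ia[i], ib[i]] <- tab_pos[ia[i], ib[i]] + 1
    else        tab_neg[ia[i], ib[i]] <- tab_neg[ia[i], ib[i]] + 1
  }
  cum2 <- function(m) apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  neg_called_pos <- cum2(tab_pos)  # positives with sa<=t1 & sb<=t2
  neg_called_neg <- cum2(tab_neg)
  tpr <- 1 - neg_called_pos / npos
  fpr <- 1 - neg_called_neg / nneg
  pts <- cbind(fpr = as.vector(fpr), tpr = as.vector(tpr))
  pts <- rbind(pts, c(0, 0), c(1, 1))
  # upper-left staircase (Pareto frontier)
  ord <- order(pts[, 1], -pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  best <- cummax(pts[, 2])
  keep <- !duplicated(pts[, 1], fromLast = FALSE) # first = highest tpr per fpr
  env <- cbind(pts[keep, 1], best[keep])
  # area under the staircase f(u) = max{tpr achievable with fpr <= u}:
  # left heights, since raising tpr beyond f(u_i) costs fpr = u_(i+1)
  a <- sum(diff(env[, 1]) * env[-nrow(env), 2])
  if (keep_curve) {
    attr(a, "fpr") <- env[, 1]
    attr(a, "tpr") <- env[, 2]
  }
  a
}
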