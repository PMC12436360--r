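# Diagnostic-accuracy statistics: AUROC (Mann-Whitney), Youden cutoff,
# confusion-matrix metrics with exact binomial confidence intervals, the
# DeLong test for paired AUROCs, McNemar's test, five-point reader-score
# dichotomization and model-level reports.

checkTwoClasses <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  labels
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive outscores the negative,
#' ties counting 1/2 — identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @param scores numeric scores (higher = more fracture-like).
#' @param labels binary 0/1 truth; both classes must be present.
#' @return AUROC in [0,1].
#' @export
auroc <- function(scores, labels) {
  labels <- checkTwoClasses(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  r <- rank(scores)    # midranks handle ties
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties 1/2); and symmetrically for negatives.
placements <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), numeric(1))
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUROC with a DeLong-variance confidence interval
#'
#' @inheritParams auroc
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (normal-theory interval clipped to
#'   [0,1]).
#' @export
aurocCi <- function(scores, labels, level = 0.95) {
  labels <- checkTwoClasses(labels)
  pl <- placements(scores, labels)
  se <- sqrt(var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = pl$auc, se = se,
       ci = c(max(0, pl$auc - z * se), min(1, pl$auc + z * se)))
}

#' Youden-index operating point
#'
#' Sweeps the distinct observed scores as thresholds (predict positive when
#' `score >= threshold`) and returns the threshold maximizing
#' J = sensitivity + specificity - 1. Ties are broken toward the lower
#' threshold, i.e. the higher sensitivity, matching the screening intent of
#' ruling fractures out.
#'
#' @inheritParams auroc
#' @return list with `threshold`, `J`, `sensitivity`, `specificity`.
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- checkTwoClasses(labels)
  thr <- sort(unique(scores))
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  sens <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / nPos,
                 numeric(1))
  spec <- vapply(thr, function(t) sum(scores < t & labels == 0L) / nNeg,
                 numeric(1))
  J <- sens + spec - 1
  # lowest threshold among ties; J values within 1e-12 are ties (genuine
  # differences between count ratios are orders of magnitude larger)
  best <- which(J >= max(J) - 1e-12)[1L]
  list(threshold = thr[best], J = J[best],
       sensitivity = sens[best], specificity = spec[best])
}

#' Confusion counts from scores at a threshold
#'
#' @inheritParams auroc
#' @param threshold predict positive when `score >= threshold`.
#' @return a [ConfusionCounts-class].
#' @export
confusionCounts <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  new("ConfusionCounts",
      tp = sum(pred == 1L & labels == 1L), fp = sum(pred == 1L & labels == 0L),
      fn = sum(pred == 0L & labels == 1L), tn = sum(pred == 0L & labels == 0L))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Beta-quantile form of the exact interval; the lower bound is exactly 0
#' when `k = 0` and the upper exactly 1 when `k = n`.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `(low, high)`.
#' @export
clopperPearsonCi <- function(k, n, level = 0.95) {
  if (n < 1L || k < 0L || k > n)
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  a <- (1 - level) / 2
  c(if (k == 0L) 0 else qbeta(a, k, n - k + 1),
    if (k == n) 1 else qbeta(1 - a, k + 1, n - k))
}

#' F1 score from sensitivity and positive predictive value
#'
#' The harmonic mean `2 * ppv * sens / (ppv + sens)`.
#'
#' @param sensitivity,ppv values in [0,1].
#' @return F1 in [0,1] (`NA` when both are 0).
#' @export
f1Score <- function(sensitivity, ppv) {
  ifelse(sensitivity + ppv == 0, NA_real_,
         2 * ppv * sensitivity / (ppv + sensitivity))
}

#' Derived metrics (with exact CIs) from a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and F1, each ratio with its exact binomial 95% CI. A
#' ratio with a zero denominator is reported as `NA` with the reason in the
#' `note` column — never silently as 0. For PPV and NPV a standard
#' logit-transform interval is reported alongside the exact one
#' (`ci_method` flags each), since predictive-value intervals differ across
#' statistical packages.
#'
#' @param counts a [ConfusionCounts-class].
#' @param level confidence level.
#' @return data.frame with columns metric, value, ci_low, ci_high,
#'   ci_method, note.
#' @export
metricsFromConfusion <- function(counts, level = 0.95) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  one <- function(metric, k, n, reason) {
    if (n == 0L)
      return(data.frame(metric = metric, value = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, ci_method = NA_character_,
                        note = reason))
    ci <- clopperPearsonCi(k, n, level)
    data.frame(metric = metric, value = k / n, ci_low = ci[1], ci_high = ci[2],
               ci_method = "clopper_pearson", note = "")
  }
  logitCi <- function(k, n) {
    if (k == 0L || k == n) return(c(NA_real_, NA_real_))
    p <- k / n; se <- sqrt(1 / k + 1 / (n - k))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lg <- log(p / (1 - p)) + c(-z, z) * se
    1 / (1 + exp(-lg))
  }
  out <- rbind(
    one("sensitivity", tp, tp + fn, "no positives in truth (tp + fn = 0)"),
    one("specificity", tn, tn + fp, "no negatives in truth (tn + fp = 0)"),
    one("ppv", tp, tp + fp, "no positive calls (tp + fp = 0)"),
    one("npv", tn, tn + fn, "no negative calls (tn + fn = 0)"))
  for (m in c("ppv", "npv")) {
    k <- if (m == "ppv") tp else tn
    n <- if (m == "ppv") tp + fp else tn + fn
    if (n > 0L) {
      ci <- logitCi(k, n)
      out <- rbind(out, data.frame(metric = paste0(m, "_logit"), value = k / n,
                                   ci_low = ci[1], ci_high = ci[2],
                                   ci_method = "logit", note = ""))
    }
  }
  sens <- out$value[out$metric == "sensitivity"]
  ppv <- out$value[out$metric == "ppv"]
  f1 <- if (is.na(sens) || is.na(ppv)) NA_real_ else f1Score(sens, ppv)
  rbind(out, data.frame(metric = "f1", value = f1, ci_low = NA_real_,
                        ci_high = NA_real_, ci_method = NA_character_,
                        note = if (is.na(f1)) "undefined component" else ""))
}

#' DeLong test for two correlated AUROCs
#'
#' Both score sets must be paired on the identical cases. The variance of
#' the AUC difference comes from the empirical covariance of the per-case
#' placement values; the test is two-sided normal.
#'
#' @param scoresA,scoresB paired score vectors.
#' @param labels shared binary truth.
#' @param level confidence level for the difference CI.
#' @return list with `aucA`, `aucB`, `diff`, `se`, `ci`, `p`.
#' @export
delongTest <- function(scoresA, scoresB, labels, level = 0.95) {
  if (length(scoresA) != length(scoresB) ||
      length(scoresA) != length(labels))
    stop("scoresA, scoresB and labels must have equal length", call. = FALSE)
  labels <- checkTwoClasses(labels)
  pa <- placements(scoresA, labels)
  pb <- placements(scoresB, labels)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  se <- sqrt(max(varDiff, 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) 1 else 2 * pnorm(-abs(d / se))
  list(aucA = pa$auc, aucB = pb$auc, diff = d, se = se,
       ci = c(d - z * se, d + z * se), p = min(1, p))
}

#' McNemar's test from discordant-pair counts
#'
#' Exact two-sided binomial test `p = min(1, 2 P(X <= min(b, c)))` with
#' `X ~ Binomial(b + c, 1/2)` when `b + c < 25`; continuity-corrected
#' chi-square otherwise; `p = 1` when there are no discordant pairs.
#'
#' @param b,c non-negative discordant-pair counts.
#' @return two-sided p value.
#' @export
mcnemarTest <- function(b, c) {
  if (b < 0 || c < 0) stop("counts must be non-negative", call. = FALSE)
  nd <- b + c
  if (nd == 0) return(1)
  if (nd < 25) return(min(1, 2 * pbinom(min(b, c), nd, 0.5)))
  stat <- (abs(b - c) - 1)^2 / nd
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Dichotomize five-point reader scores
#'
#' Scores 1-3 (definitely normal .. indeterminate) map to 0, scores 4-5
#' (probable / definite fracture) to 1.
#'
#' @param scores integer vector with values in 1..5.
#' @return binary integer vector.
#' @export
dichotomizeScores <- function(scores) {
  if (any(!scores %in% 1:5))
    stop("reader scores must lie in 1..5", call. = FALSE)
  as.integer(scores >= 4L)
}

#' Model performance report at the Youden operating point
#'
#' AUROC with DeLong CI, the Youden threshold (from the same scores by
#' default, or a threshold carried over from the tuning set), and the
#' confusion metrics with exact CIs at that operating point.
#'
#' @param scores,labels test scores and truth.
#' @param threshold optional fixed operating point; when `NULL` the Youden
#'   cutoff of these scores is used (the report records which).
#' @return list with `auroc` (from [aurocCi()]), `threshold`,
#'   `thresholdSource`, `counts`, `metrics`.
#' @export
modelReport <- function(scores, labels, threshold = NULL) {
  labels <- checkTwoClasses(labels)
  src <- if (is.null(threshold)) "youden_on_these_scores" else "supplied"
  if (is.null(threshold)) threshold <- youdenCutoff(scores, labels)$threshold
  counts <- confusionCounts(scores, labels, threshold)
  list(auroc = aurocCi(scores, labels), threshold = threshold,
       thresholdSource = src, counts = counts,
       metrics = metricsFromConfusion(counts))
}

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: tp", object@tp, "fp", object@fp,
      "fn", object@fn, "tn", object@tn, "\n")
  invisible(NULL)
})
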