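#' Derive activation labels from normalized activation fractions
#'
#' A peptide counts as activating when its background-corrected, epitope-
#' normalized activation exceeds the threshold (default 0.75, the 75%
#' activation split).
#'
#' @param activation_observed numeric vector of normalized activation
#'   fractions.
#' @param threshold activation threshold (default 0.75); the comparison is
#'   strict (`>`), so exactly-threshold peptides are non-activating.
#' @return logical vector.
#' @export
activation_labels <- function(activation_observed, threshold = 0.75) {
  activation_observed > threshold
}

#' ROC analysis of recognition scores against activation labels
#'
#' Sweeps the classification rule "positive iff score >= threshold" over all
#' realized scores (plus an `Inf` sentinel) and reports the resulting ROC
#' points together with the area under the curve, computed as the
#' Mann-Whitney concordance statistic with half credit for ties.
#'
#' @param score numeric vector of combined TCR recognition scores.
#' @param label logical (or 0/1) vector: `TRUE` for activating peptides.
#' @return an object of class `tcr_roc`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`, and the input
#'   `score`/`label`.
#' @export
roc_curve <- function(score, label) {
  label <- as.logical(label)
  stopifnot(length(score) == length(label), !anyNA(score), !anyNA(label))
  n_pos <- sum(label)
  n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative label",
         call. = FALSE)
  }
  thresholds <- c(Inf, sort(unique(score), decreasing = TRUE))
  pts <- t(vapply(thresholds, function(th) {
    pred <- score >= th
    c(fpr = sum(pred & !label) / n_neg,
      tpr = sum(pred & label) / n_pos)
  }, c(fpr = 0, tpr = 0)))
  # ties-aware Mann-Whitney AUC
  r <- rank(score)
  auc <- (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(points = data.frame(threshold = thresholds,
                                     fpr = pts[, "fpr"], tpr = pts[, "tpr"]),
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 score = score, label = label),
            class = "tcr_roc")
}

#' @export
print.tcr_roc <- function(x, ...) {
  cat(sprintf("ROC: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' @method plot tcr_roc
#' @export
plot.tcr_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "false positive rate", ylab = "true positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc),
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Select a score cutoff from a ROC analysis
#'
#' Under the default `"max-sensitivity"` policy the cutoff is chosen, among
#' the realized thresholds achieving maximal sensitivity (always 1, since a
#' threshold at or below the lowest positive score exists), as the one with
#' maximal specificity, remaining ties broken toward the largest threshold —
#' the most conservative cutoff that still misses no activating peptide.
#'
#' @param roc a [roc_curve()] result.
#' @param policy cutoff policy; only `"max-sensitivity"` is implemented.
#' @return an object of class `tcr_cutoff`: list with `cutoff`,
#'   `sensitivity`, `specificity`, `accuracy` and the confusion counts.
#' @export
select_cutoff <- function(roc, policy = c("max-sensitivity")) {
  policy <- match.arg(policy)
  stopifnot(inherits(roc, "tcr_roc"))
  thr <- sort(unique(roc$score), decreasing = TRUE)
  metrics <- t(vapply(thr, function(th) {
    pred <- roc$score >= th
    tp <- sum(pred & roc$label)
    tn <- sum(!pred & !roc$label)
    c(sens = tp / roc$n_pos, spec = tn / roc$n_neg,
      acc = (tp + tn) / length(roc$label), tp = tp, tn = tn)
  }, c(sens = 0, spec = 0, acc = 0, tp = 0, tn = 0)))
  best_sens <- max(metrics[, "sens"])
  cand <- which(metrics[, "sens"] == best_sens)
  cand <- cand[metrics[cand, "spec"] == max(metrics[cand, "spec"])]
  pick <- cand[which.max(thr[cand])]  # thresholds sorted desc: first is largest
  structure(list(cutoff = unname(thr[pick]),
                 sensitivity = unname(metrics[pick, "sens"]),
                 specificity = unname(metrics[pick, "spec"]),
                 accuracy = unname(metrics[pick, "acc"]),
                 tp = unname(metrics[pick, "tp"]),
                 tn = unname(metrics[pick, "tn"]),
                 n_pos = roc$n_pos, n_neg = roc$n_neg,
                 policy = policy),
            class = "tcr_cutoff")
}

#' @export
print.tcr_cutoff <- function(x, ...) {
  cat(sprintf(
    "Selected cutoff %.4g (policy %s)\n  sensitivity %.3f, specificity %.3f, accuracy %.3f\n",
    x$cutoff, x$policy, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Call peptides cross-reactive at a score cutoff
#'
#' @param scores named numeric vector (or plain numeric) of combined
#'   recognition scores.
#' @param cutoff score cutoff; the call is boundary-inclusive
#'   (`score >= cutoff` is positive).
#' @return logical vector (names preserved).
#' @export
classify <- function(scores, cutoff) {
  if (inherits(cutoff, "tcr_cutoff")) cutoff <- cutoff$cutoff
  scores >= cutoff
}

#' Rank-sum comparison of scores between activating and non-activating groups
#'
#' Convenience wrapper around the two-sided Wilcoxon rank-sum test comparing
#' combined recognition scores between labelled groups.
#'
#' @param score numeric scores.
#' @param label logical activating labels.
#' @return an object of class `htest` from [stats::wilcox.test()].
#' @export
score_group_test <- function(score, label) {
  label <- as.logical(label)
  wilcox.test(score[label], score[!label], exact = FALSE)
}
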