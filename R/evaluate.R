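# Classification metrics and predictor comparison: confusion counts, MCC,
# accuracy, ROC/AROC (Mann-Whitney ties-half convention), the
# MCC-maximizing score sweep, and the DeLong test for paired AROCs.

check_scores_labels <- function(scores, labels, need_both = TRUE) {
  if (length(scores) == 0) stop("empty score vector")
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (need_both && length(unique(labels)) < 2)
    stop("both classes must be present")
  invisible(TRUE)
}

#' Confusion counts at a cutoff
#'
#' Classification rule: score >= cutoff is called positive.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth labels.
#' @param cutoff Decision cutoff.
#' @return List with integer counts \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}.
#' @export
confusion <- function(scores, labels, cutoff) {
  check_scores_labels(scores, labels, need_both = FALSE)
  pred <- scores >= cutoff
  list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
       tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' Matthews correlation coefficient
#'
#' \code{(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))}, defined
#' as 0 when any factor of the denominator is zero.
#'
#' @param counts Confusion counts from [confusion()].
#' @return MCC in [-1, 1].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' Classification accuracy
#'
#' @param counts Confusion counts from [confusion()].
#' @return Percentage in [0, 100].
#' @export
accuracy <- function(counts) {
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total == 0) stop("empty confusion counts")
  100 * (counts$tp + counts$tn) / total
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) computation with half credit for ties;
#' identical to the trapezoidal area of [roc()].
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth labels (both classes required).
#' @return AROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve
#'
#' Threshold sweep over the unique observed scores with tied scores
#' grouped; the trapezoidal area equals the Mann-Whitney U statistic
#' divided by \code{n_pos * n_neg} with ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth labels (both classes required).
#' @return List of class \code{roc_curve} with \code{points} (data frame
#'   \code{fpr}, \code{tpr} from (0,0) to (1,1)) and \code{area}.
#' @export
roc <- function(scores, labels) {
  check_scores_labels(scores, labels)
  np <- sum(labels == 1); nn <- sum(labels == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 1), 0) / np)
  fpr <- c(0, vapply(thr, function(t) sum(scores >= t & labels == 0), 0) / nn)
  area <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), area = area),
            class = "roc_curve")
}

#' Cutoff maximizing the Matthews correlation coefficient
#'
#' Sweeps the unique observed scores as candidate cutoffs (rule: score >=
#' cutoff is positive) and returns the one maximizing MCC, breaking ties
#' toward the smallest cutoff.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary 0/1 truth labels (both classes required).
#' @return List with \code{cutoff} and the achieved \code{mcc}.
#' @export
max_mcc_sweep <- function(scores, labels) {
  check_scores_labels(scores, labels)
  candidates <- sort(unique(scores))
  mccs <- vapply(candidates,
                 function(cut) mcc(confusion(scores, labels, cut)),
                 numeric(1))
  best <- which.max(mccs)  # ties -> smallest cutoff (candidates ascending)
  list(cutoff = candidates[best], mcc = mccs[best])
}

# placement values: for each positive, the fraction of negatives it
# outscores (ties half), and vice versa
placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  np <- length(pos); nn <- length(neg)
  r_all <- rank(c(pos, neg))
  v10 <- (r_all[seq_len(np)] - rank(pos)) / nn
  v01 <- 1 - (r_all[np + seq_len(nn)] - rank(neg)) / np
  list(v10 = v10, v01 = v01)
}

#' DeLong test for the difference of two correlated AROCs
#'
#' Compares two score sets over the same examples using the DeLong
#' variance of paired placement values; returns the AROC difference, its
#' standard error and a two-sided normal p-value.
#'
#' @param scores_a,scores_b Paired prediction scores on the same
#'   examples.
#' @param labels Binary 0/1 truth labels (both classes required).
#' @return List with \code{auc_a}, \code{auc_b}, \code{delta}, \code{se},
#'   \code{p_value}.
#' @export
delta_aroc_test <- function(scores_a, scores_b, labels) {
  check_scores_labels(scores_a, labels)
  if (length(scores_a) != length(scores_b))
    stop("scores_a and scores_b differ in length")
  pa <- placements(scores_a, labels)
  pb <- placements(scores_b, labels)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  np <- length(pa$v10); nn <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / np +
               (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / nn
  delta <- auc_a - auc_b
  se <- sqrt(max(var_delta, 0))
  p <- if (se == 0) {
    if (delta == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(delta / se))
  }
  list(auc_a = auc_a, auc_b = auc_b, delta = delta, se = se, p_value = p)
}
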