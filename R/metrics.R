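#' Confusion counts at a threshold
#'
#' A score is classified suitable (positive) iff `score >= threshold`;
#' ties at the threshold are suitable, which guarantees that binarizing
#' at the minimum-training-presence threshold keeps every training
#' presence suitable.
#'
#' @param scores numeric predicted suitabilities.
#' @param labels binary labels (1 = presence, 0 = absence).
#' @param threshold classification threshold.
#' @return list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  if (!length(scores)) stop("empty input")
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1")
  pred <- scores >= threshold
  list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
       tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1))
}

#' True Skill Statistic
#'
#' `sensitivity + specificity - 1` from confusion counts; requires both
#' classes to be present.
#'
#' @param counts list with `tp`, `fp`, `tn`, `fn` (see [confusion_at()]).
#' @return TSS in `[-1, 1]`.
#' @export
tss_stat <- function(counts) {
  pos <- counts$tp + counts$fn; neg <- counts$tn + counts$fp
  if (pos == 0 || neg == 0) stop("TSS undefined: a class is absent")
  counts$tp / pos + counts$tn / neg - 1
}

#' Area under the ROC curve
#'
#' Mann-Whitney pair-counting estimator via rank sums: the probability
#' that a random presence scores higher than a random absence, ties
#' counting one half.
#'
#' @param scores numeric predicted suitabilities.
#' @param labels binary labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_stat <- function(scores, labels) {
  pos <- labels == 1; neg <- labels == 0
  n1 <- sum(pos); n0 <- sum(neg)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: a class is absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum-sensitivity-plus-specificity threshold (MTSS)
#'
#' Searches the exact candidate set (the unique observed scores) for the
#' threshold maximizing sensitivity + specificity; among ties the
#' smallest threshold is returned.
#'
#' @param scores,labels as in [confusion_at()].
#' @return list with `threshold` and `tss` at that threshold.
#' @export
find_mtss <- function(scores, labels) {
  if (!any(labels == 1) || !any(labels == 0))
    stop("MTSS undefined: a class is absent")
  cand <- sort(unique(scores))
  tss <- vapply(cand, function(t) tss_stat(confusion_at(scores, labels, t)),
                numeric(1))
  best <- which.max(tss)  # which.max returns the first (smallest) maximizer
  list(threshold = cand[best], tss = tss[best])
}

#' Minimum-training-presence threshold (MTP)
#'
#' The smallest predicted suitability at any training presence; the most
#' liberal threshold that still classifies every training presence as
#' suitable.
#'
#' @param presence_scores predicted suitabilities at training presences.
#' @return the threshold.
#' @export
find_mtp <- function(presence_scores) {
  if (!length(presence_scores)) stop("no presence scores")
  min(presence_scores)
}

#' Binarize a suitability surface
#'
#' @param surface a [raster_grid] with values in `[0, 1]`.
#' @param threshold value in `[0, 1]`; cells with `value >= threshold`
#'   become 1, others 0; `NA` propagates.
#' @return a binary [raster_grid].
#' @export
binarize <- function(surface, threshold) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  v <- surface$values
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("surface values must lie in [0, 1]")
  surface$values <- ifelse(is.na(v), NA_real_, as.numeric(v >= threshold))
  surface
}

#' Evaluate scores against labels at a threshold
#'
#' Bundles AUC, sensitivity, specificity and TSS at the supplied
#' threshold into the standard evaluation record.
#'
#' @param scores,labels as in [confusion_at()].
#' @param threshold evaluation threshold (typically the MTSS threshold).
#' @return list with `auc`, `tss`, `sensitivity`, `specificity`,
#'   `threshold`.
#' @export
evaluate_scores <- function(scores, labels, threshold) {
  cm <- confusion_at(scores, labels, threshold)
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  list(auc = auc_stat(scores, labels), tss = sens + spec - 1,
       sensitivity = sens, specificity = spec, threshold = threshold)
}
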