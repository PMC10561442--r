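#' Pixel-level confusion counts
#'
#' Binarises the probability mask at `threshold` and counts true/false
#' positives/negatives against the binary ground truth. A lesion pixel whose
#' prediction is lesion is a true positive; a non-lesion pixel predicted
#' non-lesion is a true negative.
#'
#' @param p Probability mask (any shape).
#' @param t Binary ground-truth mask, same shape.
#' @param threshold Binarisation threshold in (0, 1), default 0.5.
#' @return Named integer vector `tp`, `tn`, `fp`, `fn` (sums to the pixel
#'   count).
#' @examples
#' confusionCounts(c(.9, .9, .8, .6, .2, .1, .1, .2, .3, .4),
#'                 c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0))
#' @export
confusionCounts <- function(p, t, threshold = 0.5) {
  if (length(p) != length(t)) stop("p and t shapes differ", call. = FALSE)
  if (!is.null(dim(p)) && !is.null(dim(t)) && !identical(dim(p), dim(t))) {
    stop("p and t shapes differ", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  pb <- as.numeric(p) >= threshold
  tb <- as.numeric(t) >= 0.5
  c(tp = sum(pb & tb), tn = sum(!pb & !tb),
    fp = sum(pb & !tb), fn = sum(!pb & tb))
}

#' Segmentation metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, precision, F1 and Jaccard similarity:
#' `AC = (TP+TN)/total`, `SE = TP/(TP+FN)`, `SP = TN/(TN+FP)`,
#' `PC = TP/(TP+FP)`, `F1 = 2*PC*SE/(PC+SE)`, `JS = TP/(TP+FP+FN)`.
#' A metric whose denominator is zero is reported as `NaN` with a warning.
#'
#' @param counts Named vector with `tp`, `tn`, `fp`, `fn`.
#' @return Named numeric vector `ac`, `se`, `sp`, `pc`, `f1`, `js`.
#' @export
segmentationMetrics <- function(counts) {
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  total <- tp + tn + fp + fn
  if (total == 0) stop("all confusion counts are zero", call. = FALSE)
  safe <- function(num, den, name) {
    if (den == 0) {
      warning("metric ", name, " undefined (zero denominator)")
      return(NaN)
    }
    num / den
  }
  se <- safe(tp, tp + fn, "SE")
  pc <- safe(tp, tp + fp, "PC")
  f1 <- if (is.nan(se) || is.nan(pc) || pc + se == 0) {
    warning("metric F1 undefined (zero denominator)")
    NaN
  } else {
    2 * pc * se / (pc + se)
  }
  c(ac = (tp + tn) / total,
    se = se,
    sp = safe(tn, tn + fp, "SP"),
    pc = pc,
    f1 = f1,
    js = safe(tp, tp + fp + fn, "JS"))
}

#' ROC curve and AUC over pixel scores
#'
#' Sweeps the binarisation threshold over the sorted unique scores, emitting
#' one (FPR, TPR) point per threshold plus the (0,0) and (1,1) endpoints,
#' and integrates by the trapezoid rule. Tied scores are grouped, so the
#' AUC equals the probability that a random positive pixel outscores a
#' random negative one (ties counted half).
#'
#' @param p Probability scores (vector, array, or list of arrays pooled
#'   together).
#' @param t Binary labels of matching total length.
#' @return List with `curve` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
rocAuc <- function(p, t) {
  if (is.list(p)) p <- unlist(lapply(p, as.numeric))
  if (is.list(t)) t <- unlist(lapply(t, as.numeric))
  p <- as.numeric(p); t <- as.numeric(t) >= 0.5
  if (length(p) != length(t)) stop("p and t lengths differ", call. = FALSE)
  npos <- sum(t); nneg <- sum(!t)
  if (npos == 0 || nneg == 0) {
    stop("ROC needs at least one positive and one negative pixel",
         call. = FALSE)
  }
  o <- order(p, decreasing = TRUE)
  ps <- p[o]; ts <- t[o]
  grp <- cumsum(c(TRUE, diff(ps) != 0))
  ctp <- cumsum(ts); cfp <- cumsum(!ts)
  last <- which(c(diff(grp) != 0, TRUE))
  tpr <- c(0, ctp[last] / npos)
  fpr <- c(0, cfp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(curve = data.frame(threshold = c(Inf, ps[last]), fpr = fpr, tpr = tpr),
       auc = auc)
}
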