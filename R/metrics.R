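#' Confusion counts
#'
#' @param tp,fn,fp,tn non-negative integer counts: true positives, false
#'   negatives (positives called negative), false positives, true negatives.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  v <- c(TP = tp, FN = fn, FP = fp, TN = tn)
  if (anyNA(v) || any(v < 0)) stopf("confusion counts must be non-negative")
  if (any(v != round(v))) stopf("confusion counts must be integers")
  out <- as.list(round(v))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion: TP %d  FN %d | FP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

# tally predictions against truth; both character vectors of positive/negative
tally_confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  confusion_counts(tp = sum(truth == "positive" & predicted == "positive"),
                   fn = sum(truth == "positive" & predicted == "negative"),
                   fp = sum(truth == "negative" & predicted == "positive"),
                   tn = sum(truth == "negative" & predicted == "negative"))
}

#' Sensitivity, specificity, overall accuracy and MCC from confusion counts
#'
#' Sn = 100 TP/(TP+FN), Sp = 100 TN/(TN+FP), Qa = 100 (TP+TN)/N, and the
#' Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' If any factor of the MCC denominator is zero, MCC is reported as 0 and the
#' `mcc_undefined` flag is set (with a warning). Percentages are additionally
#' reported rounded half-up to 2 decimals and MCC to 3, matching the printed
#' precision of published benchmark tables; the unrounded values stay
#' available for arithmetic.
#'
#' @param counts a [confusion_counts()]; requires at least one positive and
#'   one negative.
#' @return An object of class `metrics_report`: list with `counts`, unrounded
#'   `sn`, `sp`, `qa`, `mcc`, a `rounded` sub-list, and `mcc_undefined`.
#' @examples
#' compute_metrics(confusion_counts(tp = 124, fn = 14, fp = 8, tn = 198))
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fn <- counts$FN; fp <- counts$FP; tn <- counts$TN
  if (tp + fn < 1 || tn + fp < 1)
    stopf("need at least one positive and one negative")
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  qa <- 100 * (tp + tn) / (tp + fn + fp + tn)
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc_undefined <- den == 0
  if (mcc_undefined) {
    warnf("an MCC denominator factor is zero; reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  }
  out <- list(counts = counts, sn = sn, sp = sp, qa = qa, mcc = mcc,
              mcc_undefined = mcc_undefined,
              rounded = list(sn = round_half_up(sn, 2), sp = round_half_up(sp, 2),
                             qa = round_half_up(qa, 2),
                             mcc = round_half_up(mcc, 3)))
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Sn %.2f%%  Sp %.2f%%  Qa %.2f%%  MCC %.3f%s\n",
              x$rounded$sn, x$rounded$sp, x$rounded$qa, x$rounded$mcc,
              if (x$mcc_undefined) " (undefined, reported as 0)" else ""))
  print(x$counts)
  invisible(x)
}

#' Recover confusion counts from printed per-class accuracies
#'
#' Published tables print Sn and Sp to two decimals together with the class
#' sizes; the integer counts behind them are TP = round(sn/100 * n_pos) and
#' TN = round(sp/100 * n_neg) (half-up), with FN and FP by complement. This
#' makes a table's Qa/MCC arithmetic checkable without the underlying data.
#' If the re-derived two-decimal Sn/Sp do not reproduce the inputs, the
#' result carries `consistent = FALSE` (with a warning).
#'
#' @param sn_pct,sp_pct printed sensitivity and specificity, in percent.
#' @param n_pos,n_neg class sizes (>= 1).
#' @return A [confusion_counts()] with a `consistent` attribute.
#' @examples
#' recover_confusion(89.86, 96.12, 138, 206)  # TP 124, TN 198
#' @export
recover_confusion <- function(sn_pct, sp_pct, n_pos, n_neg) {
  if (sn_pct < 0 || sn_pct > 100 || sp_pct < 0 || sp_pct > 100)
    stopf("percentages must lie in [0, 100]")
  if (n_pos < 1 || n_neg < 1) stopf("class sizes must be >= 1")
  tp <- round_half_up(sn_pct / 100 * n_pos)
  tn <- round_half_up(sp_pct / 100 * n_neg)
  out <- confusion_counts(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
  ok <- isTRUE(all.equal(round_half_up(100 * tp / n_pos, 2), sn_pct)) &&
        isTRUE(all.equal(round_half_up(100 * tn / n_neg, 2), sp_pct))
  if (!ok) warnf("recovered counts do not reproduce the printed Sn/Sp")
  attr(out, "consistent") <- ok
  out
}

#' Class-mean amino-acid composition
#'
#' For each class, the unweighted mean of the per-peptide AAC vectors: short
#' and long peptides contribute equally, so each class vector still sums
#' to 1. This is the composition-divergence summary used to judge whether
#' composition features can separate anticancer from non-anticancer peptides.
#'
#' @param x a labelled [peptide_set()] with both classes non-empty.
#' @return numeric matrix with rows `positive` and `negative`, 20 residue
#'   columns.
#' @export
class_mean_composition <- function(x) {
  stopifnot(inherits(x, "peptide_set"))
  out <- matrix(NA_real_, 2, 20, dimnames = list(c("positive", "negative"),
                                                 AA_ALPHABET))
  for (cl in rownames(out)) {
    idx <- which(!is.na(x$label) & x$label == cl)
    if (length(idx) == 0) stopf("class '%s' is empty", cl)
    out[cl, ] <- colMeans(encode_aac(x$sequence[idx]))
  }
  out
}
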