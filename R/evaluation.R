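# Classifier evaluation: confusion matrices, Precision / Recall / MCC,
# probability-score threshold sweeps and consensus classification.
#
# Conventions: the positive class is "ACTIVE"; a probability score (PS) is
# the estimated probability of activity and a compound is predicted active
# when PS >= threshold (default 0.5, inclusive).

#' Tally a confusion matrix from labels
#'
#' @param truth,predicted character/factor vectors in
#'   `{"ACTIVE", "INACTIVE"}`, same length.
#' @return list with counts `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    .stopf("truth and predictions have different lengths (%d vs %d)",
           length(truth), length(predicted))
  }
  ok <- c("ACTIVE", "INACTIVE")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    .stopf("labels must be ACTIVE or INACTIVE")
  }
  list(tp = sum(truth == "ACTIVE" & predicted == "ACTIVE"),
       tn = sum(truth == "INACTIVE" & predicted == "INACTIVE"),
       fp = sum(truth == "INACTIVE" & predicted == "ACTIVE"),
       fn = sum(truth == "ACTIVE" & predicted == "INACTIVE"))
}

# MCC with the zero-marginal convention: if any marginal of the confusion
# matrix is zero the coefficient is undefined and reported as 0.
.mcc <- function(tp, tn, fp, fn) {
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  if (any(marg == 0)) {
    return(structure(0, degenerate = TRUE))
  }
  num <- tp * tn - fp * fn
  # product of marginals can overflow the exact-double range for huge counts;
  # accumulate the denominator in log space and clamp rounding noise
  structure(min(1, max(-1, num / exp(0.5 * sum(log(marg))))),
            degenerate = FALSE)
}

#' Precision, Recall and MCC of a confusion matrix
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A metric whose denominator is zero is reported as 0 and flagged in the
#' `degenerate` field.
#'
#' @param cm list with counts `tp`, `tn`, `fp`, `fn`
#'   (see [confusion_matrix()]), or the four counts given separately.
#' @param tp,tn,fp,fn confusion-matrix counts (used when `cm` is missing).
#' @param threshold optional PS threshold annotation carried into the report.
#' @return object of class `vs_eval`: the counts plus `precision`, `recall`,
#'   `mcc`, `threshold` and a `degenerate` flag vector.
#' @examples
#' compute_metrics(tp = 30, fp = 10, fn = 61, tn = 206)
#' @export
compute_metrics <- function(cm, tp, tn, fp, fn, threshold = NA_real_) {
  if (!missing(cm)) {
    tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    .stopf("confusion-matrix entries must be non-negative integers")
  }
  if (sum(counts) == 0) .stopf("empty confusion matrix")
  degenerate <- c(precision = FALSE, recall = FALSE, mcc = FALSE)
  if (tp + fp == 0) {
    precision <- 0; degenerate["precision"] <- TRUE
  } else {
    precision <- tp / (tp + fp)
  }
  if (tp + fn == 0) {
    recall <- 0; degenerate["recall"] <- TRUE
  } else {
    recall <- tp / (tp + fn)
  }
  mcc <- .mcc(tp, tn, fp, fn)
  degenerate["mcc"] <- attr(mcc, "degenerate")
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 precision = precision, recall = recall,
                 mcc = as.numeric(mcc),
                 threshold = threshold, degenerate = degenerate),
            class = "vs_eval")
}

#' @export
print.vs_eval <- function(x, ...) {
  if (!is.na(x$threshold)) {
    cat(sprintf("Evaluation at PS threshold %.2f\n", x$threshold))
  } else {
    cat("Evaluation\n")
  }
  cat(sprintf("  confusion: TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.3f   recall %.3f   MCC %.3f%s\n",
              x$precision, x$recall, x$mcc,
              if (any(x$degenerate)) "   [degenerate metric(s) reported as 0]" else ""))
  invisible(x)
}

# Metrics from probability scores and true labels at one threshold.
.metrics_at <- function(ps, labels, threshold) {
  pred <- ifelse(ps >= threshold, "ACTIVE", "INACTIVE")
  compute_metrics(confusion_matrix(labels, pred), threshold = threshold)
}

#' Evaluate a classifier across probability-score thresholds
#'
#' Classifies each compound active when its PS is at least the threshold and
#' recomputes Precision, Recall and MCC at every threshold (default 0.5 to
#' 0.9 in steps of 0.1). Raising the threshold trades Recall for Precision:
#' the number of predicted positives and the Recall are non-increasing in
#' the threshold.
#'
#' @param ps numeric vector of probability scores in `[0, 1]`.
#' @param labels true labels, `"ACTIVE"`/`"INACTIVE"`, aligned with `ps`.
#' @param thresholds increasing vector of PS thresholds.
#' @return object of class `vs_sweep`: a data.frame with one row per
#'   threshold (counts, precision, recall, mcc, predicted positives) plus
#'   the per-threshold `vs_eval` reports as an attribute.
#' @export
threshold_sweep <- function(ps, labels, thresholds = seq(0.5, 0.9, by = 0.1)) {
  if (length(ps) == 0) .stopf("no predictions supplied")
  if (length(ps) != length(labels)) {
    .stopf("ps and labels have different lengths (%d vs %d)",
           length(ps), length(labels))
  }
  if (any(ps < 0 | ps > 1)) .stopf("probability scores must lie in [0, 1]")
  reports <- lapply(thresholds, function(t) .metrics_at(ps, labels, t))
  df <- data.frame(
    threshold = thresholds,
    tp = vapply(reports, `[[`, 0, "tp"),
    fp = vapply(reports, `[[`, 0, "fp"),
    fn = vapply(reports, `[[`, 0, "fn"),
    tn = vapply(reports, `[[`, 0, "tn"),
    precision = vapply(reports, `[[`, 0, "precision"),
    recall = vapply(reports, `[[`, 0, "recall"),
    mcc = vapply(reports, `[[`, 0, "mcc")
  )
  df$n_predicted_active <- df$tp + df$fp
  structure(df, reports = reports, class = c("vs_sweep", "data.frame"))
}

#' @export
plot.vs_sweep <- function(x, ...) {
  graphics::plot(x$threshold, x$precision, type = "b", pch = 19, ylim = c(0, 1),
                 xlab = "PS threshold", ylab = "score",
                 main = "Precision/Recall vs classification threshold", ...)
  graphics::lines(x$threshold, x$recall, type = "b", pch = 17, lty = 2)
  graphics::lines(x$threshold, x$mcc, type = "b", pch = 15, lty = 3)
  graphics::legend("left", legend = c("precision", "recall", "MCC"),
                   pch = c(19, 17, 15), lty = 1:3, bty = "n")
  invisible(x)
}

#' Consensus classification from several models' probability scores
#'
#' Combines the PS values that independent models assign to a compound.
#' `"mean"` mode calls a compound active when the average PS is at least 0.5;
#' `"unanimity"` mode requires every model's PS to be at least 0.5. A
#' unanimity-active compound is always mean-active.
#'
#' @param ps_per_model numeric vector of one compound's PS values (one per
#'   model), or a matrix with one row per compound and one column per model.
#' @param mode `"mean"` (default) or `"unanimity"`.
#' @param threshold the activity threshold applied to the combined score.
#' @return `"ACTIVE"`/`"INACTIVE"` (vector if a matrix was given).
#' @examples
#' consensus_classify(c(0.9, 0.9, 0.9, 0.3), mode = "mean")       # ACTIVE
#' consensus_classify(c(0.9, 0.9, 0.9, 0.3), mode = "unanimity")  # INACTIVE
#' @export
consensus_classify <- function(ps_per_model, mode = c("mean", "unanimity"),
                               threshold = 0.5) {
  mode <- match.arg(mode)
  if (is.matrix(ps_per_model)) {
    if (nrow(ps_per_model) == 0 || ncol(ps_per_model) == 0) {
      .stopf("no probability scores supplied")
    }
    if (any(ps_per_model < 0 | ps_per_model > 1)) {
      .stopf("probability scores must lie in [0, 1]")
    }
    score <- if (mode == "mean") {
      rowMeans(ps_per_model)
    } else {
      apply(ps_per_model, 1, min)
    }
    return(ifelse(score >= threshold, "ACTIVE", "INACTIVE"))
  }
  if (length(ps_per_model) == 0) .stopf("no probability scores supplied")
  if (any(ps_per_model < 0 | ps_per_model > 1)) {
    .stopf("probability scores must lie in [0, 1]")
  }
  score <- if (mode == "mean") mean(ps_per_model) else min(ps_per_model)
  if (score >= threshold) "ACTIVE" else "INACTIVE"
}
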