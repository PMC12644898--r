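#' Confusion counts and threshold metrics for binary scores
#'
#' Applies the decision rule `score >= threshold` (the study's >= 0.5
#' convention) and reports accuracy, precision, recall (sensitivity),
#' specificity, F1 and the Matthews correlation coefficient, together with
#' threshold-free auROC and auPR. Zero denominators follow the total-report
#' conventions MCC = 0 and F1 = 0 (flagged via the `degenerate` field).
#'
#' @param scores Numeric probabilities or scores.
#' @param labels Binary truth (0/1 or logical).
#' @param threshold Decision threshold; positives are `score >= threshold`.
#' @return A list: `counts` (TP, FP, TN, FN) and `metrics` (accuracy,
#'   precision, recall, specificity, f1, mcc, auroc, aupr, degenerate).
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), all(is.finite(scores)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)

  degenerate <- FALSE
  prec <- if (tp + fp > 0L) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  rec <- if (tp + fn > 0L) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  spec <- if (tn + fp > 0L) tn / (tn + fp) else { degenerate <- TRUE; 0 }
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
    degenerate <- TRUE; 0
  }
  denom <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else {
    degenerate <- TRUE; 0
  }

  if (length(unique(labels)) < 2L) {
    warning("only one class present; auROC/auPR undefined")
    auroc <- NA_real_
    aupr <- NA_real_
  } else {
    cv <- curves(scores, labels)
    auroc <- cv$auroc
    aupr <- cv$aupr
  }
  list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
       metrics = list(accuracy = (tp + tn) / length(labels),
                      precision = prec, recall = rec,
                      specificity = spec, f1 = f1, mcc = mcc,
                      auroc = auroc, aupr = aupr,
                      degenerate = degenerate))
}

#' ROC and precision-recall curves with areas
#'
#' ROC points come from a threshold sweep over the unique scores; auROC is
#' the Mann-Whitney concordance probability (ties count one half). auPR
#' uses step-wise precision integration (no linear interpolation between
#' PR points).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Binary truth (0/1).
#' @return List with `roc` (data.frame fpr, tpr, threshold), `pr`
#'   (data.frame recall, precision, threshold), `auroc`, `aupr`.
#' @export
curves <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L) stop2("both classes must be present")

  # Mann-Whitney with mean ranks handles ties as half-credit exactly
  r <- rank(scores)
  auroc <- (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # group tied scores so each unique score is one threshold
  grp_last <- which(c(s[-1] != s[-length(s)], TRUE))
  ctp <- cumsum(y)[grp_last]
  cfp <- (seq_along(y) - cumsum(y))[grp_last]
  thr <- s[grp_last]

  roc <- data.frame(fpr = c(0, cfp / nn), tpr = c(0, ctp / np),
                    threshold = c(Inf, thr))
  prec <- ctp / (ctp + cfp)
  rec <- ctp / np
  pr <- data.frame(recall = rec, precision = prec, threshold = thr)
  # step-wise integration: precision held at each achieved point
  d_rec <- diff(c(0, rec))
  aupr <- sum(d_rec * prec)

  list(roc = roc, pr = pr, auroc = auroc, aupr = aupr)
}

#' Pearson correlation and RMSE for regression predictions
#'
#' @param predicted,observed Equal-length numeric vectors (n >= 2).
#' @return List with `pearson_r` (NA with a warning when either vector has
#'   zero variance) and `rmse`.
#' @export
regression_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  rmse <- sqrt(mean((predicted - observed)^2))
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero variance; Pearson correlation undefined")
    r <- NA_real_
  } else {
    r <- stats::cor(predicted, observed)
  }
  list(pearson_r = r, rmse = rmse)
}

#' Write a metrics report to JSON and curve point tables to TSV
#'
#' @param report List from [confusion_metrics()].
#' @param path Output JSON path.
#' @export
write_metrics <- function(report, path) {
  jsonlite::write_json(c(as.list(report$counts), report$metrics),
                       path, auto_unbox = TRUE, digits = NA)
}
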