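# Uncertain-aware three-class evaluation: 3x2 confusion tables, metrics
# excluding abstentions, discovery rates, rank-based ROC-AUC and
# probability-distribution summaries by five-tier label.

.pred_levels <- c("benign", "uncertain", "pathogenic")
.true_levels <- c("benign", "pathogenic")

#' Build a 3x2 confusion table
#'
#' Tallies three-class calls (benign / uncertain / pathogenic) against
#' binary truth labels.
#'
#' @param calls character vector of calls.
#' @param labels character vector of true labels (`benign`/`pathogenic`),
#'   same length.
#' @return 3x2 integer matrix of class `confusion_3x2`, rows = predicted,
#'   columns = true.
#' @export
build_confusion <- function(calls, labels) {
  if (length(calls) != length(labels)) {
    stop("calls and labels differ in length")
  }
  if (!all(calls %in% .pred_levels)) stop("calls outside {benign, uncertain, pathogenic}")
  if (!all(labels %in% .true_levels)) stop("labels outside {benign, pathogenic}")
  ct <- table(factor(calls, levels = .pred_levels),
              factor(labels, levels = .true_levels))
  out <- matrix(as.integer(ct), nrow = 3, dimnames = dimnames(ct))
  class(out) <- c("confusion_3x2", class(out))
  out
}

#' Construct a 3x2 confusion table from the six cell counts
#'
#' Convenience constructor for published confusion tables. Counts are given
#' by true class: for each of the benign and pathogenic columns, the number
#' of records called benign, pathogenic and uncertain.
#'
#' @param benign_col,pathogenic_col length-3 integer vectors of counts
#'   (called-benign, called-pathogenic, called-uncertain) within the true
#'   benign and true pathogenic columns respectively.
#' @return `confusion_3x2` matrix.
#' @examples
#' # a published loss-model test table: 1062/6/221 true-benign,
#' # 11/413/116 true-pathogenic
#' ct <- confusion_from_counts(c(1062, 6, 221), c(11, 413, 116))
#' @export
confusion_from_counts <- function(benign_col, pathogenic_col) {
  stopifnot(length(benign_col) == 3L, length(pathogenic_col) == 3L,
            all(benign_col >= 0), all(pathogenic_col >= 0))
  out <- matrix(as.integer(c(benign_col[1], pathogenic_col[1],
                             benign_col[2], pathogenic_col[2],
                             benign_col[3], pathogenic_col[3])),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("benign", "pathogenic", "uncertain"),
                                .true_levels))
  out <- out[.pred_levels, , drop = FALSE]
  class(out) <- c("confusion_3x2", class(out))
  out
}

.safe_ratio <- function(num, den) if (den == 0) NA_real_ else num / den

#' Metrics from a 3x2 confusion table
#'
#' Two denominator conventions coexist and are reported as separate fields:
#' accuracy, sensitivity, specificity, precision and MCC are computed on
#' definite calls only (uncertain-significance calls excluded), while the
#' per-class discovery rates divide the correctly called count by the full
#' column total including abstentions. `included_fraction` is the share of
#' records receiving a definite call. Metrics with a zero denominator are
#' reported as `NA` (flagged in `undefined`), never as 0.
#'
#' @param ct a `confusion_3x2` matrix (see [build_confusion()]).
#' @return list of class `metrics_report` with fields `included_fraction`,
#'   `uncertain_fraction`, `accuracy`, `sensitivity`, `specificity`,
#'   `precision_benign`, `precision_pathogenic`, `mcc`, `discovery_benign`,
#'   `discovery_pathogenic`, `n_total`, `undefined`.
#' @export
metrics_from_confusion <- function(ct) {
  stopifnot(inherits(ct, "confusion_3x2"))
  tp <- ct["pathogenic", "pathogenic"]
  tn <- ct["benign", "benign"]
  fp <- ct["pathogenic", "benign"]
  fn <- ct["benign", "pathogenic"]
  unc_b <- ct["uncertain", "benign"]
  unc_p <- ct["uncertain", "pathogenic"]
  total <- tp + tn + fp + fn + unc_b + unc_p
  included <- tp + tn + fp + fn

  mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den

  out <- list(
    included_fraction = .safe_ratio(included, total),
    uncertain_fraction = .safe_ratio(unc_b + unc_p, total),
    accuracy = .safe_ratio(tp + tn, included),
    sensitivity = .safe_ratio(tp, tp + fn),
    specificity = .safe_ratio(tn, tn + fp),
    precision_benign = .safe_ratio(tn, tn + fn),
    precision_pathogenic = .safe_ratio(tp, tp + fp),
    mcc = mcc,
    discovery_benign = .safe_ratio(tn, tn + fp + unc_b),
    discovery_pathogenic = .safe_ratio(tp, tp + fn + unc_p),
    n_total = total
  )
  out$undefined <- names(out)[vapply(out, function(v) is.na(v), logical(1))]
  class(out) <- "metrics_report"
  out
}

#' @method print metrics_report
#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat("Three-class evaluation (n = ", x$n_total, ")\n", sep = "")
  cat("  included: ", pct(x$included_fraction),
      "  (uncertain: ", pct(x$uncertain_fraction), ")\n", sep = "")
  cat("  accuracy: ", pct(x$accuracy),
      "  sensitivity: ", pct(x$sensitivity),
      "  specificity: ", pct(x$specificity), "\n", sep = "")
  cat("  precision benign/pathogenic: ", pct(x$precision_benign), " / ",
      pct(x$precision_pathogenic), "\n", sep = "")
  cat("  discovery benign/pathogenic: ", pct(x$discovery_benign), " / ",
      pct(x$discovery_pathogenic), "\n", sep = "")
  cat("  MCC: ", if (is.na(x$mcc)) "undefined" else sprintf("%.4f", x$mcc),
      "\n", sep = "")
  invisible(x)
}

#' Rank-based ROC-AUC
#'
#' Mann-Whitney formulation: the probability that a randomly chosen
#' pathogenic record receives a higher score than a randomly chosen benign
#' one, with ties sharing rank (counted 1/2). Invariant under any strictly
#' monotone transform of the scores.
#'
#' @param probabilities numeric scores.
#' @param labels binary truth (`benign`/`pathogenic` or 0/1).
#' @param calls optional three-class calls; when supplied, records called
#'   uncertain are excluded before computing the AUC (the
#'   "definite-calls-only" view).
#' @return AUC in \[0, 1\], or `NA` (with a warning) if only one class is
#'   present.
#' @export
roc_auc <- function(probabilities, labels, calls = NULL) {
  y <- .label01(labels)
  if (!is.null(calls)) {
    keep <- calls != "uncertain"
    probabilities <- probabilities[keep]
    y <- y[keep]
  }
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Probability distribution summaries by five-tier label
#'
#' For each five-tier label present, summarizes the predicted pathogenicity
#' probabilities: count, quartiles, and the fractions falling in the
#' pathogenic (`p >= p_ct`) and benign (`p <= 1 - p_ct`) call regions. This
#' is the tabular counterpart of a per-label strip plot of predictions.
#'
#' @param probabilities numeric predictions in \[0, 1\].
#' @param five_tier_labels character labels from [five_tier_labels()].
#' @param p_ct probability threshold used for the call-region fractions.
#' @return data.frame, one row per label present (empty groups omitted).
#' @export
probability_distribution_by_label <- function(probabilities, five_tier_labels,
                                              p_ct = 0.95) {
  stopifnot(length(probabilities) == length(five_tier_labels))
  bad <- setdiff(unique(five_tier_labels), .five_tier_labels)
  if (length(bad) > 0L) stop("unknown label(s): ", paste(bad, collapse = ", "))
  present <- intersect(.five_tier_labels, unique(five_tier_labels))
  rows <- lapply(present, function(lab) {
    p <- probabilities[five_tier_labels == lab]
    q <- stats::quantile(p, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(label = lab, n = length(p), mean = mean(p),
               q25 = q[1], median = q[2], q75 = q[3],
               frac_pathogenic_call = mean(p >= p_ct),
               frac_benign_call = mean(p <= 1 - p_ct))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
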