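# Dataset preprocessing: size and multiplicity filters, label binarization
# and stratified partitioning of labeled CNV sets.

#' Filter CNVs by length
#'
#' Keeps CNVs with `min_exclusive < length < max_exclusive` (strict
#' inequalities; length = end - start). CNVs at or above the upper bound are
#' returned separately as the long-CNV evaluation set rather than dropped,
#' since overlong variants are almost always pathogenic and would distort
#' training. CNVs at or below the lower bound are discarded.
#'
#' @param records CNV data.frame (`chrom`, `start`, `end`, ...).
#' @param min_exclusive lower length bound in bp, exclusive (default 1000).
#' @param max_exclusive upper length bound in bp, exclusive (default 5e6).
#' @return list with elements `kept` (training-regime records) and
#'   `oversized` (length >= `max_exclusive`).
#' @export
filter_by_size <- function(records, min_exclusive = 1000, max_exclusive = 5e6) {
  records <- validate_intervals(records, "CNV")
  len <- records$end - records$start
  list(
    kept = records[len > min_exclusive & len < max_exclusive, , drop = FALSE],
    oversized = records[len >= max_exclusive, , drop = FALSE]
  )
}

#' Split CNVs by copy-number multiplicity
#'
#' Canonical copy numbers are 1 for losses (heterozygous deletion) and 3 for
#' gains (single duplication); these form the training regime. All other
#' multiplicities (e.g. 0, homozygous deletion; 4, double duplication) are
#' routed to a separate evaluation set. Records without a multiplicity
#' annotation are treated as canonical, since most public CNV records omit
#' it.
#'
#' @param records CNV data.frame with a `cnv_type` column and optionally a
#'   `multiplicity` column.
#' @return list with elements `canonical` and `multiple`.
#' @export
filter_by_multiplicity <- function(records) {
  if (is.null(records$cnv_type)) stop("records lack a 'cnv_type' column")
  if (is.null(records$multiplicity)) {
    return(list(canonical = records,
                multiple = records[0, , drop = FALSE]))
  }
  m <- records$multiplicity
  expected <- ifelse(records$cnv_type == "loss", 1, 3)
  canonical <- is.na(m) | m == expected
  list(
    canonical = records[canonical, , drop = FALSE],
    multiple = records[!canonical, , drop = FALSE]
  )
}

#' Binarize five-tier labels
#'
#' Retains records labeled `benign` or `pathogenic` for model training and
#' basic testing; records with intermediate labels (`likely_benign`,
#' `uncertain`, `likely_pathogenic`) are returned separately for five-tier
#' evaluation of the trained model only.
#'
#' @param records CNV data.frame with a `label` column drawn from
#'   [five_tier_labels()].
#' @return list with elements `binary` and `other`.
#' @export
binarize_labels <- function(records) {
  if (nrow(records) == 0L) {
    return(list(binary = records, other = records))
  }
  if (is.null(records$label)) stop("records lack a 'label' column")
  bad <- setdiff(unique(records$label[!is.na(records$label)]),
                 .five_tier_labels)
  if (length(bad) > 0L) {
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  }
  is_binary <- records$label %in% c("benign", "pathogenic")
  list(
    binary = records[is_binary, , drop = FALSE],
    other = records[!is_binary, , drop = FALSE]
  )
}

#' Stratified train / validation / test split
#'
#' Deterministic label-stratified random partition of a labeled record
#' table. Within each label stratum, records are shuffled with the given
#' seed and allocated to the three partitions by the requested fractions, so
#' class proportions are preserved to within one record per stratum.
#'
#' @param records data.frame with a `label` column.
#' @param fractions numeric length-3 vector (train, validation, test)
#'   summing to 1; default `c(0.70, 0.15, 0.15)`.
#' @param seed integer RNG seed.
#' @return list of data.frames `train`, `validation`, `test` (disjoint,
#'   exhaustive).
#' @export
split_train_val_test <- function(records, fractions = c(0.70, 0.15, 0.15),
                                 seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  if (is.null(records$label)) stop("records lack a 'label' column")
  n <- nrow(records)
  part <- character(n)
  set.seed(seed)
  for (lab in unique(records$label)) {
    idx <- which(records$label == lab)
    idx <- sample(idx)
    k <- length(idx)
    n_train <- round(fractions[1] * k)
    n_val <- round(fractions[2] * k)
    n_val <- min(n_val, k - n_train)
    part[idx[seq_len(n_train)]] <- "train"
    if (n_val > 0) part[idx[n_train + seq_len(n_val)]] <- "validation"
    rest <- idx[setdiff(seq_len(k), seq_len(n_train + n_val))]
    part[rest] <- "test"
  }
  list(
    train = records[part == "train", , drop = FALSE],
    validation = records[part == "validation", , drop = FALSE],
    test = records[part == "test", , drop = FALSE]
  )
}
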