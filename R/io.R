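# Readers and writers for the plain-text interchange formats: BED-like
# element tracks, TSV/BED/VCF CNV call sets, TSV feature matrices and
# prediction tables, JSON metrics.
#
# Coordinates on disk follow each format's convention: BED and the TSV
# dialect are 0-based half-open and pass through unchanged; VCF POS is
# 1-based and is converted by subtracting 1.

.file_header <- function(kind) {
  ver <- tryCatch(as.character(utils::packageVersion("cnvimpact")),
                  error = function(e) "dev")
  sprintf("# cnvimpact %s %s", ver, kind)
}

.write_table <- function(df, path, kind) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header(kind), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a categorized element track file
#'
#' BED3+ dialect: tab-separated, columns chrom, start, end, category and an
#' optional integer dosage-sensitivity score in column 5; lines starting
#' with `#` are comments. Coordinates are 0-based half-open.
#'
#' @param path file path.
#' @return data.frame with columns `chrom`, `start`, `end`, `category` and,
#'   when present, `score`.
#' @export
read_tracks <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("track file needs >= 4 columns (chrom, start, end, category)")
  names(df)[1:4] <- c("chrom", "start", "end", "category")
  if (ncol(df) >= 5L) names(df)[5] <- "score"
  validate_intervals(df, "track element")
  df
}

#' Read a CNV call set
#'
#' Three dialects:
#' * `tsv` — header line with columns `chrom`, `start`, `end`, `cnv_type`
#'   and optionally `multiplicity`, `label`, `source_id` (0-based
#'   half-open).
#' * `bed` — headerless BED-like: chrom, start, end, cnv_type
#'   \[, multiplicity \[, label\]\].
#' * `vcf` — VCF 4.x; records with `SVTYPE` DEL or DUP and an `END` INFO
#'   field are mapped to loss/gain with `start = POS - 1`, `end = END`.
#'   Records with other SVTYPEs are skipped with a warning; symbolic SV
#'   records lacking END are rejected with a warning listing the line.
#'
#' @param path file path.
#' @param format `"tsv"`, `"bed"` or `"vcf"` (default guessed from the
#'   extension).
#' @return validated CNV data.frame (`chrom`, `start`, `end`, `cnv_type`,
#'   `multiplicity`, `label`, `source_id`).
#' @export
read_cnvs <- function(path, format = c("auto", "tsv", "bed", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf"
              else if (grepl("\\.bed$", path)) "bed" else "tsv"
  }
  df <- switch(format,
    tsv = {
      x <- utils::read.table(path, sep = "\t", comment.char = "#",
                             header = TRUE, stringsAsFactors = FALSE)
      req <- c("chrom", "start", "end", "cnv_type")
      miss <- setdiff(req, names(x))
      if (length(miss)) stop("CNV TSV lacks column(s): ",
                             paste(miss, collapse = ", "))
      x
    },
    bed = {
      x <- utils::read.table(path, sep = "\t", comment.char = "#",
                             header = FALSE, fill = TRUE, na.strings = c("NA", ""),
                             stringsAsFactors = FALSE)
      if (ncol(x) < 4L) stop("CNV BED needs >= 4 columns")
      names(x)[1:4] <- c("chrom", "start", "end", "cnv_type")
      if (ncol(x) >= 5L) names(x)[5] <- "multiplicity"
      if (ncol(x) >= 6L) names(x)[6] <- "label"
      x
    },
    vcf = .read_cnvs_vcf(path)
  )
  df$cnv_type <- normalize_cnv_type(df$cnv_type)
  if (is.null(df$multiplicity)) df$multiplicity <- NA_integer_
  if (is.null(df$label)) df$label <- NA_character_
  if (is.null(df$source_id)) df$source_id <- NA_character_
  auto_id <- sprintf("%s:%d-%d:%s", df$chrom, as.integer(df$start),
                     as.integer(df$end), df$cnv_type)
  df$source_id <- ifelse(is.na(df$source_id), auto_id, df$source_id)
  validate_intervals(df, "CNV")
  df[, c("chrom", "start", "end", "cnv_type", "multiplicity", "label",
         "source_id")]
}

.read_cnvs_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]
  pos <- as.numeric(fix[, "POS"])
  id <- fix[, "ID"]
  svtype <- toupper(vcfR::extract.info(vcf, "SVTYPE"))
  end <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "END")))

  keep_type <- svtype %in% c("DEL", "DUP")
  if (any(!keep_type)) {
    warning("skipping ", sum(!keep_type),
            " VCF record(s) with SVTYPE outside {DEL, DUP}")
  }
  no_end <- keep_type & is.na(end)
  if (any(no_end)) {
    warning("rejecting ", sum(no_end),
            " DEL/DUP record(s) lacking INFO/END: ",
            paste(utils::head(id[no_end], 5), collapse = ", "))
  }
  keep <- keep_type & !no_end
  data.frame(
    chrom = chrom[keep],
    start = pos[keep] - 1,  # VCF POS is 1-based
    end = end[keep],
    cnv_type = ifelse(svtype[keep] == "DEL", "loss", "gain"),
    source_id = ifelse(is.na(id[keep]) | id[keep] == ".", NA_character_,
                       id[keep]),
    stringsAsFactors = FALSE
  )
}

#' Write / read a feature matrix TSV
#'
#' One row per CNV, columns = schema attributes in stable order, plus any
#' leading identifier/label columns supplied. The first line is a `#`
#' comment carrying the tool version.
#'
#' @param features data.frame to write.
#' @param path file path.
#' @return `write_feature_matrix`: the path, invisibly;
#'   `read_feature_matrix`: the data.frame.
#' @export
write_feature_matrix <- function(features, path) {
  .write_table(features, path, "feature-matrix")
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  utils::read.table(path, sep = "\t", comment.char = "#", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write a predictions table
#'
#' TSV with columns `source_id`, `probability`, `call`, `p_ct`; probability
#' printed with fixed 6-digit formatting so output is byte-stable.
#'
#' @param source_id record identifiers.
#' @param probability pathogenicity probabilities.
#' @param call three-class calls.
#' @param p_ct threshold used.
#' @param path file path.
#' @export
write_predictions <- function(source_id, probability, call, p_ct, path) {
  df <- data.frame(source_id = source_id,
                   probability = sprintf("%.6f", probability),
                   call = call, p_ct = p_ct)
  .write_table(df, path, "predictions")
}

#' Write a metrics report as JSON
#'
#' Undefined metrics (zero denominators) are serialized as JSON nulls.
#'
#' @param report a `metrics_report`.
#' @param path file path.
#' @export
write_metrics_json <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  x <- unclass(report)
  x[] <- lapply(x, function(v) if (is.numeric(v) && anyNA(v)) NULL else v)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' Write an element track table as BED4+
#'
#' @param tracks long-format track data.frame (`chrom`, `start`, `end`,
#'   `category`, optional `score`).
#' @param path file path.
#' @export
write_tracks <- function(tracks, path) {
  cols <- intersect(c("chrom", "start", "end", "category", "score"),
                    names(tracks))
  df <- tracks[, cols, drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.file_header("tracks"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a CNV table as TSV
#'
#' @param cnvs CNV data.frame.
#' @param path file path.
#' @export
write_cnvs <- function(cnvs, path) {
  cols <- intersect(c("chrom", "start", "end", "cnv_type", "multiplicity",
                      "label", "source_id"), names(cnvs))
  .write_table(cnvs[, cols, drop = FALSE], path, "cnvs")
}
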