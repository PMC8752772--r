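# CNV annotation: count-based feature vectors by interval overlap.
#
# All coordinates are 0-based half-open ([start, end), BED convention)
# throughout the package. Conversion to the 1-based closed convention of
# IRanges happens only inside these helpers.

#' Validate a table of genomic intervals
#'
#' Checks that `chrom`, `start` and `end` columns exist, coordinates are
#' non-negative and every interval satisfies start < end under the 0-based
#' half-open convention.
#'
#' @param df data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages (e.g. "CNV", "track element").
#' @return The input, invisibly, with `start`/`end` coerced to numeric.
#' @export
validate_intervals <- function(df, what = "interval") {
  req <- c("chrom", "start", "end")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop(what, " table lacks column(s): ", paste(miss, collapse = ", "))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$start >= df$end)
  if (length(bad) > 0L) {
    id <- if (!is.null(df$source_id)) df$source_id[bad[1L]] else bad[1L]
    stop("invalid ", what, " (need 0 <= start < end) at record ", id,
         ": ", df$chrom[bad[1L]], ":", df$start[bad[1L]], "-", df$end[bad[1L]])
  }
  invisible(df)
}

# data.frame (0-based half-open) -> GRanges (1-based closed)
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

#' Count track elements overlapping each query interval
#'
#' Any-overlap semantics: an element is counted when it shares at least one
#' base with the query on the same chromosome, and each element is counted at
#' most once per query. No minimum reciprocal-overlap fraction is applied.
#'
#' @param query data.frame of intervals (`chrom`, `start`, `end`; 0-based
#'   half-open).
#' @param track data.frame of element intervals in the same convention; may
#'   have zero rows.
#' @return Integer vector, one count per query row.
#' @examples
#' cnv <- data.frame(chrom = "chr1", start = 100, end = 200)
#' trk <- data.frame(chrom = c("chr1", "chr2"), start = 150, end = 160)
#' count_overlapping_elements(cnv, trk)  # 1: the chr2 element never overlaps
#' @export
count_overlapping_elements <- function(query, track) {
  query <- validate_intervals(query, "query interval")
  if (is.null(track) || nrow(track) == 0L) {
    return(integer(nrow(query)))
  }
  track <- validate_intervals(track, "track element")
  # disjoint chromosome sets are a legitimate zero-overlap case, not a
  # malformed query; silence the seqlevel mismatch warning
  suppressWarnings(
    GenomicRanges::countOverlaps(.as_granges(query), .as_granges(track))
  )
}

#' Filter a dosage-sensitivity track by evidence score
#'
#' Keeps exactly the elements whose integer evidence score equals
#' `required_score` (default 3, "sufficient evidence" on the
#' haploinsufficiency / triplosensitivity scale). Equality, not `>=`: higher
#' numeric codes on that scale (e.g. 40, "dosage-sensitivity unlikely") do
#' not denote stronger evidence.
#'
#' @param track data.frame with interval columns and an integer `score`
#'   column; every element must be scored.
#' @param required_score integer score to retain (default 3).
#' @return The filtered track (same columns).
#' @export
filter_dosage_sensitive <- function(track, required_score = 3L) {
  if (nrow(track) == 0L) return(track)
  if (is.null(track$score) || anyNA(suppressWarnings(as.numeric(track$score)))) {
    stop("dosage-sensitivity track has missing or non-numeric scores")
  }
  track[as.numeric(track$score) == required_score, , drop = FALSE]
}

#' Build an element catalog from a track table
#'
#' Splits a long-format track table (one row per element, with a `category`
#' column) into per-category tracks, applies the score filter to
#' dosage-sensitivity categories, and drops categories outside the schema
#' vocabulary with a warning.
#'
#' @param tracks data.frame with columns `chrom`, `start`, `end`, `category`
#'   and, for dosage categories, `score`.
#' @param required_score evidence score retained for dosage categories.
#' @param complete if TRUE, vocabulary categories absent from `tracks` are
#'   added as empty tracks (useful for sparse toy genomes where a category
#'   happens to have no elements).
#' @return An object of class `element_catalog`: a named list of per-category
#'   interval data.frames.
#' @export
element_catalog <- function(tracks, required_score = 3L, complete = FALSE) {
  validate_intervals(tracks, "track element")
  if (is.null(tracks$category)) stop("track table lacks a 'category' column")
  vocab <- union(.loss_attributes, .gain_attributes)
  unknown <- setdiff(unique(tracks$category), vocab)
  if (length(unknown) > 0L) {
    warning("ignoring track categories outside the schema vocabulary: ",
            paste(unknown, collapse = ", "))
    tracks <- tracks[tracks$category %in% vocab, , drop = FALSE]
  }
  cat_list <- split(tracks, tracks$category)
  for (nm in intersect(names(cat_list), .dosage_categories)) {
    cat_list[[nm]] <- filter_dosage_sensitive(cat_list[[nm]], required_score)
  }
  if (complete) {
    empty <- tracks[0, c("chrom", "start", "end"), drop = FALSE]
    for (nm in setdiff(vocab, names(cat_list))) cat_list[[nm]] <- empty
  }
  structure(cat_list, class = "element_catalog")
}

#' Annotate CNVs with element overlap counts
#'
#' Produces the count feature matrix for a set of CNVs of one type: one
#' column per schema attribute, one row per CNV, each cell the number of
#' elements of that category overlapping the CNV by at least one base.
#' A category entirely absent from the toy/real genome may be supplied as an
#' empty track; a category missing from the catalog altogether is a
#' configuration error.
#'
#' @param cnvs data.frame of CNVs (`chrom`, `start`, `end`), all of
#'   `cnv_type`.
#' @param catalog an [element_catalog()] (or named list of interval
#'   data.frames) covering every schema category for `cnv_type`. Categories
#'   not present at all are treated as missing unless `missing_as_empty`.
#' @param cnv_type `"loss"` or `"gain"`; chooses the 19- or 18-attribute
#'   schema.
#' @param missing_as_empty if TRUE, schema categories absent from the catalog
#'   count as empty tracks (all zeros) instead of raising an error.
#' @return data.frame of non-negative integer counts, columns in schema
#'   order.
#' @export
annotate_cnv <- function(cnvs, catalog, cnv_type = c("loss", "gain"),
                         missing_as_empty = FALSE) {
  cnv_type <- match.arg(cnv_type)
  cnvs <- validate_intervals(cnvs, "CNV")
  schema <- annotation_schema(cnv_type)
  absent <- setdiff(schema, names(catalog))
  if (length(absent) > 0L && !missing_as_empty) {
    stop("catalog lacks required categories for ", cnv_type, " schema: ",
         paste(absent, collapse = ", "))
  }
  counts <- lapply(schema, function(nm) {
    count_overlapping_elements(cnvs, catalog[[nm]])
  })
  names(counts) <- schema
  out <- as.data.frame(counts, optional = TRUE)
  rownames(out) <- NULL
  out
}

#' Tile a genome into fixed-length CNV-like windows
#'
#' Splits each chromosome into consecutive non-overlapping windows of
#' `tile_length` bases; a trailing partial window is kept so every base is
#' covered exactly once. For each window, one loss and one gain record are
#' emitted, so a trained model pair can score pathogenicity potential
#' genome-wide (the 1-Mbp default mirrors whole-genome tiling annotation).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param tile_length window length in bp (default 1e6).
#' @return data.frame with columns `chrom`, `start`, `end`, `cnv_type`,
#'   `source_id`; two rows (loss + gain) per tile, ordered by chromosome then
#'   start.
#' @export
tile_genome <- function(chrom_sizes, tile_length = 1e6) {
  if (length(tile_length) != 1L || is.na(tile_length) || tile_length < 1) {
    stop("tile_length must be a positive integer")
  }
  if (is.null(names(chrom_sizes)) || any(chrom_sizes < 1)) {
    stop("chrom_sizes must be a named vector of positive lengths")
  }
  per_chrom <- lapply(names(chrom_sizes), function(chr) {
    len <- chrom_sizes[[chr]]
    starts <- seq(0, len - 1, by = tile_length)
    ends <- pmin(starts + tile_length, len)
    data.frame(chrom = chr, start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, per_chrom)
  out <- rbind(
    data.frame(tiles, cnv_type = "loss", stringsAsFactors = FALSE),
    data.frame(tiles, cnv_type = "gain", stringsAsFactors = FALSE)
  )
  out <- out[order(out$chrom, out$start, out$cnv_type), , drop = FALSE]
  out$source_id <- sprintf("%s:%d-%d:%s", out$chrom, as.integer(out$start),
                           as.integer(out$end), out$cnv_type)
  rownames(out) <- NULL
  out
}
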