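# Download-free fixtures: labeled count datasets matched to published
# per-class moments, and toy genomes with element tracks + CNVs that
# exercise the full annotate -> train -> predict -> explain path.

# Per-attribute count moments (mean, sd) of benign and pathogenic variants,
# separately for loss and gain CNVs, taken from the descriptive statistics
# of the ClinVar-derived training data. These defaults define the synthetic
# study conditions.
.count_moments <- local({
  # attribute, loss: b_mean b_sd p_mean p_sd, gain: b_mean b_sd p_mean p_sd
  m <- rbind(
    c("overlapped_gencode_elements", 4.11, 10.49, 56.43, 54.73,  9.46, 18.39, 80.30, 65.18),
    c("protein_coding_genes",        1.41,  3.29, 19.28, 19.49,  2.61,  4.60, 28.17, 25.22),
    c("pseudogenes",                 1.42,  5.46, 11.30, 15.62,  3.97, 10.85, 17.34, 19.58),
    c("micro_rna",                   0.07,  0.45,  2.08,  2.98,  0.23,  1.18,  2.91,  3.38),
    c("long_noncoding_rna",          0.79,  1.78, 16.45, 16.34,  1.77,  3.16, 21.70, 18.29),
    c("ribosomal_rna",               0.00,  0.20,  0.02,  0.15,  0.00,  0.05,  0.03,  0.20),
    c("small_nuclear_rna",           0.08,  0.45,  1.20,  2.17,  0.19,  0.81,  1.94,  2.90),
    c("morbid_genes",                0.20,  0.48,  3.84,  3.65,  0.37,  0.70,  5.22,  4.60),
    c("disease_associated_genes",    0.18,  0.46,  3.24,  3.11,  0.34,  0.68,  4.26,  3.85),
    c("haploinsufficient_genes",     0.02,  0.14,  0.48,  0.69,    NA,    NA,    NA,    NA),
    c("haploinsufficient_regions",   0.06,  0.27,  0.47,  0.67,    NA,    NA,    NA,    NA),
    c("regulatory_elements",        18.13, 40.77, 453.31, 396.98, 40.36, 59.97, 559.55, 424.50),
    c("enhancers",                   3.35,  7.55, 75.64, 72.11,  6.70, 11.01, 82.97, 65.57),
    c("open_chromatin_regions",      3.02,  6.88, 58.18, 53.91,  6.43, 10.76, 66.38, 51.71),
    c("promoters",                   1.16,  3.43, 35.69, 37.78,  2.88,  5.30, 51.44, 49.52),
    c("promoter_flanking_regions",   3.41,  8.43, 99.24, 92.16,  7.72, 12.95, 118.60, 91.80),
    c("ctcf_binding_sites",          5.95, 15.41, 53.41, 46.64, 13.77, 23.12, 197.61, 168.01),
    c("tf_binding_sites",            1.11,  3.38, 26.93, 35.99,  2.60,  5.47, 36.90, 44.69),
    c("curated_regulatory_elements", 0.12,  0.61,  4.25,  4.66,  0.26,  0.73,  5.64,  5.28),
    c("triplosensitive_regions",       NA,    NA,    NA,    NA,  0.02,  0.17,  0.62,  0.74)
  )
  df <- data.frame(attribute = m[, 1],
                   apply(m[, -1, drop = FALSE], 2, as.numeric))
  names(df) <- c("attribute", "loss_benign_mean", "loss_benign_sd",
                 "loss_pathogenic_mean", "loss_pathogenic_sd",
                 "gain_benign_mean", "gain_benign_sd",
                 "gain_pathogenic_mean", "gain_pathogenic_sd")
  df
})

#' Default per-class count moments
#'
#' Mean and standard deviation of each annotation attribute for benign and
#' pathogenic variants, per CNV type — the moment targets the synthetic
#' feature generator reproduces. Long format, one row per (attribute,
#' class).
#'
#' @param cnv_type `"loss"` or `"gain"`.
#' @return data.frame with columns `attribute`, `class`, `mean`, `sd`,
#'   ordered by the annotation schema.
#' @export
default_count_moments <- function(cnv_type = c("loss", "gain")) {
  cnv_type <- match.arg(cnv_type)
  schema <- annotation_schema(cnv_type)
  m <- .count_moments[match(schema, .count_moments$attribute), ]
  out <- rbind(
    data.frame(attribute = m$attribute, class = "benign",
               mean = m[[paste0(cnv_type, "_benign_mean")]],
               sd = m[[paste0(cnv_type, "_benign_sd")]]),
    data.frame(attribute = m$attribute, class = "pathogenic",
               mean = m[[paste0(cnv_type, "_pathogenic_mean")]],
               sd = m[[paste0(cnv_type, "_pathogenic_sd")]])
  )
  rownames(out) <- NULL
  out
}

# one column of counts with the requested moments: negative binomial by
# moment matching when overdispersed, Poisson when var <= mean, constant
# when sd == 0, all-zero when mean == 0
.sample_counts <- function(n, mean, sd) {
  if (mean == 0) return(integer(n))
  if (sd == 0) return(rep.int(as.integer(round(mean)), n))
  v <- sd^2
  if (v <= mean) {
    stats::rpois(n, lambda = mean)
  } else {
    size <- mean^2 / (v - mean)
    stats::rnbinom(n, size = size, mu = mean)
  }
}

# copula variant: correlated standard normals -> per-attribute quantiles
.sample_counts_copula <- function(z, mean, sd) {
  n <- length(z)
  if (mean == 0) return(integer(n))
  u <- stats::pnorm(z)
  if (sd == 0) return(rep.int(as.integer(round(mean)), n))
  v <- sd^2
  if (v <= mean) {
    stats::qpois(u, lambda = mean)
  } else {
    size <- mean^2 / (v - mean)
    stats::qnbinom(u, size = size, mu = mean)
  }
}

#' Sample a labeled feature-count dataset
#'
#' Draws per-attribute counts from negative-binomial distributions
#' parameterized by moment matching to the supplied (mean, sd) targets,
#' falling back to Poisson when the variance does not exceed the mean and
#' to a constant column when sd = 0. By default attributes are sampled
#' independently; `copula_rho` > 0 induces a common rank correlation across
#' attributes via a Gaussian copula (equicorrelated latent normals), for
#' callers that want gene-count co-variation.
#'
#' @param cnv_type `"loss"` or `"gain"`.
#' @param n_benign,n_pathogenic class sizes.
#' @param seed integer RNG seed; same seed, same dataset.
#' @param moments long-format moment table as from
#'   [default_count_moments()]; must cover the full schema for both
#'   classes.
#' @param copula_rho latent correlation in \[0, 1); 0 (default) samples
#'   attributes independently.
#' @return list with `features` (data.frame in schema column order),
#'   `labels` (character vector) and `cnv_type`.
#' @export
sample_feature_dataset <- function(cnv_type = c("loss", "gain"),
                                   n_benign = 2000L, n_pathogenic = 2000L,
                                   seed = 1L,
                                   moments = default_count_moments(cnv_type),
                                   copula_rho = 0) {
  cnv_type <- match.arg(cnv_type)
  schema <- annotation_schema(cnv_type)
  for (cls in c("benign", "pathogenic")) {
    have <- moments$attribute[moments$class == cls]
    miss <- setdiff(schema, have)
    if (length(miss) > 0L) {
      stop("moment specs incomplete for class ", cls, ": missing ",
           paste(miss, collapse = ", "))
    }
  }
  set.seed(seed)
  draw_class <- function(cls, n) {
    spec <- moments[moments$class == cls, ]
    spec <- spec[match(schema, spec$attribute), ]
    if (copula_rho > 0) {
      shared <- stats::rnorm(n)
      cols <- lapply(seq_len(nrow(spec)), function(i) {
        z <- sqrt(copula_rho) * shared + sqrt(1 - copula_rho) * stats::rnorm(n)
        .sample_counts_copula(z, spec$mean[i], spec$sd[i])
      })
    } else {
      cols <- lapply(seq_len(nrow(spec)), function(i) {
        .sample_counts(n, spec$mean[i], spec$sd[i])
      })
    }
    names(cols) <- schema
    as.data.frame(cols, optional = TRUE)
  }
  fb <- draw_class("benign", n_benign)
  fp <- draw_class("pathogenic", n_pathogenic)
  list(
    features = rbind(fb, fp),
    labels = rep(c("benign", "pathogenic"), c(n_benign, n_pathogenic)),
    cnv_type = cnv_type
  )
}

#' Toy genome specification
#'
#' Parameters of the simulated genome: chromosome lengths, per-category
#' element density, element and CNV length ranges, class sizes and the
#' density separation between the element-dense region (where pathogenic
#' CNVs are placed) and the element-sparse region (benign CNVs). Each
#' chromosome is split at `dense_fraction` into a dense head and sparse
#' tail.
#'
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param categories category names to simulate (default: the full
#'   vocabulary).
#' @param density_per_mbp baseline (sparse-region) element density per
#'   category, elements per Mbp.
#' @param separation density multiplier of the dense region over the sparse
#'   region; also the expected ratio of per-class mean element counts.
#' @param element_length_range,cnv_length_range uniform length ranges (bp).
#' @param n_benign,n_pathogenic CNVs per class.
#' @param dense_fraction fraction of each chromosome that is element-dense.
#' @param seed integer RNG seed.
#' @return list of class `toy_genome_spec`.
#' @export
toy_genome_spec <- function(chrom_lengths = c(chrA = 10e6, chrB = 8e6),
                            categories = union(annotation_schema("loss"),
                                               annotation_schema("gain")),
                            density_per_mbp = 5,
                            separation = 8,
                            element_length_range = c(500, 5000),
                            cnv_length_range = c(5e4, 5e5),
                            n_benign = 60L, n_pathogenic = 60L,
                            dense_fraction = 0.5,
                            seed = 1L) {
  stopifnot(all(chrom_lengths > 0), density_per_mbp > 0, separation > 0,
            dense_fraction > 0, dense_fraction < 1)
  structure(as.list(environment()), class = "toy_genome_spec")
}

#' Build a toy genome with element tracks and labeled CNVs
#'
#' Places elements uniformly within the dense and sparse region of each
#' chromosome at densities differing by the configured separation factor,
#' then places pathogenic CNVs inside dense regions and benign CNVs inside
#' sparse regions, so overlap annotation yields class-separated counts.
#' Dosage-sensitivity categories receive integer evidence scores with a
#' majority at 3, so score filtering is exercised. For every CNV the
#' generator also records its own brute-force overlap counts
#' (`truth_counts`), usable as an independent oracle for the annotation
#' module.
#'
#' @param spec a [toy_genome_spec()].
#' @return list with `tracks` (long-format element data.frame: `chrom`,
#'   `start`, `end`, `category`, `score`), `cnvs` (CNV data.frame with
#'   `label`), `truth_counts` (per-CNV brute-force counts over all
#'   categories, score-filtered) and `spec`.
#' @export
build_toy_genome <- function(spec = toy_genome_spec()) {
  stopifnot(inherits(spec, "toy_genome_spec"))
  set.seed(spec$seed)
  chroms <- names(spec$chrom_lengths)

  place_elements <- function(chr, lo, hi, n, category) {
    if (n == 0L) return(NULL)
    len <- round(stats::runif(n, spec$element_length_range[1],
                              spec$element_length_range[2]))
    start <- floor(stats::runif(n, lo, pmax(lo + 1, hi - len)))
    data.frame(chrom = chr, start = start, end = start + len,
               category = category, stringsAsFactors = FALSE)
  }

  tracks <- list()
  for (chr in chroms) {
    L <- spec$chrom_lengths[[chr]]
    split_at <- round(spec$dense_fraction * L)
    for (category in spec$categories) {
      n_dense <- stats::rpois(1, spec$density_per_mbp * spec$separation *
                                split_at / 1e6)
      n_sparse <- stats::rpois(1, spec$density_per_mbp * (L - split_at) / 1e6)
      tracks[[length(tracks) + 1L]] <-
        place_elements(chr, 0, split_at, n_dense, category)
      tracks[[length(tracks) + 1L]] <-
        place_elements(chr, split_at, L, n_sparse, category)
    }
  }
  tracks <- do.call(rbind, tracks)
  tracks$score <- NA_integer_
  dosage <- tracks$category %in% dosage_score_categories()
  # ~70% score 3 (retained), the rest spread over other evidence codes
  tracks$score[dosage] <- sample(c(3L, 3L, 3L, 3L, 3L, 3L, 3L, 0L, 1L, 2L),
                                 sum(dosage), replace = TRUE)

  place_cnvs <- function(n, label, dense) {
    chr <- sample(chroms, n, replace = TRUE)
    L <- spec$chrom_lengths[chr]
    split_at <- round(spec$dense_fraction * L)
    len <- round(stats::runif(n, spec$cnv_length_range[1],
                              spec$cnv_length_range[2]))
    lo <- if (dense) 0 else split_at
    hi <- if (dense) split_at else L
    start <- floor(lo + stats::runif(n) * pmax(1, hi - lo - len))
    data.frame(chrom = chr, start = start, end = start + len,
               label = label, stringsAsFactors = FALSE)
  }
  cnvs <- rbind(place_cnvs(spec$n_pathogenic, "pathogenic", dense = TRUE),
                place_cnvs(spec$n_benign, "benign", dense = FALSE))
  cnvs$source_id <- sprintf("toy_%04d", seq_len(nrow(cnvs)))
  rownames(cnvs) <- NULL

  # generator bookkeeping: brute-force all-pairs overlap counts, applying
  # the score == 3 rule to dosage categories; independent of the
  # interval-tree path used by annotate_cnv
  counted <- tracks
  drop <- counted$category %in% dosage_score_categories() & counted$score != 3L
  counted <- counted[!drop, , drop = FALSE]
  truth <- sapply(spec$categories, function(category) {
    el <- counted[counted$category == category, , drop = FALSE]
    vapply(seq_len(nrow(cnvs)), function(i) {
      sum(el$chrom == cnvs$chrom[i] & el$start < cnvs$end[i] &
            el$end > cnvs$start[i])
    }, integer(1))
  })
  truth <- as.data.frame(truth, optional = TRUE)

  list(tracks = tracks, cnvs = cnvs, truth_counts = truth, spec = spec)
}
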