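# Attribute vocabulary for CNV annotation.
#
# Feature vectors are ordered counts of overlapped genomic elements, one
# count per category track. Loss (deletion) models use haploinsufficiency
# categories; gain (duplication) models use triplosensitivity instead, so the
# two schemas differ in length (19 vs 18).

#' @keywords internal
.shared_attributes <- c(
  "overlapped_gencode_elements",
  "protein_coding_genes",
  "pseudogenes",
  "micro_rna",
  "long_noncoding_rna",
  "ribosomal_rna",
  "small_nuclear_rna",
  "morbid_genes",
  "disease_associated_genes",
  "regulatory_elements",
  "enhancers",
  "open_chromatin_regions",
  "promoters",
  "promoter_flanking_regions",
  "ctcf_binding_sites",
  "tf_binding_sites",
  "curated_regulatory_elements"
)

.loss_attributes <- append(.shared_attributes,
                           c("haploinsufficient_genes", "haploinsufficient_regions"),
                           after = 9L)

.gain_attributes <- c(.shared_attributes, "triplosensitive_regions")

# categories whose elements carry a dosage-sensitivity evidence score and are
# filtered to score == 3 before counting
.dosage_categories <- c("haploinsufficient_genes",
                        "haploinsufficient_regions",
                        "triplosensitive_regions")

#' Annotation schema for a CNV type
#'
#' Returns the ordered attribute (category) names used to annotate and model
#' a CNV of the given type. Loss CNVs are annotated with 19 attributes
#' including counts of haploinsufficient genes and regions; gain CNVs with 18
#' attributes where those two are replaced by triplosensitive regions.
#'
#' @param cnv_type `"loss"` or `"gain"`.
#' @return Character vector of attribute names, in stable column order.
#' @examples
#' length(annotation_schema("loss"))  # 19
#' length(annotation_schema("gain"))  # 18
#' @export
annotation_schema <- function(cnv_type = c("loss", "gain")) {
  cnv_type <- match.arg(cnv_type)
  if (cnv_type == "loss") .loss_attributes else .gain_attributes
}

#' Dosage-sensitivity score categories
#'
#' Category tracks whose elements carry an integer evidence score
#' (haploinsufficiency for losses, triplosensitivity for gains). Only
#' elements with the maximal evidence score (3, "sufficient evidence") are
#' counted during annotation.
#'
#' @return Character vector of category names.
#' @export
dosage_score_categories <- function() .dosage_categories

.valid_cnv_types <- c("loss", "gain")

.five_tier_labels <- c("benign", "likely_benign", "uncertain",
                       "likely_pathogenic", "pathogenic")

#' Five-tier variant classification vocabulary
#'
#' The ACMG/AMP-style labels accepted on input CNVs: benign, likely_benign,
#' uncertain, likely_pathogenic, pathogenic. Models train on the binary
#' extremes only; the intermediate tiers are kept for separate evaluation.
#'
#' @return Character vector of the five labels.
#' @export
five_tier_labels <- function() .five_tier_labels

# normalize user-supplied cnv_type strings ("DEL", "deletion", "LOSS", ...)
normalize_cnv_type <- function(x) {
  x <- tolower(as.character(x))
  out <- ifelse(x %in% c("loss", "del", "deletion"), "loss",
         ifelse(x %in% c("gain", "dup", "duplication"), "gain", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown cnv_type value(s): ", paste(bad, collapse = ", "))
  }
  out
}
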