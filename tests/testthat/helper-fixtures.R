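# Shared fixtures, built in code. Heavier objects (trained classifiers) are
# memoised so the suite trains each model once.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, build(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# brute-force any-overlap count: the independent O(n*m) oracle
brute_force_counts <- function(query, track) {
  vapply(seq_len(nrow(query)), function(i) {
    sum(track$chrom == query$chrom[i] &
          track$start < query$end[i] &
          track$end > query$start[i])
  }, integer(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), genome_len = 1e7,
                             max_len = 5e4) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- floor(runif(n, 0, genome_len - max_len))
  len <- ceiling(runif(n, 1, max_len))
  data.frame(chrom = chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

# hand-built toy catalog on one chromosome: 2 protein-coding genes, 1 morbid
# gene and 3 enhancers inside [1000, 9000), other categories empty
toy_catalog <- function() {
  tracks <- rbind(
    data.frame(chrom = "chr1", start = c(1000, 4000), end = c(2000, 5000),
               category = "protein_coding_genes"),
    data.frame(chrom = "chr1", start = 4200, end = 4800,
               category = "morbid_genes"),
    data.frame(chrom = "chr1", start = c(6000, 7000, 8000),
               end = c(6100, 7100, 8100), category = "enhancers"),
    data.frame(chrom = "chr1", start = 50000, end = 51000,
               category = "promoters")  # outside the CNV below
  )
  element_catalog(tracks, complete = TRUE)
}

# moment-matched synthetic loss dataset + 70/15/15 split, memoised
loss_split <- function(seed = 101) {
  memo(paste0("loss_split_", seed), function() {
    ds <- sample_feature_dataset("loss", 2000, 2000, seed = seed)
    split_train_val_test(cbind(ds$features, label = ds$labels), seed = seed)
  })
}

# classifier trained on the synthetic loss dataset with the default tuned
# hyperparameters, memoised
loss_classifier <- function(seed = 101) {
  memo(paste0("loss_clf_", seed), function() {
    sp <- loss_split(seed)
    sc <- annotation_schema("loss")
    train_classifier(sp$train[, sc], sp$train$label,
                     sp$validation[, sc], sp$validation$label,
                     cnv_type = "loss", seed = seed)
  })
}
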