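test_that("overlap counting handles empty tracks, containment and chromosomes", {
  cnv <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_identical(count_overlapping_elements(cnv, NULL), 0L)
  expect_identical(
    count_overlapping_elements(cnv, data.frame(chrom = "chr1", start = 150,
                                               end = 160)), 1L)
  expect_identical(
    count_overlapping_elements(cnv, data.frame(chrom = "chr2", start = 150,
                                               end = 160)), 0L)
  # half-open: an element starting exactly at the CNV end does not overlap
  expect_identical(
    count_overlapping_elements(cnv, data.frame(chrom = "chr1", start = 200,
                                               end = 210)), 0L)
  expect_identical(
    count_overlapping_elements(cnv, data.frame(chrom = "chr1", start = 199,
                                               end = 210)), 1L)
})

test_that("overlap counting rejects invalid intervals", {
  expect_error(count_overlapping_elements(
    data.frame(chrom = "chr1", start = 200, end = 100),
    data.frame(chrom = "chr1", start = 1, end = 2)), "invalid")
  expect_error(count_overlapping_elements(
    data.frame(chrom = "chr1", start = 100, end = 100),
    data.frame(chrom = "chr1", start = 1, end = 2)), "invalid")
})

test_that("overlap counts agree with the brute-force all-pairs oracle", {
  set.seed(4242)
  query <- random_intervals(1000)
  track <- random_intervals(500)
  expect_identical(count_overlapping_elements(query, track),
                   brute_force_counts(query, track))
  # many small seeded instances
  for (s in 1:100) {
    set.seed(s)
    q <- random_intervals(30, genome_len = 1e5, max_len = 5e3)
    t <- random_intervals(20, genome_len = 1e5, max_len = 5e3)
    expect_identical(count_overlapping_elements(q, t),
                     brute_force_counts(q, t))
  }
})

test_that("overlap counting is symmetric and shift invariant", {
  set.seed(99)
  a <- random_intervals(50, genome_len = 1e6, max_len = 1e4)
  b <- random_intervals(50, genome_len = 1e6, max_len = 1e4)
  expect_identical(sum(count_overlapping_elements(a, b)),
                   sum(count_overlapping_elements(b, a)))
  shift <- function(df, k) transform(df, start = start + k, end = end + k)
  expect_identical(count_overlapping_elements(shift(a, 1e4), shift(b, 1e4)),
                   count_overlapping_elements(a, b))
})

test_that("dosage-score filter keeps exactly score == 3", {
  trk <- data.frame(chrom = "chr1", start = (0:4) * 100, end = (0:4) * 100 + 50,
                    score = c(3, 2, 3, 1, 40))
  kept <- filter_dosage_sensitive(trk)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$score == 3))
  # all 3s -> identity
  all3 <- transform(trk, score = 3)
  expect_equal(filter_dosage_sensitive(all3), all3)
  # equals a one-pass predicate filter on a random scored set
  set.seed(11)
  rnd <- data.frame(chrom = "chr1", start = 1:200 * 10, end = 1:200 * 10 + 5,
                    score = sample(0:40, 200, replace = TRUE))
  expect_equal(filter_dosage_sensitive(rnd), rnd[rnd$score == 3, ])
  # missing scores are an error
  expect_error(filter_dosage_sensitive(transform(trk, score = NA)), "score")
})

test_that("annotate_cnv counts the hand-built toy catalog correctly", {
  catalog <- toy_catalog()
  cnv <- data.frame(chrom = "chr1", start = 500, end = 9000)
  fv <- annotate_cnv(cnv, catalog, "loss")
  expect_equal(ncol(fv), 19L)
  expect_equal(fv$protein_coding_genes, 2L)
  expect_equal(fv$morbid_genes, 1L)
  expect_equal(fv$enhancers, 3L)
  expect_equal(fv$promoters, 0L)
  other <- setdiff(names(fv), c("protein_coding_genes", "morbid_genes",
                                "enhancers"))
  expect_true(all(unlist(fv[, other]) == 0L))
})

test_that("annotate_cnv schemas differ by type and empty overlap is all zero", {
  catalog <- toy_catalog()
  far <- data.frame(chrom = "chr9", start = 0, end = 1000)
  loss <- annotate_cnv(far, catalog, "loss")
  gain <- annotate_cnv(far, catalog, "gain")
  expect_equal(ncol(loss), 19L)
  expect_equal(ncol(gain), 18L)
  expect_true(all(unlist(loss) == 0L) && all(unlist(gain) == 0L))
  expect_true("haploinsufficient_genes" %in% names(loss))
  expect_false("haploinsufficient_genes" %in% names(gain))
  expect_true("triplosensitive_regions" %in% names(gain))
})

test_that("annotate_cnv errors on a missing category and warns on unknown ones", {
  partial <- element_catalog(data.frame(chrom = "chr1", start = 1, end = 10,
                                        category = "enhancers"))
  cnv <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_error(annotate_cnv(cnv, partial, "loss"), "protein_coding_genes")
  expect_warning(element_catalog(data.frame(chrom = "chr1", start = 1,
                                            end = 10, category = "exotic")),
                 "exotic")
})

test_that("a whole-chromosome CNV counts every element on that chromosome", {
  set.seed(5)
  tracks <- data.frame(chrom = sample(c("chrA", "chrB"), 80, replace = TRUE),
                       start = 0, end = 0, category = "enhancers")
  tracks$start <- floor(runif(80, 0, 9e5))
  tracks$end <- tracks$start + 100
  catalog <- element_catalog(tracks, complete = TRUE)
  whole <- data.frame(chrom = "chrA", start = 0, end = 1e6)
  fv <- annotate_cnv(whole, catalog, "loss")
  expect_equal(fv$enhancers, sum(tracks$chrom == "chrA"))
})

test_that("genome tiling is a disjoint exact cover with trailing partials", {
  tiles <- tile_genome(c(c1 = 2.5e6), 1e6)
  loss_tiles <- tiles[tiles$cnv_type == "loss", ]
  expect_equal(loss_tiles$start, c(0, 1e6, 2e6))
  expect_equal(loss_tiles$end, c(1e6, 2e6, 2.5e6))
  # chromosome shorter than tile -> single full-chromosome tile
  short <- tile_genome(c(s = 4e5), 1e6)
  expect_equal(nrow(short), 2L)  # one loss + one gain
  expect_equal(unique(short$end), 4e5)
  # partition sweep on a multi-chromosome genome
  sizes <- c(a = 3.2e6, b = 1e6, c = 7e5)
  t2 <- tile_genome(sizes, 1e6)
  for (ty in c("loss", "gain")) {
    for (chr in names(sizes)) {
      tt <- t2[t2$cnv_type == ty & t2$chrom == chr, ]
      tt <- tt[order(tt$start), ]
      expect_equal(tt$start[1], 0)
      expect_equal(tt$end[nrow(tt)], unname(sizes[chr]))
      if (nrow(tt) > 1) expect_equal(tt$start[-1], tt$end[-nrow(tt)])
    }
  }
  expect_error(tile_genome(c(a = 1e6), 0), "tile_length")
})
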