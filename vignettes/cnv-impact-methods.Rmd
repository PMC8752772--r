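---
title: "Methods: count-based CNV pathogenicity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: count-based CNV pathogenicity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvimpact)
```

## The model and its assumptions

`cnvimpact` treats CNV interpretation as binary classification with
abstention. A CNV is represented solely by how many genomic elements of
each category it overlaps: six GENCODE gene classes plus the total GENCODE
count, morbid and disease-associated genes, dosage-sensitivity regions
(haploinsufficient genes/regions for losses, triplosensitive regions for
gains), the total regulatory-element count and six regulatory
subcategories. Losses and gains get separate models because the biology of
dosage differs: a heterozygous deletion of a haploinsufficient gene is
damaging while its duplication may be tolerated, so the loss schema (19
attributes) carries haploinsufficiency counts and the gain schema (18)
carries triplosensitivity instead.

The underlying assumptions are that (a) pathogenic CNVs are distinguished
by the functional content of the affected interval rather than by raw
length — counts grow with length, but length alone is not in the schema —
and (b) any-overlap counting (one shared base suffices) is an acceptable
proxy for disruption. Both are simplifications: a CNV clipping the last
exon of a gene counts the same as one deleting it entirely.

Classification uses gradient-boosted trees (`xgboost`), which handle
integer count features, skewed distributions and feature interactions
without scaling or transformation, and admit exact per-feature Shapley
attributions (TreeSHAP).

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `max_depth` | 8 | tree depth; deep enough for gene x regulatory interactions |
| `eta` | 0.3 | learning rate |
| `gamma` | 1 | minimum split gain, regularizes small noisy splits |
| `subsample` | 1 | row fraction per round |
| `lambda` | 0.1 | L2 penalty on leaf weights |
| `colsample_bytree` | 0.8 | per-tree column subsampling (decorrelates trees) |
| `scale_pos_weight` | `sqrt(n_benign / n_pathogenic)` | softened reweighting of the pathogenic minority; the square root deliberately under-corrects so precision on the majority class is preserved |
| `n_rounds` / `early_stopping_rounds` | 100 / 15 | boosting budget; fitting stops when validation log-loss stagnates for 15 rounds |
| `p_ct` | 0.95 (presets 0.5 / 0.95 / 0.99) | abstention threshold: pathogenic iff `p >= p_ct`, benign iff `p <= 1 - p_ct` |

The 0.95 operating point trades a modest abstention fraction for high
precision on definite calls; 0.99 is stricter, 0.5 disables abstention
entirely (and `p = 0.5` exactly is called pathogenic, because `>=` wins).

Model selection across a hyperparameter grid ranks by validation MCC of
the definite calls at `p_ct = 0.5`. MCC is preferred over accuracy because
the classes are imbalanced in real call sets. Ties are broken by higher
validation accuracy, then smaller `max_depth` (prefer the simpler model),
then grid order — a deterministic stand-in for manual inspection of
several metrics at once.

## Design choices where the design was open

* **Coordinates** are 0-based half-open throughout (BED convention). BED
  and TSV input pass through; VCF `POS` is converted by subtracting 1 and
  `INFO/END` is used as the exclusive end. Overlap means at least one
  shared base; no reciprocal-overlap fraction is applied.
* **Dosage-score filtering** keeps elements whose evidence score *equals*
  3, not `>= 3`: on the haploinsufficiency/triplosensitivity scale, codes
  above 3 (e.g. 40) do not denote stronger evidence.
* **Size filter** reads "larger than 1 kbp" and "smaller than 5 Mbp" as
  strict inequalities; a CNV of exactly 5 Mbp is routed to the long-CNV
  evaluation set. This keeps the training regime conservatively under
  5 Mbp, where benign examples still exist.
* **Multiplicity**: records lacking a multiplicity annotation are treated
  as canonical (copy number 1 for losses, 3 for gains), since most public
  CNV records omit it; all other multiplicities form a separate
  evaluation set.
* **Partitioning** is a label-stratified random 70/15/15 split with a
  logged seed. The upstream data split procedure is not recoverable, and
  near-equal validation/test sizes are consistent with this choice.
* **Early stopping** monitors validation log-loss. MCC is used only to
  compare fitted configurations, not as the stopping objective — log-loss
  is smooth per boosting round, whereas thresholded MCC is a step
  function.
* **Explanations** are computed on the log-odds (margin) scale where
  TreeSHAP is exact and additive; the probability scale is a display
  transform of the two endpoints only. Mapping every individual
  contribution through the logistic function would break additivity.
  The baseline is the tree-path-dependent expectation over the training
  set, the standard tree-explainer behavior.
* **Tiling** emits trailing partial tiles (dropping them would leave
  chromosome ends unannotated), and an element spanning a tile boundary
  counts in every tile it touches, consistent with any-overlap.
* Unknown track categories are ignored with a warning; a *required*
  category entirely missing from a catalog is an error unless the caller
  opts into treating it as empty (useful for sparse toy genomes).

## The synthetic data: what it does and does not emulate

The feature generator draws each attribute independently from a negative
binomial matched to the per-class (benign/pathogenic) mean and standard
deviation observed in ClinVar-derived training data, falling back to
Poisson when the variance does not exceed the mean, a constant when
`sd = 0`, and all-zeros when `mean = 0`. The negative binomial was chosen
because nearly every attribute shows variance far above its mean
(e.g. loss-benign protein-coding genes: mean 1.41, sd 3.29). A Gaussian
copula option (`copula_rho`) can induce rank correlation across
attributes, off by default.

This emulates the marginal per-class count distributions, hence the
separability structure that the classifier exploits. It does **not**
emulate: the strong natural correlations among attributes (gene counts
co-vary with regulatory counts through CNV length), the length-count
coupling, genomic clustering of recurrent syndromic CNVs, or label noise
in curated databases. Because the independent marginals overlap less than
correlated real data, the synthetic classes are close to perfectly
separable — trained models reach validation MCC near 1.0, well above what
is achievable on clinical data. Passing tests therefore demonstrate that
the annotation, training, thresholding, explanation and evaluation
machinery is correct, not that any particular clinical accuracy would be
attained.

The toy-genome builder is complementary: it places elements uniformly at
a dense-region/sparse-region density ratio (`separation`, default 8) and
puts pathogenic CNVs in dense, benign CNVs in sparse regions, recording
its own brute-force overlap counts per CNV. These bookkept counts serve
as an independent oracle for the interval-tree annotation path, and the
emitted BED/TSV files exercise the real parsers end to end.

## Numerical choices

* **Additivity tolerance.** `xgboost` stores leaf values and SHAP outputs
  in single precision. On well-separated data margins reach magnitudes
  around 30, where one float32 ULP is ~4e-6, so the additivity identity
  `base + sum(contributions) = margin` is asserted to 1e-6 *relative to*
  `max(1, |margin|)` — identical to an absolute 1e-6 for outputs of
  magnitude at most 1.
* **Permutation null.** The no-signal control permutes every label the
  fit can see, including the validation labels that steer early stopping
  (leaving those intact lets iteration selection recover genuine signal).
  A single permuted fit still produces probabilities hovering at 0.5
  whose thresholded calls align with the feature clusters by chance,
  giving per-draw MCC spread of roughly ±0.4 independent of sample size;
  the control therefore reports the mean over 20 permutation replicates,
  which centers near 0 when no signal is available.
* **Undefined metrics** (zero denominators, e.g. pathogenic precision
  when nothing is called pathogenic) are reported as explicit `NA` /
  JSON `null` and listed in the report's `undefined` field, never
  silently coerced to 0.
* **Determinism.** Every stochastic step (generation, splitting,
  training, permutation) takes an explicit seed; fixed seed plus fixed
  input reproduces bit-identical probabilities (`nthread = 1` and the
  seed is passed to the booster).
* **Degenerate inputs.** Empty tracks yield zero counts; single-class
  training sets, empty grids, invalid intervals (`start >= end`),
  probabilities outside [0, 1] and malformed labels raise validation
  errors naming the offending record where possible.

## Problem sizes

The test suite and the acceptance script run on synthetic data sized to
exercise the statistics without excess: 2,000 + 2,000 records per class
for classifier properties (70/15/15 split), 50,000 per class for
moment-matching checks, 1,000 x 500 intervals plus 100 smaller seeded
instances for the overlap oracle, toy genomes of two chromosomes
(10 + 8 Mbp) with 120-300 CNVs, and 20 permutation replicates for the
null control. The full suite runs in well under a minute on one CPU.

## Known limitations

* Counts ignore partial-overlap severity and gene identity; two CNVs
  hitting different genes with equal counts are indistinguishable.
* The classifier is only as good as its element catalogs; the package
  ships no human annotation tracks and performs no liftover, gene-name
  resolution or database queries.
* Probabilities are uncalibrated boosting outputs; the abstention
  thresholds interpret them as confidence scores, not calibrated
  frequencies.
* The five-tier evaluation view summarizes predictions for likely-benign
  / likely-pathogenic / uncertain records, but those records never
  contribute to training.
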