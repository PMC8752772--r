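# cnvimpact

Clinical-impact classification of copy number variants (CNVs) in R.

Clinical labs routinely face deletions and duplications of kilobase-to-
megabase genomic segments whose pathogenicity is unknown. `cnvimpact`
implements a machine-learning alternative to manual ACMG-style scoring:
each CNV is described only by **counts of the genomic elements it
overlaps** — GENCODE gene classes (protein-coding, pseudogene, miRNA,
lncRNA, rRNA, snRNA), morbid and disease-associated genes,
haploinsufficient genes/regions (losses) or triplosensitive regions
(gains), and six classes of regulatory elements — and a gradient-boosted
tree ensemble (XGBoost) trained separately for copy-number **losses** (19
attributes) and **gains** (18 attributes) returns a probability of
pathogenicity.

## The model

For a CNV with feature vector *x* (non-negative overlap counts), the
per-type booster *f* returns *p = σ(f(x))*, the probability the variant is
pathogenic. Calls use an abstention policy inspired by ACMG thresholds
with operating point *P<sub>ct</sub>* ∈ {0.5, 0.95, 0.99} (default 0.95):

* *p ≥ P<sub>ct</sub>* → **pathogenic**
* *p ≤ 1 − P<sub>ct</sub>* → **benign**
* otherwise → **uncertain significance** (abstain)

Training uses the tuned hyperparameters `max_depth = 8`, `eta = 0.3`,
`gamma = 1`, `subsample = 1`, `lambda = 0.1`, `colsample_bytree = 0.8`,
100 rounds with early stopping after 15 stagnant rounds of validation
log-loss, and class weighting
`scale_pos_weight = sqrt(n_benign / n_pathogenic)`. Model selection across
a hyperparameter grid ranks by validation Matthews correlation coefficient
(MCC). Evaluation is uncertain-aware: a 3×2 confusion table (three calls ×
two truth classes) yields uncertain-excluded accuracy / sensitivity /
specificity / precision / MCC, plus per-class *discovery* rates whose
denominators include abstentions. Every individual call is explained by
exact additive Shapley (TreeSHAP) contributions on the log-odds scale, and
a tiling mode scores consecutive 1-Mbp windows of a genome as hypothetical
losses and gains.

The package also ships a synthetic-data module: a moment-matched
negative-binomial generator that reproduces the per-class mean/sd of each
attribute observed in ClinVar-derived training data, and a toy-genome
builder (element tracks + labeled CNVs with bookkept ground-truth counts),
so the entire pipeline runs and is tested without any external downloads.

## Worked example

```r
library(cnvimpact)

# a published loss-model test confusion table, by true class:
# (called-benign, called-pathogenic, called-uncertain)
ct <- confusion_from_counts(c(1062, 6, 221), c(11, 413, 116))
metrics_from_confusion(ct)
#> Three-class evaluation (n = 1829)
#>   included: 81.57%  (uncertain: 18.43%)
#>   accuracy: 98.86%  sensitivity: 97.41%  specificity: 99.44%
#>   precision benign/pathogenic: 98.97% / 98.57%
#>   discovery benign/pathogenic: 82.39% / 76.48%
#>   MCC: 0.9719
```

Accuracy and MCC are computed on definite calls only (the 81.57% of CNVs
not abstained on); the discovery rates say what fraction of each truth
class received a correct definite call.

Training on synthetic moment-matched data and explaining one prediction:

```r
ds  <- sample_feature_dataset("loss", 2000, 2000, seed = 42)
sp  <- split_train_val_test(cbind(ds$features, label = ds$labels), seed = 42)
sc  <- annotation_schema("loss")
clf <- train_classifier(sp$train[, sc], sp$train$label,
                        sp$validation[, sc], sp$validation$label,
                        "loss", seed = 42)
clf
#> cnv_classifier (loss), 19 attributes
#>   training counts: 1400 benign / 1400 pathogenic
#>   scale_pos_weight: 1; best iteration: 29

p <- predict_proba(clf, sp$test[, sc])
metrics_from_confusion(build_confusion(classify(p, 0.95), sp$test$label))
#> Three-class evaluation (n = 600)
#>   included: 99.50%  (uncertain: 0.50%)
#>   accuracy: 100.00%  sensitivity: 100.00%  specificity: 100.00%
#>   ...

explain_prediction(clf, sp$test[1, sc])
#> Prediction explanation (log-odds scale)
#>   base 0.0076 -> output -5.5650 (probability 0.0038)
#>   promoter_flanking_regions     -2.6528 (value 0)
#>   enhancers                     -2.1913 (value 0)
#>   regulatory_elements           +1.7626 (value 163)
#>   ...
```

The synthetic classes are far better separated than real clinical data
(see the methods vignette), so perfect test metrics here demonstrate
pipeline mechanics, not expected clinical performance.

## Command line

An installed `exec/cnvimpact` script exposes the pipeline:

```sh
cnvimpact simulate --out-dir sim --seed 1
cnvimpact annotate --tracks sim/tracks.bed --cnvs sim/cnvs.tsv \
    --cnv-type loss --out features.tsv
cnvimpact train    --features features.tsv --cnv-type loss \
    --out-model model --seed 1
cnvimpact predict  --model model --features features.tsv \
    --out pred.tsv --p-ct 0.95
cnvimpact evaluate --predictions pred.tsv --labels features.tsv \
    --out metrics.json
cnvimpact explain  --model model --features features.tsv --row 1 \
    --out waterfall.tsv
cnvimpact tile     --chrom-sizes sizes.tsv --tracks sim/tracks.bed \
    --model-loss model --model-gain model_gain --out tiles.tsv
```

CNV input is TSV/BED (0-based half-open) or VCF (`SVTYPE` DEL/DUP with
`INFO/END`; POS converted to 0-based).

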