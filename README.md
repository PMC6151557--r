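# dbpmix

Mixed-feature prediction of DNA-binding proteins in R.

DNA-binding proteins (histones, nucleases, transcription factors,
single-strand binding proteins, ...) drive DNA packaging, replication,
transcription and repair. Identifying them experimentally is slow and
expensive, so sequence-based classifiers are the standard screening tool.
dbpmix is for computational biologists who want a complete, inspectable
implementation of a classical mixed-feature pipeline: encode each protein
with several complementary feature sets, fuse them, reduce the dimension,
and classify with a Gaussian-kernel SVM or a random forest.

## The method

Three encoders turn a protein (its sequence plus, optionally, its
PSI-BLAST PSSM and PSI-PRED secondary-structure profiles) into a feature
vector:

* **Information theory (3 features).** From the amino-acid composition
  *p*: Shannon entropy `SEn = -Σ pᵢ log₂ pᵢ`, relative Shannon entropy
  `RSEn = Σ pᵢ log₂(pᵢ/p₀)` with `p₀ = 1/20` (the KL divergence from the
  uniform composition), and the information gain score `IGS = SEn − RSEn`.
* **K-skip-n-grams (400 features for n = 2).** Gapped dipeptide
  composition: every ordered residue pair separated by up to *k* skipped
  positions (default k = 3), pooled as a multiset and normalised to a
  frequency over all 20² grams.
* **Sequential and structural features, SSF (473 features).** From the
  L×20 PSSM: the 20 per-amino-acid column averages, plus 420 weighted
  1-gram/2-gram frequencies of the consensus sequence
  (`S'ᵢⱼ = 2^{Sᵢⱼ} pⱼ`, consensus residue = argmaxⱼ S'ᵢⱼ). From the
  predicted secondary structure: 6 state-sequence features (H/E/C
  fractions, longest helix and strand runs, strand–helix–strand motif
  frequency), the 3 global state-probability means, and 24 local means
  over λ = 8 row segments.

Fused blocks (up to 3 + 400 + 473 = 876 features) are ranked by
**max-relevance–max-distance (MRMD)**: each feature scores
`w₁·|cor(feature, label)| + w₂·distance`, where distance is the mean
Euclidean separation of the standardized feature column from all others,
rescaled to [0, 1]. Selection keeps the top *m* (or chooses *m* by
internal cross-validation). Classification uses a Gaussian-kernel SVM
`K(x₁,x₂) = exp(−‖x₁−x₂‖² / 2σ²)` or a random forest, evaluated by
stratified k-fold cross-validation, jackknife validation, or a stratified
80/20 train/test split, reporting SN, SP, ACC and Matthews correlation
coefficient.

## Worked example

The synthetic fixture generator plants a composition and helix-probability
signal in the positive class, so the whole pipeline runs without any
external databases:

```r
library(dbpmix)

fx <- generate_fixture_dataset(30, 30, seed = 42)          # 60 proteins
fused <- encode_features(fx$sequences, pssms = fx$pssms, ss2s = fx$ss2s,
                         features = c("it", "ksng", "ssf")) # 876 features
ds <- add_labels(fused, fx$labels)

head(mrmd_rank(ds), 3)
#> # A tibble: 3 × 5
#>   feature         relevance distance combined  rank
#>   <chr>               <dbl>    <dbl>    <dbl> <int>
#> 1 ssf.ss_glob.H       0.979    0.994     1.97     1
#> 2 ssf.ss_seq.f_H      0.967    0.993     1.96     2
#> 3 it.RSEn             0.892    1         1.89     3

k_fold_cv(ds, k = 10, classifier = "svm", seed = 42, mrmd_m = 50)
#> <dbp_cv: 10-fold, svm, mean accuracy 1.0000>

split <- train_test_split_stratified(ds, train_fraction = 0.8, seed = 42)
train_sel <- mrmd_select(split$train, m = 50)
model <- train_classifier(train_sel, classifier = "svm", seed = 42)
evaluate_model(model, split$test[, names(train_sel)])
#> <dbp_eval: TP=6 FP=0 TN=6 FN=0 | SN=1.0000 SP=1.0000 ACC=1.0000 MCC=1.0000>
```

The top-ranked features are exactly the planted signal: the global helix
probability and helix fraction (the generator enriches H states in
positives) and the relative Shannon entropy (positives have a skewed
composition). `mrmd_m = 50` refits the feature selection inside every
training fold, so the cross-validated accuracy is free of selection bias.

A command-line interface over the same functions is installed at
`inst/scripts/dbpmix` (`dbpmix help` lists the `fixture`, `encode`,
`fuse`, `select`, `train`, `cv`, `jackknife`, `predict` and `evaluate`
subcommands); `vignettes/dbpmix-methods.Rmd` documents the model choices.

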