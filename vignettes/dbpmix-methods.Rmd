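---
title: "Mixed-feature DNA-binding protein prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-feature DNA-binding protein prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbpmix)
```

# The problem

Whether a protein binds DNA is a binary property with broad functional
consequences, and sequence-based classifiers are the standard way to
screen for it at scale. The accuracy of such classifiers is dominated by
the feature representation: single feature families (plain composition,
evolutionary profiles, predicted structure) each miss part of the signal.
dbpmix implements a mixed-feature pipeline — three complementary encoders,
feature fusion, max-relevance–max-distance (MRMD) dimension reduction, and
a Gaussian-kernel SVM or random forest — together with the validation
machinery (stratified splits, k-fold and jackknife cross-validation,
SN/SP/ACC/MCC) needed to compare feature sets honestly.

# Feature encoders

## Information theory (3 features)

With $p_i$ the frequency of amino acid $i$ in the sequence and
$p_0 = 1/20$:

$$\mathrm{SEn} = -\sum_{i=1}^{20} p_i \log_2 p_i, \qquad
  \mathrm{RSEn} = \sum_{i=1}^{20} p_i \log_2 \frac{p_i}{p_0}, \qquad
  \mathrm{IGS} = \mathrm{SEn} - \mathrm{RSEn}.$$

$\mathrm{SEn} \in [0, \log_2 20]$; $\mathrm{RSEn}$ is the Kullback–Leibler
divergence from the uniform composition, so it is non-negative and zero
exactly for a perfectly uniform 20-letter composition. We use the
convention $0 \log 0 = 0$ and base-2 logarithms throughout, and compute
frequencies over the sanitized sequence (see *Input handling*). All three
are composition-level features: permuting the residues leaves them
unchanged.

## K-skip-n-grams (400 features)

A skip-gram with gap $d$ picks residues at positions $(i, i+d+1)$;
pooling $d = 0, \dots, k$ and normalising the multiset counts gives a
frequency vector over all $20^n$ grams ($n = 2$ by default, hence 400
features; $d = 0$ recovers classical dipeptide composition). Two points
are deliberately fixed here and exposed as configuration:

* **Multiset pooling.** The union over gap values keeps multiplicity —
  the normaliser is the total element count, which only makes sense if
  duplicates accumulate.
* **Default $k = 3$,** capped per sequence at $L - n$ so every sequence
  of length $\ge n$ admits at least one gram. Small $k$ keeps the
  multiset dominated by local pairs; larger values dilute the signal with
  long-range pairs whose counts are nearly composition products.

## Sequential and structural features (473 features)

The SSF encoder consumes two per-sequence profiles produced by external
tools (we parse their output formats; we never run the tools):

* an $L \times 20$ PSSM in PSI-BLAST `-out_ascii_pssm` layout — only the
  first (log-odds) block is used, since the features below average
  *scores*; columns are remapped to a fixed alphabetical amino-acid order
  on read, and
* an $L \times 3$ secondary-structure probability matrix with an H/E/C
  state string, in PSI-PRED `.ss2` VFORMAT (probability columns read as
  C, H, E).

The blocks are:

1. **PSSM averages (20).** $\bar S_j = \frac{1}{L}\sum_i S_{ij}$.
2. **Weighted consensus n-grams (420).** Each position is assigned the
   consensus residue $\arg\max_j 2^{S_{ij}} p_j$, with $p_j$ a background
   frequency; the feature vector concatenates the consensus 1-gram
   frequencies weighted $20/420$ and the contiguous 2-gram frequencies
   weighted $400/420$, so the whole block sums to 1. The default
   background is uniform ($1/20$): database-derived frequencies are a
   supported configuration slot, but a uniform default is reproducible
   without external data. Argmax ties break alphabetically, which makes
   the transform deterministic.
3. **State-sequence features (6).** H, E and C fractions; the longest H
   run and longest E run, each normalised by $L$; and the frequency of
   the strand–helix–strand (β–α–β-like) pattern: collapsing the state
   string to its run sequence and dropping coil runs leaves the segment
   sequence, and the feature is the count of consecutive E,H,E run
   triplets divided by the number of length-3 run windows (floored at 1).
   Run-length and motif definitions admit several readings; these
   concrete normalised-run-length and run-triplet definitions are the
   package's documented interpretation and are unit-tested.
4. **Global probability means (3).** Column means of the probability
   matrix.
5. **Local probability means (24).** The matrix rows are split into
   $\lambda = 8$ contiguous segments whose sizes differ by at most one
   (remainder rows go to the earliest segments — a deterministic,
   commonly used rule); each segment contributes its 3 column means.

At the defaults ($\lambda = 8$, order $n = 1$) the layout is
$20 + 420 + 6 + 3 + 24 = 473$; the PSSM-derived sub-block alone is 440
wide and the structure-derived sub-block $\lambda 3^n + 3^n + 6 = 33$.
Higher structural orders ($n > 1$, products over consecutive rows) are
not implemented: the default order already reproduces the full layout,
and the configuration rejects $n > 1$ with a clear error rather than
guessing the intended product scheme.

# Fusion and MRMD selection

Blocks are concatenated by sample (widths add: e.g. 3 + 400 = 403,
473 + 3 + 400 = 876), keeping block-prefixed feature names
(`it.*`, `ksng.*`, `ssf.*`). MRMD then scores feature $i$ as

$$w_r \cdot \underbrace{|\mathrm{cor}(x_i, y)|}_{\text{relevance}}
  + w_d \cdot \underbrace{\tilde d_i}_{\text{distance}},$$

where $y$ is the 0/1 label, constant features get relevance 0, and
$\tilde d_i$ is the mean Euclidean distance between the standardized
column $i$ and all other standardized columns, rescaled to $[0,1]$.
Standardization makes the ranking invariant to (positive) affine
rescaling of any feature. The weights are a declared configuration with
default $w_r = w_d = 1$: nothing in the method fixes a ratio, and an
unbiased default is the only choice that does not smuggle in a tuned
constant. Ties in the combined score break by original column position.

Selection keeps the top $m$ features; `m = "auto"` sweeps the geometric
grid $\{1, 2, 5, 10, 20, 50, 100, 200, \text{all}\}$ (clipped to the
width) and keeps the smallest $m$ maximising 5-fold cross-validated
accuracy, ties to the smaller $m$.

**Selection must live inside resampling.** Ranking features against the
labels of the full dataset and then cross-validating on the same data
leaks label information into the estimate: on label-permuted data the
leak alone lifts 10-fold accuracy well above chance (we measured
0.66–0.76 across fixed $m$ at $n = 100$, against a true chance level of
0.5). `k_fold_cv(..., mrmd_m = )` therefore refits the ranking and
selection on every training fold and applies it to the held-out fold.
This is the configuration the package's end-to-end checks use; with it
the planted-signal fixtures still cross-validate at $\ge 0.9$ while
label-permuted fixtures fall back to chance.

# Classifiers and evaluation

The SVM uses the Gaussian kernel
$K(x_1, x_2) = \exp(-\lVert x_1 - x_2\rVert^2 / 2\sigma^2)$ with
soft-margin penalty $C$. Neither hyperparameter is canonical for this
problem; the defaults are $C = 1$ and $\sigma = \sqrt{d/2}$ for $d$
features — the familiar $\gamma = 1/d$ automatic-width heuristic — and
both are configurable and recorded in run logs. Features are
standardized to training-set mean/variance before an SVM fit and the same
transform is reapplied to test data; without this, a Gaussian kernel on
features of wildly different scales (PSSM averages in $[-9, 13]$ next to
frequencies in $[0, 1]$) degenerates to a few dominating coordinates.
The random forest (500 trees, seeded) uses raw features, as trees are
scale-invariant.

Evaluation uses the confusion-matrix metrics
$\mathrm{SN} = \mathrm{TP}/(\mathrm{TP{+}FN})$,
$\mathrm{SP} = \mathrm{TN}/(\mathrm{TN{+}FP})$,
$\mathrm{ACC} = (\mathrm{TP{+}TN})/n$ and

$$\mathrm{MCC} = \frac{\mathrm{TP}\cdot\mathrm{TN} -
  \mathrm{FP}\cdot\mathrm{FN}}
  {\sqrt{(\mathrm{TP{+}FP})(\mathrm{TP{+}FN})
         (\mathrm{TN{+}FP})(\mathrm{TN{+}FN})}},$$

with $\mathrm{MCC} := 0$ when any denominator factor vanishes (the
standard convention for degenerate predictions). Validation schemes:
stratified k-fold cross-validation (folds seeded and stratified — the
balanced two-class design makes unstratified folds needlessly noisy),
reported as the mean of fold accuracies alongside pooled counts;
jackknife (leave-one-out, predictions pooled into a single confusion
matrix); and a stratified train/test split assigning
$\lfloor f \cdot n_c \rfloor$ of each class to training (at $f = 0.8$ a
balanced 186-protein set splits 148/38 as 74+74 and 19+19).

# The synthetic fixture generator

`generate_fixture_dataset()` fabricates everything the pipeline consumes
— FASTA sequences, PSI-BLAST-layout PSSM files, `.ss2` files, labels —
with a controllable class signal, deterministically from a seed:

* positives draw residues from
  $(1-s)\,\mathrm{Unif} + s\,\mathrm{Unif}\{K, R, G, S\}$, so the
  composition bias scales from absent ($s = 0$) to total ($s = 1$); the
  enriched subset is a plausible DNA-binding-like signal (basic plus
  small residues) but is synthetic test material, not biology;
* PSSM rows are integer scores in $[-9, 13]$ (matching real PSI-BLAST
  output ranges) with the emitted residue's score elevated;
* structure probabilities are Dirichlet draws with the helix
  concentration raised by `ss_bias` in positives, states set to the
  per-row argmax.

Defaults ($s = 0.5$, helix bias 0.3, lengths 50–80, balanced classes)
give a strong but not degenerate signal. The generator emulates the
*formats* and a *detectable class difference*; it does not emulate real
proteins: no residue-order structure, no correlation between PSSM and
structural signal beyond the labels, no alignment-depth artifacts, and
sequence lengths far below typical proteins. Passing the end-to-end
checks therefore demonstrates that the pipeline recovers a planted,
separable signal and fabricates none from noise — not any particular
accuracy on real benchmark sets, which additionally require externally
computed profiles.

# Numerical and interface choices

* Non-standard residues (B, J, O, U, X, Z) are dropped by default; a
  `map` policy substitutes the ambiguity codes with their nearest
  standard residue (B→D, Z→E, U→C) and drops the rest. All encoders
  assume the 20-letter alphabet.
* Every 20-wide vector uses the fixed alphabetical residue order;
  file-specific column orders (e.g. PSI-BLAST's) are remapped on read so
  results are bit-stable across input conventions.
* The PSSM reader accepts only finite scores and rejects truncated rows;
  the `.ss2` reader requires probabilities in $[0,1]$ with row sums
  within 0.05 of 1 (predictor outputs are rounded to three decimals).
* Degenerate inputs error early with the offending record named: empty
  sequences after sanitization, profile/sequence length mismatches,
  single-class label vectors, consensus sequences too short for the
  2-gram block.
* `0 \log 0 = 0` in both entropies; KL non-negativity and the
  $\mathrm{IGS}$ identity are enforced by property tests.
* Feature tables round-trip through CSV (named columns) and LIBSVM
  (±1 labels, dense 1-based `index:value`) to $10^{-9}$.

Problem sizes in the test suite and the acceptance script were chosen to
exercise every code path at desk scale: dimensionality and format checks
on 3+3-sequence fixtures, property suites on 20–200 random sequences, and
the end-to-end recovery runs on 50+50 fixtures with 876 fused features
and in-fold auto-selected MRMD.

# Known limitations

* Structural feature orders $n > 1$ and gram sizes $n > 3$ are out of
  scope (combinatorial growth with no fixed reference layout).
* MRMD's distance component is Euclidean only; mutual-information-based
  selection (mRMR) and wrapper elimination are deliberately not
  implemented.
* The SVM provides hard labels, not calibrated probabilities; multi-class
  problems and alternative kernels are out of scope.
* Real-data accuracy depends on externally generated PSSM and secondary
  structure profiles (database and tool versions), which the package
  parses but cannot produce.
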