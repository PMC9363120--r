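---
title: "Deconvolving cfDNA fragment-length distributions into source signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving cfDNA fragment-length distributions into source signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsig)
```

## The model

Cell-free DNA (cfDNA) in plasma is fragmented around nucleosomes, giving a
characteristic length distribution with a mono-nucleosome mode near 166 bp and
a di-nucleosome mode one nucleosome repeat further out. Tumor-derived cfDNA
(ctDNA) is systematically shorter: its mode is left-shifted, the 10-bp
periodicity below the main mode is amplified, and the di-nucleosome peak is
enlarged. A patient's observed fragment-length histogram is therefore
(approximately) a *mixture* of a small number of source-specific length
distributions — at minimum a hematopoietic background and a tumor source.

`fragsig` treats deconvolution of that mixture as non-negative matrix
factorization (NMF). Let $V$ be the $n \times L$ matrix of per-sample
fragment-length frequencies (each row a histogram scaled to sum to one, lengths
30–700 bp, $L = 671$). We seek non-negative $W$ ($n \times k$) and $H$
($k \times L$) minimizing the generalized Kullback–Leibler divergence

$$D(V \,\|\, WH) = \sum_{ij} V_{ij} \log\frac{V_{ij}}{(WH)_{ij}} - V_{ij} + (WH)_{ij},$$

which is the natural objective for count-derived frequencies (it is, up to
constants, the negative multinomial log-likelihood). Optimization uses the
standard multiplicative updates

$$H \leftarrow H \odot \frac{W^\top (V \oslash WH)}{W^\top \mathbf 1}, \qquad
  W \leftarrow W \odot \frac{(V \oslash WH) H^\top}{\mathbf 1 H^\top},$$

which provably never increase the loss. Because the objective is non-convex,
the fit is repeated from independent random initializations (`restarts`,
default 20) and the lowest-loss fit kept. Afterwards each row of $H$ and each
row of $W$ is rescaled to sum to one, so signatures are probability
distributions over length and each sample's weights are mixing proportions.
This rescaling changes the factors only by per-row positive constants; the
row-normalized reconstruction is invariant.

The entire procedure is unsupervised: no labels, no variants, no copy-number
input. The component with the **lowest mean fragment length** is taken to be
the tumor-related signature; its per-sample weight is the ctDNA-burden
estimate. For $k > 2$, the same rule applies unless the user supplies
reference signatures to match by cosine similarity.

## Fitting and methods

```{r fit, eval = FALSE}
sim <- simulate_cohort(n_samples = 50, depth = 1e6, seed = 1)
fit <- fl_nmf(normalize_rows(sim$matrix), k = 2, restarts = 20, seed = 1)
summary(fit)
plot(fit)                         # signature length profiles
w <- coef(fit)                    # per-sample mixing weights
ti <- tumor_signature_index(fit)  # lowest-mean-length component
predict(fit, new_counts)          # project unseen samples (W update only,
                                  # signatures held fixed)
```

`predict()`/`transform_weights()` run only the $W$ update with $H$ fixed, so
signatures learned on a training cohort can score held-out samples — the basis
of the hold-out experiment below.

## Tunable parameters

* `k` (components): a hyperparameter set in advance, default 2
  (background + tumor, or open + closed chromatin in bin-wise mode). No
  automatic selection is attempted.
* `restarts` (default 20): random initializations; more restarts can only
  lower the selected loss. Initial entries are uniform on $(0,1]$ scaled by
  $\sqrt{\bar V / k}$ so the initial reconstruction has the data's magnitude.
* `max_iter` (2000) and `tol` ($10^{-6}$ relative loss improvement): the
  stopping rule. The loss trace is retained on the fitted object so
  monotonicity is checkable.
* `eps` ($10^{-12}$): numerical floor inside the update quotients to avoid
  0/0 — standard KL-NMF practice; it is configurable and far below any
  frequency of interest.
* Fragment filters: minimum MAPQ 30 for both mates, soft/hard-clip rejection,
  excluded-region overlap (any overlap of either mate, ≥ 1 bp), retained
  lengths 30–700 bp. Each pair is counted once via the leftmost mate of a
  proper pair with positive template length; the fragment length is the
  aligner's absolute template length.
* Bin-wise mode: 250 kb default bins, fragments assigned by midpoint
  (symmetric; avoids double counting at bin edges), and bin QC keeping bins
  whose mean control fragment count lies within median ± 2·IQR (inclusive
  bounds, type-7 linear-interpolation quartiles — stated because the window
  depends on the quartile convention). Bins with fewer than 100 fragments
  yield `NA` features rather than noisy weights.
* Classifier: linear SVM with cost $C = 1$ and no inner tuning, features
  standardized with training-fold statistics, missing features imputed with
  training-fold means, stratified 10-fold cross-validation repeated 50 times,
  one AUC per repeat from pooled out-of-fold decision scores (stabler than
  averaging per-fold AUCs when folds are small).

## ctDNA fraction from driver variants

For validation against an orthogonal estimate, targeted-sequencing variant
observations are reduced to a per-sample ctDNA fraction: the highest-VAF
somatic mutation is the driver (if several VAFs lie within an absolute 0.02
of the maximum, their median is used — the ±2% window is read as absolute
percentage points, not relative); purity is $2\cdot\mathrm{VAF}$ without LOH
or $2/(1/\mathrm{VAF}+1)$ with LOH, clipped at 1 with a warning when VAF >
0.5 lacks an LOH annotation (whether such cases imply LOH is left to the
caller); and the ctDNA fraction adjusts purity $p$ for tumor ploidy $t$ as
$pt/(pt + (1-p)\cdot 2)$, with normal ploidy fixed at 2.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` draws each sample's counts as a multinomial of `depth`
fragments from $(1-w)\,p_{\mathrm{bg}} + w\,p_{\mathrm{tumor}}$ with known
per-sample tumor weight $w$. The source profiles are parametric: a Gaussian
main mode, a Gaussian di-nucleosome mode at +167 bp, and a comb of narrow
bumps every 10.4 bp (the helical repeat; configurable to 10.0) below the mode
with geometrically decaying amplitude. Defaults — background mode 166 bp
(sd 20), weak ladder (3%) and di-nucleosome peak (4%); tumor mode 145 bp
(sd 18), strong ladder (22%), enlarged di-nucleosome peak (10%) — were chosen
once to resemble published cfDNA length histograms and are not tuned
thereafter. `simulate_binned_cohort()` plays the same game per genomic bin
with open/closed chromatin profiles (open chromatin sheds shorter fragments)
and a known per-bin openness fraction, which doubles as the external
accessibility signal for rank-correlation checks.

The generator reproduces the *mixture structure* and *multinomial sampling
noise* of real cohorts. It does not emulate GC or mappability bias, batch
effects between library preparations, inter-individual variation in the
background source, sequence-dependent cleavage, or the fact that real tumor
length profiles vary between patients. Passing the recovery tests therefore
shows the estimator solves the inference problem it is designed for —
identifying mixture components and weights from length histograms at realistic
depths — not that any particular clinical accuracy will be attained on real
plasma data.

## Numerical and design choices

* Subsampling histograms to a fixed fragment count uses sequential
  multivariate-hypergeometric draws (sampling without replacement), the
  histogram-level equivalent of subsampling read pairs from an alignment.
* One master seed drives everything; per-restart and per-replicate seeds are
  derived deterministically by sampling child seeds, so experiments are
  reproducible and individually re-runnable.
* Degenerate inputs fail loudly: all-zero histogram rows cannot be normalized
  (they can be dropped explicitly), zero-variance vectors refuse to
  correlate, an empty long-fragment count makes the short/long ratio `NA`
  rather than infinite, and exact ties in the tumor-signature rule go to the
  lowest index with a warning.
* Permutation nulls for the classifier average over several independent label
  permutations rather than reusing one: a single permutation retains its
  chance alignment with the features (AUC standard deviation ≈ 0.04 at
  n = 200), which an average over permutations removes.
* When both mates of a pair cover a variant locus and disagree on the base,
  the pair is assigned to neither allele histogram; third alleles and
  deletions at the locus are likewise excluded and counted.
* Autosome-only analysis is a caller decision: `make_bins()` tiles whatever
  chromosome-size table it is given.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run entirely on synthetic cohorts:
the reference deep cohort (50 samples × 10⁶ fragments), 20 replicate shallow
cohorts (50 × 1000 fragments, 5 restarts), 20 train/test half-splits,
a 500-bin chromatin cohort at 10⁵ fragments/bin (20 restarts), and an
SVM null/separable pair at n = 200 with 10-fold × 50-repeat cross-validation.
These sizes make every check exact enough to be informative while keeping a
full run in the minutes range on one CPU.

## Known limitations

* NMF identifiability: when no sample is pure tumor, the recovered "tumor"
  signature is the extreme of the cohort's mixture fan, not necessarily the
  pure source; weights remain affinely related to truth (correlations are
  unaffected), but absolute weights can be compressed.
* `k` must be chosen by the user; model-selection criteria are out of scope.
* The SVM reports decision scores, not calibrated probabilities.
* LOH calling, ploidy estimation, variant calling and alignment preprocessing
  are upstream of this package and consumed as plain inputs.
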