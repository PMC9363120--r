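# fragsig

Unsupervised deconvolution of cell-free DNA (cfDNA) fragment-length
distributions into source-specific **fragment length signatures** and
per-sample mixing weights, for liquid-biopsy analysis.

## The problem

Plasma cfDNA is nucleosome-protected DNA with a characteristic length
distribution (mono-nucleosome mode ≈ 166 bp, di-nucleosome mode ≈ 332 bp).
Tumor-derived cfDNA (ctDNA) is shorter: left-shifted mode, amplified 10-bp
periodicity below the mode, enlarged di-nucleosome peak. A cancer patient's
histogram is a mixture of a hematopoietic background source and a tumor
source, with the tumor's mixing weight tracking ctDNA burden.

`fragsig` estimates both the source distributions and the per-sample weights
with **non-negative matrix factorization under the generalized
Kullback–Leibler loss**. With the samples-by-lengths frequency matrix $V$
(rows scaled to sum to one), it finds non-negative $W, H$ minimizing

$$D(V\|WH)=\sum_{ij} V_{ij}\log\frac{V_{ij}}{(WH)_{ij}}-V_{ij}+(WH)_{ij}$$

by multiplicative updates from random restarts, keeps the lowest-loss fit,
and rescales so each signature (row of $H$) and each weight vector (row of
$W$) sums to one. The component with the lowest mean fragment length is the
tumor signature; its weight is an estimate of the ctDNA fraction that needs
no variants, copy-number calls or labels. The same machinery applied to
histograms from 250 kb genomic bins (aggregated over healthy controls)
yields chromatin-state length signatures and per-bin features for
case/control classification with a linear SVM.

The package also provides: fragment-length extraction from paired-end BAMs
(MAPQ ≥ 30 for both mates, clip rejection, excluded-region filter, lengths
30–700 bp) with mutation-aware splitting at a variant locus; driver-VAF
ctDNA fractions (purity `2*VAF` without LOH, `2/(1/VAF+1)` with LOH, ploidy
adjustment); the short/long (100–150 / 151–220 bp) fragment ratio;
hypergeometric histogram subsampling; signature-stability and hold-out
experiments; and a fully seeded synthetic cohort generator with known ground
truth.

## Worked example

```r
library(fragsig)

# a synthetic cohort with known per-sample tumor weights
sim <- simulate_cohort(n_samples = 50, depth = 1e6, seed = 1)
fit <- fl_nmf(normalize_rows(sim$matrix), k = 2, restarts = 20, seed = 1)
fit
#> Fragment-length KL-NMF fit: 50 samples x 671 lengths, k = 2
#>   final KL loss 0.0101027 after 575 iterations (best of 20 restarts)
#>   signature mean lengths (bp): 155.7, 171.3; tumor-like: S1

ti <- tumor_signature_index(fit)        # S1: the short, tumor-like signature
correlate(coef(fit)[, ti], sim$truth$tumor_weight)
#> [1] 0.9999929
```

The two recovered signatures have mean lengths 155.7 bp and 171.3 bp; the
shorter one is the tumor-like component, and its per-sample weight matches
the true mixing weight with Pearson r > 0.999. Unseen samples are projected
onto fixed signatures with `predict(fit, new_counts)`.

Driver-variant ctDNA fractions from a variant table:

```r
v <- data.frame(sample = "pt1", vaf = c(0.40, 0.39, 0.10), loh = FALSE,
                tumor_ploidy = 2.4)
ctdna_from_variants(v)
#>   sample driver_vaf purity ctdna_fraction
#> 1    pt1      0.395   0.79      0.8186528
```

The two VAFs within 2 points of the maximum are medianed (0.395), purity is
`2*0.395 = 0.79`, and the ploidy-2.4 adjustment gives a ctDNA fraction of
0.819.

A thin CLI over the same functions ships at `inst/scripts/fragsig`
(`extract`, `matrix`, `subsample`, `nmf`, `transform`, `ctdna`,
`delfi-ratio`, `simulate`, `classify`).

See `vignettes/fragment-length-signatures.Rmd` for the model, parameter and
design documentation.

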