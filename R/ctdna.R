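#' Select the driver VAF for a sample
#'
#' The somatic mutation with the highest variant allele fraction is taken as
#' the clear driver; if several mutations lie within an absolute 0.02 window
#' of the maximum, the median of those VAFs is used instead.
#'
#' @param vafs numeric VAFs in (0, 1) for one sample.
#' @param window absolute window around the maximum (default 0.02, i.e. 2
#'   percentage points).
#' @return the selected driver VAF.
#' @examples
#' select_driver_vaf(c(0.40, 0.39, 0.10))  # 0.395
#' @export
select_driver_vaf <- function(vafs, window = 0.02) {
  if (!length(vafs)) stop_fatal("no VAF observations supplied")
  if (any(vafs <= 0 | vafs >= 1)) stop_fatal("VAFs must be in (0, 1)")
  m <- max(vafs)
  stats::median(vafs[vafs >= m - window])
}

#' Tumor cell purity from a driver VAF
#'
#' `purity = 2 * VAF` when the variant locus retains both alleles, or
#' `purity = 2 / (1/VAF + 1)` when the wild-type allele is lost (LOH). A
#' purity exceeding 1 (VAF > 0.5 without LOH) is clipped to 1 with a warning.
#'
#' @param vaf driver variant allele fraction in (0, 1).
#' @param loh logical: loss of heterozygosity at the variant locus.
#' @return tumor cell purity in (0, 1].
#' @examples
#' purity_from_vaf(0.25, loh = FALSE)  # 0.5
#' purity_from_vaf(0.5, loh = TRUE)    # 2/3
#' @export
purity_from_vaf <- function(vaf, loh = FALSE) {
  if (any(vaf <= 0 | vaf >= 1)) stop_fatal("VAF must be in (0, 1)")
  p <- ifelse(loh, 2 / (1 / vaf + 1), 2 * vaf)
  if (any(p > 1)) {
    warning("purity exceeds 1 (VAF > 0.5 without LOH); clipping to 1")
    p <- pmin(p, 1)
  }
  p
}

#' ctDNA fraction from tumor purity and ploidy
#'
#' The tumor's share of circulating DNA, adjusting purity for tumor ploidy:
#' \deqn{ctDNA = \frac{p \cdot t}{p \cdot t + (1 - p) \cdot 2}}
#' with tumor purity `p`, tumor ploidy `t`, normal purity `1 - p` and normal
#' ploidy fixed at 2.
#'
#' @param purity tumor cell purity in \[0, 1\].
#' @param tumor_ploidy average tumor genome copy number (> 0; default 2).
#' @return ctDNA fraction in \[0, 1\].
#' @examples
#' ctdna_fraction(0.5, tumor_ploidy = 3)  # 0.6
#' @export
ctdna_fraction <- function(purity, tumor_ploidy = 2) {
  if (any(purity < 0 | purity > 1)) stop_fatal("purity must be in [0, 1]")
  if (any(tumor_ploidy <= 0)) stop_fatal("tumor ploidy must be positive")
  purity * tumor_ploidy / (purity * tumor_ploidy + (1 - purity) * 2)
}

#' ctDNA fractions for a variant table
#'
#' Applies [select_driver_vaf()], [purity_from_vaf()] and [ctdna_fraction()]
#' per sample. A sample's LOH flag is taken from its selected (maximum-VAF)
#' variant.
#'
#' @param variants data.frame with columns `sample`, `vaf`, `loh` (logical or
#'   0/1) and optionally `tumor_ploidy` (default 2).
#' @return data.frame with one row per sample: `sample`, `driver_vaf`,
#'   `purity`, `ctdna_fraction`.
#' @export
ctdna_from_variants <- function(variants) {
  need <- c("sample", "vaf", "loh")
  if (!all(need %in% names(variants)))
    stop_fatal("variant table needs columns: ", paste(need, collapse = ", "))
  if (is.null(variants$tumor_ploidy)) variants$tumor_ploidy <- 2
  out <- lapply(split(variants, variants$sample), function(d) {
    v <- select_driver_vaf(d$vaf)
    top <- d[which.max(d$vaf), ]
    p <- purity_from_vaf(v, loh = as.logical(top$loh))
    data.frame(sample = top$sample, driver_vaf = v, purity = p,
               ctdna_fraction = ctdna_fraction(p, top$tumor_ploidy))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Short/long fragment ratio (DELFI ratio)
#'
#' Count of short fragments (100--150 bp, inclusive) divided by the count of
#' long fragments (151--220 bp, inclusive). A zero long-fragment count yields
#' `NA` with a warning rather than infinity, since empty genomic bins occur
#' routinely.
#'
#' @param hist a [length_histogram()] whose grid covers 100--220 bp.
#' @param short,long inclusive length ranges.
#' @return the ratio, or `NA` if the denominator is zero.
#' @export
delfi_ratio <- function(hist, short = c(100, 150), long = c(151, 220)) {
  lens <- hist_lengths(hist)
  if (min(lens) > short[1] || max(lens) < long[2])
    stop_fatal("histogram grid must cover ", short[1], "-", long[2], " bp")
  s <- sum(hist[lens >= short[1] & lens <= short[2]])
  l <- sum(hist[lens >= long[1] & lens <= long[2]])
  if (l == 0) {
    warning("zero long-fragment count; returning NA")
    return(NA_real_)
  }
  s / l
}

#' Pearson or Spearman correlation with strict variance checks
#'
#' Thin wrapper over [stats::cor()] with pairwise-complete handling of
#' missing values; zero variance in either vector is an error rather than
#' `NA`, since a silent `NA` would propagate through downstream reports.
#'
#' @param x,y numeric vectors of equal length (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return the correlation coefficient.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop_fatal("x and y differ in length")
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3) stop_fatal("need at least 3 complete pairs")
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    stop_fatal("zero variance in input")
  stats::cor(x[ok], y[ok], method = method)
}
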