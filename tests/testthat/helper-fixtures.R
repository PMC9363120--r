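# Shared fixtures, built once per test run and cached.
.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# Small cohort for fast unit tests.
fx_small_cohort <- function() fx_get("small_cohort", function() {
  simulate_cohort(n_samples = 16, depth = 5e4, seed = 7)
})

# The reference study-condition cohort (n = 50, depth 1e6) and its fit.
fx_big_cohort <- function() fx_get("big_cohort", function() {
  simulate_cohort(n_samples = 50, depth = 1e6, seed = 1)
})

fx_big_fit <- function() fx_get("big_fit", function() {
  fl_nmf(normalize_rows(fx_big_cohort()$matrix), k = 2, restarts = 20,
         seed = 1)
})

# ---- tiny alignment fixture -------------------------------------------------
# A hand-built SAM exercising every filter rule, converted to BAM at run time.
# Variant locus: chr1:5000 A>T.
#   pairA  clean pair, TLEN 166                      -> retained @166
#   pairB  one mate MAPQ 20                          -> rejected (mapq)
#   pairC  TLEN 729                                  -> rejected (length)
#   pairD  leftmost mate soft-clipped                -> rejected (clipped)
#   pairE  inside excluded region chr1:[10000,10100) -> rejected (excluded)
#   pairF  covers locus, reads ALT (T), TLEN 150     -> retained, mutated
#   pairG  covers locus, reads REF (A), TLEN 167     -> retained, wildtype
#   pairH  covers locus, reads G (third allele)      -> retained, neither
fx_sam_records <- function() {
  seqA <- strrep("A", 50)
  seqT20 <- paste0(strrep("A", 19), "T", strrep("A", 30))  # T at query pos 20
  seqG6 <- paste0(strrep("A", 5), "G", strrep("A", 44))    # G at query pos 6
  c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000000",
    sprintf("pairA\t99\tchr1\t1001\t60\t50M\t=\t1117\t166\t%s\t*", seqA),
    sprintf("pairA\t147\tchr1\t1117\t60\t50M\t=\t1001\t-166\t%s\t*", seqA),
    sprintf("pairB\t99\tchr1\t2001\t60\t50M\t=\t2117\t166\t%s\t*", seqA),
    sprintf("pairB\t147\tchr1\t2117\t20\t50M\t=\t2001\t-166\t%s\t*", seqA),
    sprintf("pairC\t99\tchr1\t3001\t60\t50M\t=\t3680\t729\t%s\t*", seqA),
    sprintf("pairC\t147\tchr1\t3680\t60\t50M\t=\t3001\t-729\t%s\t*", seqA),
    sprintf("pairD\t99\tchr1\t4001\t60\t5S45M\t=\t4117\t166\t%s\t*", seqA),
    sprintf("pairD\t147\tchr1\t4117\t60\t50M\t=\t4001\t-166\t%s\t*", seqA),
    sprintf("pairF\t99\tchr1\t4981\t60\t50M\t=\t5081\t150\t%s\t*", seqT20),
    sprintf("pairF\t147\tchr1\t5081\t60\t50M\t=\t4981\t-150\t%s\t*", seqA),
    sprintf("pairH\t99\tchr1\t4995\t60\t50M\t=\t5085\t140\t%s\t*", seqG6),
    sprintf("pairH\t147\tchr1\t5085\t60\t50M\t=\t4995\t-140\t%s\t*", seqA),
    sprintf("pairG\t99\tchr1\t4990\t60\t50M\t=\t5107\t167\t%s\t*", seqA),
    sprintf("pairG\t147\tchr1\t5107\t60\t50M\t=\t4990\t-167\t%s\t*", seqA),
    sprintf("pairE\t99\tchr1\t10050\t60\t50M\t=\t10150\t150\t%s\t*", seqA),
    sprintf("pairE\t147\tchr1\t10150\t60\t50M\t=\t10050\t-150\t%s\t*", seqA)
  )
}

fx_bam <- function() fx_get("bam", function() {
  sam <- tempfile(fileext = ".sam")
  writeLines(fx_sam_records(), sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE, indexDestination = TRUE)
})

fx_excluded_bed <- function() fx_get("bed", function() {
  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10000\t10100", bed)
  bed
})

fx_filters <- function() fragment_filters(
  excluded_regions = read_bed(fx_excluded_bed()))
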