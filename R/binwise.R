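#' Tile chromosomes into fixed-size genomic bins
#'
#' Non-overlapping bins of `bin_size` bp tile each chromosome; the terminal
#' bin of a chromosome may be shorter. Coordinates are 0-based half-open and
#' the bin identifier is `"chrom:start-end"`.
#'
#' @param chrom_sizes data.frame with columns `chrom` and `size` (or a path
#'   to a two-column chrom.sizes TSV without header).
#' @param bin_size bin width in bp (default 250000).
#' @return data.frame with columns `chrom`, `start`, `end`, `bin_id`.
#' @examples
#' make_bins(data.frame(chrom = "chr1", size = 600000), 250000)
#' @export
make_bins <- function(chrom_sizes, bin_size = 250000) {
  if (is.character(chrom_sizes)) {
    chrom_sizes <- utils::read.table(chrom_sizes, sep = "\t",
                                     col.names = c("chrom", "size"),
                                     stringsAsFactors = FALSE)
  }
  if (bin_size <= 0) stop_fatal("bin_size must be positive")
  if (any(chrom_sizes$size <= 0)) stop_fatal("chromosome sizes must be positive")
  out <- lapply(seq_len(nrow(chrom_sizes)), function(i) {
    sz <- chrom_sizes$size[i]
    starts <- seq(0, sz - 1, by = bin_size)
    ends <- pmin(starts + bin_size, sz)
    data.frame(chrom = chrom_sizes$chrom[i], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$bin_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out
}

#' Per-bin fragment-length histograms for one sample
#'
#' Applies the same pair filters as [extract_fragment_lengths()] and assigns
#' each retained fragment to exactly one bin by its midpoint. Empty bins are
#' kept as zero rows (they are removed later by QC or normalization).
#'
#' @param bam indexed paired-end BAM.
#' @param bins data.frame from [make_bins()].
#' @param filters a [fragment_filters()] object.
#' @return count matrix, rows = bin ids, columns = fragment lengths; the
#'   `skipped_chrom` attribute counts fragments on chromosomes absent from
#'   the bin set.
#' @export
binned_histograms <- function(bam, bins, filters = fragment_filters()) {
  fr <- .retained_fragments(bam, filters)
  grid <- filters$min_length:filters$max_length
  m <- matrix(0, nrow(bins), length(grid),
              dimnames = list(bins$bin_id, as.character(grid)))
  skipped <- 0L
  if (nrow(fr)) {
    # fragment midpoint in 0-based coordinates
    mid <- (fr$pos - 1L) + fr$length %/% 2L
    bin_idx <- rep(NA_integer_, nrow(fr))
    for (ch in unique(fr$chrom)) {
      sel <- fr$chrom == ch
      b <- which(bins$chrom == ch)
      if (!length(b)) { skipped <- skipped + sum(sel); next }
      j <- findInterval(mid[sel], bins$start[b])
      j[j < 1 | mid[sel] >= max(bins$end[b])] <- NA
      bin_idx[sel] <- b[j]
    }
    keep <- !is.na(bin_idx)
    skipped <- skipped + sum(fr$chrom %in% bins$chrom & !keep)
    if (any(keep)) {
      tab <- table(factor(bin_idx[keep], levels = seq_len(nrow(bins))),
                   factor(match(fr$length[keep], grid),
                          levels = seq_along(grid)))
      m <- m + as.matrix(unclass(tab))
      dimnames(m) <- list(bins$bin_id, as.character(grid))
    }
  }
  attr(m, "normalized") <- FALSE
  attr(m, "skipped_chrom") <- skipped
  m
}

#' Sum per-bin histograms across control samples
#'
#' Element-wise sum of single-sample bin matrices sharing one bin set and
#' length grid, yielding the aggregated-control matrix whose rows are
#' factorized into chromatin-state signatures.
#'
#' @param per_sample list of bin count matrices from [binned_histograms()] or
#'   [simulate_binned_cohort()].
#' @return aggregated count matrix.
#' @export
aggregate_controls <- function(per_sample) {
  if (!length(per_sample)) stop_fatal("no bin matrices supplied")
  dn <- dimnames(per_sample[[1]])
  for (m in per_sample)
    if (!identical(dimnames(m), dn))
      stop_fatal("bin sets or length grids differ between samples")
  out <- Reduce(`+`, lapply(per_sample, unclass))
  dimnames(out) <- dn
  attr(out, "normalized") <- FALSE
  out
}

#' Bin quality control by control fragment depth
#'
#' Flags bins with unusual control coverage, which typically indicates
#' mapping artifacts. The mean fragment count per bin across control samples
#' is computed; bins whose mean lies outside
#' `[median - 2 * IQR, median + 2 * IQR]` (bounds inclusive; type-7
#' linear-interpolation quartiles) are excluded.
#'
#' @param per_sample_controls list of (>= 2) single-sample bin count matrices.
#' @return character vector of retained bin ids; the per-bin means are
#'   attached as the `bin_means` attribute.
#' @export
qc_bins <- function(per_sample_controls) {
  if (length(per_sample_controls) < 2)
    stop_fatal("bin QC needs at least 2 control samples")
  totals <- vapply(per_sample_controls, rowSums,
                   numeric(nrow(per_sample_controls[[1]])))
  means <- rowMeans(totals)
  med <- stats::median(means)
  iqr <- stats::IQR(means, type = 7)
  keep <- means >= med - 2 * iqr & means <= med + 2 * iqr
  out <- rownames(per_sample_controls[[1]])[keep]
  attr(out, "bin_means") <- means
  out
}

#' Chromatin-state fragment-length signatures from aggregated bins
#'
#' Fits the KL-loss factorization to the aggregated-control bin matrix
#' (rows = genomic bins instead of samples), after restricting to QC-passing
#' bins and dropping empty rows. The resulting signatures are length profiles
#' of chromatin states (open chromatin sheds shorter fragments), and each
#' bin's weights describe its state mixture.
#'
#' @param aggregated aggregated count matrix from [aggregate_controls()].
#' @param k components (default 2: open/closed).
#' @param kept_bins bin ids surviving [qc_bins()], or `NULL` for all.
#' @param restarts,seed,... passed to [fl_nmf()] (default 20 restarts).
#' @return an [fl_nmf()] fit on the bin matrix.
#' @export
binwise_signatures <- function(aggregated, k = 2, kept_bins = NULL,
                               restarts = 20, seed = NULL, ...) {
  if (!is.null(kept_bins))
    aggregated <- aggregated[rownames(aggregated) %in% kept_bins, ,
                             drop = FALSE]
  attr(aggregated, "normalized") <- FALSE
  x <- normalize_rows(aggregated, drop_zero = TRUE)
  fl_nmf(x, k = k, restarts = restarts, seed = seed, ...)
}

#' Per-bin signature-weight features for one sample
#'
#' Projects every kept bin of a single-sample bin matrix onto a fixed
#' signature set and reports the selected component's weight, yielding one
#' feature per bin for classification. Bins with fewer fragments than
#' `min_fragments` give `NA` rather than a noisy weight.
#'
#' @param sample_bins single-sample bin count matrix.
#' @param H row-stochastic signature matrix (bin-wise or sample-wise
#'   training).
#' @param component which component's weight to report (default 1).
#' @param kept_bins bin ids surviving QC, or `NULL` for all.
#' @param min_fragments minimum bin depth for a usable weight (default 100).
#' @param seed passed to [transform_weights()].
#' @return named numeric vector, one weight in `[0, 1]` (or `NA`) per kept
#'   bin.
#' @export
per_bin_weight_features <- function(sample_bins, H, component = 1,
                                    kept_bins = NULL, min_fragments = 100,
                                    seed = NULL) {
  H <- as.matrix(H)
  if (ncol(sample_bins) != ncol(H)) stop_fatal("length grids differ")
  if (!is.null(kept_bins))
    sample_bins <- sample_bins[rownames(sample_bins) %in% kept_bins, ,
                               drop = FALSE]
  totals <- rowSums(sample_bins)
  out <- rep(NA_real_, nrow(sample_bins))
  names(out) <- rownames(sample_bins)
  usable <- totals >= min_fragments
  if (any(usable)) {
    x <- sample_bins[usable, , drop = FALSE] / totals[usable]
    attr(x, "normalized") <- TRUE
    w <- transform_weights(x, H, seed = seed)
    out[usable] <- w[, component]
  }
  out
}

#' Rank correlation between per-bin values and an external bin signal
#'
#' Spearman correlation between a per-bin quantity (signature weight or
#' short/long ratio) and an external per-bin signal such as chromatin
#' accessibility, matched by bin id.
#'
#' @param bin_values named numeric vector (names = bin ids).
#' @param signal data.frame with columns `bin_id` and `value`.
#' @param method correlation method (default `"spearman"`).
#' @return the correlation coefficient over bins present in both inputs.
#' @export
bin_signal_correlation <- function(bin_values, signal, method = "spearman") {
  common <- intersect(names(bin_values), signal$bin_id)
  if (length(common) < 3) stop_fatal("fewer than 3 bins in common")
  correlate(bin_values[common],
            signal$value[match(common, signal$bin_id)], method = method)
}
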