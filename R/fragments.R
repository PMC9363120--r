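#' Fragment-length extraction filters
#'
#' Filter settings applied to read pairs before their fragment lengths are
#' counted: minimum mapping quality for both mates, retained length range,
#' rejection of soft/hard-clipped alignments, and an excluded-regions set
#' (e.g. the ENCODE excluded regions) that neither mate may overlap.
#'
#' @param min_mapq minimum mapping quality for both mates (default 30).
#' @param min_length,max_length retained fragment-length range in bp
#'   (defaults 30 and 700).
#' @param excluded_regions `GRanges` of regions to exclude, or `NULL`; see
#'   [read_bed()].
#' @param reject_clipped drop pairs with soft or hard clips in either mate.
#' @param include_single_end also count unpaired records (e.g. adapter-merged
#'   reads) using their aligned query length; off by default.
#' @return a `fragment_filters` list.
#' @export
fragment_filters <- function(min_mapq = 30, min_length = 30, max_length = 700,
                             excluded_regions = NULL, reject_clipped = TRUE,
                             include_single_end = FALSE) {
  if (min_length <= 0 || min_length > max_length)
    stop_fatal("need 0 < min_length <= max_length")
  if (min_mapq < 0) stop_fatal("min_mapq must be non-negative")
  structure(list(min_mapq = min_mapq, min_length = min_length,
                 max_length = max_length,
                 excluded_regions = excluded_regions,
                 reject_clipped = reject_clipped,
                 include_single_end = include_single_end),
            class = "fragment_filters")
}

#' Read a BED file of excluded regions
#'
#' BED intervals are 0-based half-open; the returned `GRanges` is 1-based
#' closed, the conversion happening only here.
#'
#' @param path BED file (first three columns used).
#' @return a `GRanges` object.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  GenomicRanges::GRanges(df[[1]],
                         IRanges::IRanges(start = df[[2]] + 1L, end = df[[3]]))
}

# Reference-space width consumed by a CIGAR string (M/D/N/=/X ops).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(0L)
    ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
    n <- as.integer(sub("[A-Z=]$", "", ops))
    op <- sub("^\\d+", "", ops)
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Query (read) index corresponding to 1-based reference position `refpos`
# for an alignment starting at `pos` with the given CIGAR. Returns the query
# index, 0 if the position falls in a deletion/skip, NA if not covered.
query_index_at <- function(cigar, pos, refpos) {
  if (refpos < pos) return(NA_integer_)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  rpos <- pos; qpos <- 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      if (refpos < rpos + n[i]) return(qpos + (refpos - rpos))
      rpos <- rpos + n[i]; qpos <- qpos + n[i]
    } else if (op[i] %in% c("D", "N")) {
      if (refpos < rpos + n[i]) return(0L)
      rpos <- rpos + n[i]
    } else if (op[i] %in% c("I", "S")) {
      qpos <- qpos + n[i]
    } # H, P consume nothing here
    if (rpos > refpos) break
  }
  NA_integer_
}

# Scan a BAM and return the retained fragments as a data.frame
# (qname, chrom, pos = leftmost 1-based start, length), with per-filter
# rejection counters attached as the "counters" attribute. Pair-level
# filters see both mates; a pair is rejected once, by the first failing
# filter in the order mapq < clipped < excluded-region < length.
.retained_fragments <- function(bam, filters, what_extra = character(0)) {
  if (!file.exists(bam)) stop_fatal("cannot read alignment file: ", bam)
  bf <- Rsamtools::BamFile(bam)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  what <- unique(c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize",
                   what_extra))
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(
    flag = flag, what = what))[[1]]
  paired <- bitwAnd(res$flag, 1L) > 0L
  proper <- bitwAnd(res$flag, 2L) > 0L
  if (!any(paired) && length(res$flag) && !filters$include_single_end)
    stop_fatal("alignment file ", bam, " contains no paired-end records; ",
               "set include_single_end = TRUE for merged single-end data")

  keep <- paired & proper
  df <- data.frame(qname = res$qname[keep], chrom = as.character(res$rname[keep]),
                   pos = res$pos[keep], mapq = res$mapq[keep],
                   cigar = res$cigar[keep], isize = res$isize[keep],
                   stringsAsFactors = FALSE)
  for (w in what_extra) df[[w]] <- as.character(res[[w]][keep])
  counters <- c(mapq = 0L, clipped = 0L, excluded_region = 0L, length = 0L,
                mate_missing = 0L)

  # pair-level summaries keyed by qname
  minq <- tapply(df$mapq, df$qname, min)
  clip <- tapply(grepl("[SH]", df$cigar), df$qname, any)
  nrec <- table(df$qname)
  excl <- logical(0)
  if (!is.null(filters$excluded_regions) && nrow(df)) {
    ends <- df$pos + cigar_ref_width(df$cigar) - 1L
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos, pmax(ends, df$pos)))
    hit <- GenomicRanges::countOverlaps(gr, filters$excluded_regions) > 0
    excl <- tapply(hit, df$qname, any)
  }

  anchors <- df[df$isize > 0, , drop = FALSE]
  ok <- logical(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    q <- anchors$qname[i]
    if (nrec[[q]] < 2L) { counters["mate_missing"] <- counters["mate_missing"] + 1L; next }
    if (minq[[q]] < filters$min_mapq) { counters["mapq"] <- counters["mapq"] + 1L; next }
    if (filters$reject_clipped && clip[[q]]) { counters["clipped"] <- counters["clipped"] + 1L; next }
    if (length(excl) && excl[[q]]) { counters["excluded_region"] <- counters["excluded_region"] + 1L; next }
    len <- abs(anchors$isize[i])
    if (len < filters$min_length || len > filters$max_length) {
      counters["length"] <- counters["length"] + 1L; next
    }
    ok[i] <- TRUE
  }
  out <- anchors[ok, , drop = FALSE]
  out$length <- abs(out$isize)

  if (filters$include_single_end) {
    se <- !paired
    qlen <- vapply(res$cigar[se], function(cg) {
      ops <- regmatches(cg, gregexpr("\\d+[MIDNSHP=X]", cg))[[1]]
      n <- as.integer(sub("[A-Z=]$", "", ops))
      op <- sub("^\\d+", "", ops)
      sum(n[op %in% c("M", "I", "S", "=", "X")])
    }, integer(1), USE.NAMES = FALSE)
    se_df <- data.frame(qname = res$qname[se], chrom = as.character(res$rname[se]),
                        pos = res$pos[se], mapq = res$mapq[se],
                        cigar = res$cigar[se], isize = 0L,
                        stringsAsFactors = FALSE)
    for (w in what_extra) se_df[[w]] <- as.character(res[[w]][se])
    se_df$length <- qlen
    se_ok <- se_df$mapq >= filters$min_mapq &
      (!filters$reject_clipped | !grepl("[SH]", se_df$cigar)) &
      se_df$length >= filters$min_length & se_df$length <= filters$max_length
    out <- rbind(out, se_df[se_ok, names(out), drop = FALSE])
  }

  attr(out, "counters") <- counters
  attr(out, "total_pairs") <- nrow(anchors)
  out
}

#' Extract a filtered fragment-length histogram from a paired-end BAM
#'
#' Each retained read pair contributes one count at its fragment length (the
#' absolute template length reported by the aligner), counted once via the
#' leftmost mate of a proper pair. Pairs are rejected when either mate has
#' mapping quality below the threshold, carries soft/hard clips, or overlaps
#' an excluded region by at least 1 bp, or when the length falls outside the
#' retained range.
#'
#' @param bam path to a coordinate-sorted, indexed, deduplicated paired-end
#'   BAM.
#' @param filters a [fragment_filters()] object.
#' @param label histogram label (default: the file name).
#' @return a [length_histogram()] on `min_length:max_length`; attribute
#'   `counters` holds per-filter rejection counts and `total_pairs` the pair
#'   count before filtering.
#' @export
extract_fragment_lengths <- function(bam, filters = fragment_filters(),
                                     label = basename(bam)) {
  fr <- .retained_fragments(bam, filters)
  grid <- filters$min_length:filters$max_length
  counts <- tabulate(match(fr$length, grid), nbins = length(grid))
  h <- length_histogram(counts, grid, label = label)
  if (sum(counts) == 0) warning("no fragments retained from ", bam)
  attr(h, "counters") <- attr(fr, "counters")
  attr(h, "total_pairs") <- attr(fr, "total_pairs")
  h
}

#' Split fragment lengths by allele at a variant locus
#'
#' Among retained pairs physically covering the locus, those reading the
#' alternate allele go to the `mutated` histogram and those reading the
#' reference allele to `wildtype`. Pairs showing a third allele or a deletion
#' at the locus, or whose two mates disagree, are counted in neither (their
#' number is reported in the `discarded` attribute).
#'
#' @param bam indexed paired-end BAM.
#' @param chrom,position,ref,alt the variant locus (1-based position; single
#'   bases).
#' @param filters a [fragment_filters()] object.
#' @return list with `mutated` and `wildtype` [length_histogram()]s.
#' @export
split_lengths_at_variant <- function(bam, chrom, position, ref, alt,
                                     filters = fragment_filters()) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T")) || ref == alt)
    stop_fatal("ref and alt must be distinct single bases")
  fr <- .retained_fragments(bam, filters, what_extra = "seq")
  grid <- filters$min_length:filters$max_length
  mut <- wt <- integer(length(grid))
  discarded <- 0L
  # base call per retained pair: inspect every mate record covering the locus
  res <- .mate_records(bam, filters)
  res <- res[res$qname %in% fr$qname & res$chrom == chrom, , drop = FALSE]
  if (nrow(res)) {
    res$end <- res$pos + cigar_ref_width(res$cigar) - 1L
    res <- res[res$pos <= position & res$end >= position, , drop = FALSE]
  }
  if (!nrow(res)) {
    warning("variant locus not covered by any retained pair")
  } else {
    base_by_pair <- tapply(seq_len(nrow(res)), res$qname, function(ix) {
      bases <- vapply(ix, function(i) {
        qi <- query_index_at(res$cigar[i], res$pos[i], position)
        if (is.na(qi)) return(NA_character_)
        if (qi == 0L) return("-")  # deletion at locus
        substr(res$seq[i], qi, qi)
      }, character(1))
      bases <- unique(toupper(bases[!is.na(bases)]))
      if (length(bases) != 1L) "?" else bases  # mate disagreement -> "?"
    })
    lens <- fr$length[match(names(base_by_pair), fr$qname)]
    for (i in seq_along(base_by_pair)) {
      b <- base_by_pair[[i]]
      j <- match(lens[i], grid)
      if (is.na(j)) next
      if (b == alt) mut[j] <- mut[j] + 1L
      else if (b == ref) wt[j] <- wt[j] + 1L
      else discarded <- discarded + 1L
    }
  }
  out <- list(mutated = length_histogram(mut, grid, label = "mutated"),
              wildtype = length_histogram(wt, grid, label = "wildtype"))
  attr(out, "discarded") <- discarded
  out
}

# All primary records (both mates) with qname/chrom/pos/cigar/seq.
.mate_records <- function(bam, filters) {
  bf <- Rsamtools::BamFile(bam)
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE,
                                 isDuplicate = FALSE)
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "cigar", "seq")))[[1]]
  data.frame(qname = res$qname, chrom = as.character(res$rname),
             pos = res$pos, cigar = res$cigar,
             seq = as.character(res$seq), stringsAsFactors = FALSE)
}
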