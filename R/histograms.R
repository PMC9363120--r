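#' Fragment-length histogram
#'
#' A length histogram is a named integer vector of fragment counts on a
#' contiguous length grid (default 30--700 bp, the range retained after
#' filtering), with the sample or bin identifier stored as the `label`
#' attribute.
#'
#' @param counts non-negative integer counts, one per grid length.
#' @param lengths the length grid (strictly increasing, contiguous integers).
#' @param label sample or genomic-bin identifier.
#' @return an object of class `length_histogram`: a named numeric vector of
#'   counts whose names are the lengths.
#' @examples
#' h <- length_histogram(c(5, 0, 2), lengths = 166:168, label = "s1")
#' sum(h)
#' @export
length_histogram <- function(counts, lengths = 30:700, label = "sample") {
  lengths <- as.integer(lengths)
  if (length(counts) != length(lengths))
    stop_fatal("counts and lengths differ in length")
  if (any(counts < 0) || anyNA(counts))
    stop_fatal("counts must be non-negative and complete")
  if (length(lengths) > 1L && any(diff(lengths) != 1L))
    stop_fatal("length grid must be contiguous and increasing")
  structure(as.numeric(counts), names = as.character(lengths),
            label = label, class = "length_histogram")
}

hist_lengths <- function(hist) as.integer(names(hist))
hist_label   <- function(hist) attr(hist, "label") %||% "sample"

#' @export
print.length_histogram <- function(x, ...) {
  l <- hist_lengths(x)
  cat(sprintf("<length_histogram> %s: %d fragments on grid %d..%d bp\n",
              hist_label(x), round(sum(x)), min(l), max(l)))
  invisible(x)
}

#' Assemble histograms into a samples-by-lengths count matrix
#'
#' Rows are samples (or genomic bins), columns are fragment lengths. All
#' histograms must share one length grid and have distinct labels.
#'
#' @param histograms list of [length_histogram()] objects.
#' @return numeric count matrix with row names = labels and column names =
#'   lengths; attribute `normalized` is `FALSE`.
#' @export
assemble_matrix <- function(histograms) {
  if (!length(histograms)) stop_fatal("no histograms supplied")
  grids <- lapply(histograms, hist_lengths)
  if (!all(vapply(grids, identical, logical(1), grids[[1]])))
    stop_fatal("histograms are on different length grids")
  labels <- vapply(histograms, hist_label, character(1))
  if (anyDuplicated(labels))
    stop_fatal("duplicate histogram labels: ",
               paste(unique(labels[duplicated(labels)]), collapse = ", "))
  m <- do.call(rbind, lapply(histograms, as.numeric))
  dimnames(m) <- list(labels, as.character(grids[[1]]))
  attr(m, "normalized") <- FALSE
  m
}

matrix_lengths <- function(m) as.integer(colnames(m))

is_normalized <- function(m) isTRUE(attr(m, "normalized"))

#' Row-normalize a count matrix to per-sample length frequencies
#'
#' Divides each row by its sum so rows are probability distributions over
#' fragment length. All-zero rows are dropped with a warning when
#' `drop_zero = TRUE`, otherwise they are an error naming the offending rows.
#'
#' @param m count matrix from [assemble_matrix()] (rows = samples or bins).
#' @param drop_zero drop all-zero rows instead of failing.
#' @return row-stochastic matrix; attribute `normalized` is `TRUE`.
#' @export
normalize_rows <- function(m, drop_zero = FALSE) {
  if (is_normalized(m)) stop_fatal("matrix is already row-normalized")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    bad <- rownames(m)[rs == 0] %||% which(rs == 0)
    if (drop_zero) {
      warning("dropping all-zero rows: ", paste(bad, collapse = ", "))
      m <- m[rs > 0, , drop = FALSE]
      rs <- rs[rs > 0]
    } else {
      stop_fatal("all-zero rows cannot be normalized: ",
                 paste(bad, collapse = ", "))
    }
  }
  out <- m / rs
  attr(out, "normalized") <- TRUE
  out
}

#' Subsample a histogram to a fixed number of fragments
#'
#' Draws `n` fragments without replacement from the fragments the histogram
#' counts, i.e. a multivariate hypergeometric draw. This is the histogram-level
#' equivalent of subsampling a fixed number of read pairs from an alignment
#' file, since fragment lengths are exchangeable given the histogram.
#'
#' @param hist a [length_histogram()].
#' @param n number of fragments to keep, `0 < n <= sum(hist)`.
#' @param seed integer seed for reproducibility.
#' @return a [length_histogram()] with total `n`.
#' @export
subsample_histogram <- function(hist, n, seed = NULL) {
  total <- sum(hist)
  if (n <= 0) stop_fatal("n must be positive")
  if (n > total) stop_fatal("n exceeds histogram total (", total, ")")
  if (n == total) return(hist)
  counts <- as.numeric(hist)
  out <- numeric(length(counts))
  with_seed(seed, {
    remaining <- total   # fragments not yet considered
    left <- n            # fragments still to draw
    for (i in seq_along(counts)) {
      if (left == 0) break
      if (counts[i] == 0) { remaining <- remaining - 0; next }
      # number drawn from cell i given what is left: hypergeometric
      x <- rhyper(1, counts[i], remaining - counts[i], left)
      out[i] <- x
      left <- left - x
      remaining <- remaining - counts[i]
    }
  })
  length_histogram(out, hist_lengths(hist), label = hist_label(hist))
}

#' Subsample every row of a count matrix
#'
#' @param m count matrix (rows = samples).
#' @param n fragments per row.
#' @param seed master seed; per-row seeds are derived from it.
#' @return count matrix with all row sums equal to `n`.
#' @export
subsample_matrix <- function(m, n, seed = NULL) {
  seeds <- derive_seeds(seed, nrow(m))
  grid <- matrix_lengths(m)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    h <- length_histogram(m[i, ], grid, label = rownames(m)[i])
    as.numeric(subsample_histogram(h, n, seed = seeds[[i]]))
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- dimnames(m)
  attr(out, "normalized") <- FALSE
  out
}

#' Read / write histogram matrices as TSV
#'
#' The on-disk dialect is a tab-separated table whose first column is `label`
#' and whose remaining column headers are the integer fragment lengths; no
#' quoting. Round trips are exact for count matrices.
#'
#' @param m matrix to write.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param normalized mark the matrix read back as row-normalized.
#' @export
read_matrix_tsv <- function(path, normalized = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (colnames(df)[1] != "label") stop_fatal("first column must be 'label'")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$label)
  if (length(colnames(m)) > 1L && any(diff(as.integer(colnames(m))) != 1L))
    stop_fatal("length grid in ", path, " is not contiguous")
  attr(m, "normalized") <- normalized
  m
}

#' Write a single histogram as two-column TSV (length, count)
#' @param hist a [length_histogram()].
#' @param path file path.
#' @export
write_histogram_tsv <- function(hist, path) {
  utils::write.table(
    data.frame(length = hist_lengths(hist), count = as.numeric(hist)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @param label label for the histogram read back.
#' @export
read_histogram_tsv <- function(path, label = basename(path)) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  length_histogram(df$count, df$length, label = label)
}
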