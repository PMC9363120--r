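#' @keywords internal
#' @importFrom stats coef fitted residuals predict simulate rhyper
#' @importFrom utils read.table write.table
"_PACKAGE"

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seeds for restarts / replicates, all < 2^31.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list(with_seed(seed, sample.int(.Machine$integer.max - 1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fatal <- function(...) stop(..., call. = FALSE)
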