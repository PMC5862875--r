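# Internal helpers: seed substreams, argument checks, quantile convention.

#' Derive a reproducible substream seed from a root seed and a stream name
#'
#' All stochastic stages draw their RNG state from one root seed through
#' named substreams, so that re-running a single stage reproduces exactly
#' what the full pipeline would have fed it.
#'
#' @param seed Integer root seed.
#' @param stream Character stream name (e.g. `"depths"`, `"sv"`).
#' @return An integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
#' @examples
#' substream_seed(1L, "depths")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps products < 2^53
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  as.integer((h + (abs(seed) %% m) * 48271) %% m)
}

# Evaluate expr with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shared quantile convention: linear interpolation between order statistics
# (type 7). Q1/median/Q3 values are reported downstream, so the convention
# is fixed here once.
mm_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE, na.rm = TRUE)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_in <- function(x, lo, hi, name, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s, got %s",
      name, if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

SEX_CHROMS <- c("chrX", "chrY", "X", "Y")

is_autosome <- function(chrom) !(chrom %in% SEX_CHROMS)
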