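#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm rnorm runif rbinom setNames quantile sd
#' @importFrom utils head read.delim write.table
NULL

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
# All simulator determinism flows through this single point.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Centred moving average with shrinking window at the edges, so the smoothed
# track has the same length as the input and no boundary artefacts.
moving_average <- function(x, window) {
  stopifnot(window >= 1)
  if (window == 1L) return(x)
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# 0-based half-open interval helpers; GTF conversion happens only in io.R.
stopifnot_intervals <- function(start, end, what = "interval") {
  bad <- which(!(end > start))
  if (length(bad)) {
    stop(sprintf("malformed %s: end <= start at record(s) %s", what,
                 paste(head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
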