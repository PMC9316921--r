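# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so simulations never perturb the user's session.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# stop() without the call, with sprintf formatting.
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Collapse a character vector for error messages, truncating long lists.
oxford <- function(x, max = 5L) {
  x <- as.character(x)
  if (length(x) > max) {
    x <- c(x[seq_len(max)], sprintf("... (%d more)", length(x) - max))
  }
  paste(x, collapse = ", ")
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

is_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
}

# Row-wise sample standard deviation (n - 1 denominator) of a numeric matrix;
# returns 0 for single-column input by convention.
row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2L) {
    return(setNames(rep(0, nrow(m)), rownames(m)))
  }
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}
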