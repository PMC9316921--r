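# Cross-reference correlation: match predicted genes to an external
# expression table by exact symbol, drop extreme upper outliers by the
# Q3 + k*IQR rule, and report the Pearson correlation test.

#' t statistic of a Pearson correlation coefficient
#'
#' Closed form behind every printed correlation test:
#' `t = r * sqrt(df) / sqrt(1 - r^2)` with `df = n - 2`.
#'
#' @param r Correlation coefficient(s), strictly inside (-1, 1).
#' @param df Degrees of freedom, integer >= 1.
#' @return The t statistic(s).
#' @examples
#' t_from_r(0.218, 85) # ~ 2.059
#' t_from_r(0.478, 78) # ~ 4.809
#' @export
t_from_r <- function(r, df) {
  if (!is.numeric(r) || any(!is.finite(r)) || any(abs(r) >= 1)) {
    abort("`r` must be strictly inside (-1, 1)")
  }
  if (!is.numeric(df) || any(!is.finite(df)) || any(df < 1) ||
      any(df != round(df))) {
    abort("`df` must be integer degrees of freedom >= 1")
  }
  r * sqrt(df) / sqrt(1 - r^2)
}

#' Pearson correlation test
#'
#' Sample Pearson coefficient with the usual t test: `df = n - 2`,
#' `t = r * sqrt(df) / sqrt(1 - r^2)`, two-sided p from the t distribution.
#' A numerically perfect correlation is reported with `t = +/-Inf` and
#' `p = 0` rather than an error, so toy fixtures with exact linear
#' relations remain usable.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with non-zero
#'   variance.
#' @return List with elements `r`, `df`, `t`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    abort("`x` and `y` must be numeric vectors of equal length")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite")
  }
  n <- length(x)
  if (n < 3L) {
    abort("need at least 3 pairs for a correlation test (got %d)", n)
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("zero variance in %s", if (sd(x) == 0) "`x`" else "`y`")
  }
  r <- cor(x, y)
  df <- n - 2L
  if (1 - r^2 < 8 * .Machine$double.eps) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- t_from_r(r, df)
    p <- 2 * pt(-abs(t), df)
  }
  list(r = r, df = df, t = t, p_value = p, n = n)
}

#' Match predicted genes to a reference expression table
#'
#' Inner join on exact (case-sensitive) gene symbol; only genes with status
#' `"predicted"` enter; pairs are returned sorted by symbol so downstream
#' results are order-independent.
#'
#' @param predictions A [target_prediction()] table.
#' @param reference Data frame with columns `gene` and `value` (see
#'   [read_reference_table()]); duplicate symbols are an error.
#' @return Data frame with columns `gene`, `predicted`, `reference`.
#' @export
match_gene_pairs <- function(predictions, reference) {
  predictions <- target_prediction(predictions)
  if (!is.data.frame(reference) ||
      !all(c("gene", "value") %in% names(reference))) {
    abort("`reference` must have columns gene and value")
  }
  ref_gene <- as.character(reference$gene)
  if (anyDuplicated(ref_gene)) {
    abort("duplicate gene symbol(s) in reference: %s",
          oxford(unique(ref_gene[duplicated(ref_gene)])))
  }
  kept <- predictions[predictions$status == "predicted", , drop = FALSE]
  common <- sort(intersect(kept$gene, ref_gene))
  if (length(common) == 0L) {
    abort("no gene symbols shared between predictions and reference")
  }
  data.frame(
    gene = common,
    predicted = kept$predicted_mean[match(common, kept$gene)],
    reference = as.numeric(reference$value)[match(common, ref_gene)],
    stringsAsFactors = FALSE
  )
}

#' Indices retained by the upper-IQR outlier rule
#'
#' Removes exactly the entries greater than `Q3 + k * IQR`, where the
#' quartiles use linear interpolation between order statistics at positions
#' `1 + q * (n - 1)` (the mainstream default; `type = 7`). With `k = Inf`
#' nothing is ever removed.
#'
#' @param values Numeric vector of length >= 4 (quartiles are ill-defined
#'   below that).
#' @param k Positive multiplier of the interquartile range; the
#'   conservative screen for extreme values uses `k = 3`.
#' @return Integer vector of retained indices; attributes `cutoff` and
#'   `removed` give the threshold and the removed indices.
#' @export
remove_upper_outliers <- function(values, k = 3) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    abort("`values` must be a finite numeric vector")
  }
  if (length(values) < 4L) {
    abort("need at least 4 values to define quartiles (got %d)", length(values))
  }
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    abort("`k` must be a single positive number")
  }
  if (is.infinite(k)) {
    cutoff <- Inf
  } else {
    q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
    cutoff <- q[2L] + k * (q[2L] - q[1L])
  }
  keep <- which(values <= cutoff)
  structure(keep, cutoff = cutoff, removed = which(values > cutoff))
}

#' Correlate predictions with a reference table, trimming upper outliers
#'
#' Matches gene pairs ([match_gene_pairs()]), removes every pair in which
#' either member exceeds its own vector's `Q3 + k * IQR` cutoff
#' ([remove_upper_outliers()] applied to both vectors, symmetric
#' treatment), then runs [pearson_test()] on the retained pairs. By default
#' the test is computed on raw FPKM-scale values; `log_transform = TRUE`
#' applies `log1p` to both vectors before outlier removal and testing.
#'
#' @param predictions A [target_prediction()] table.
#' @param reference Data frame with columns `gene` and `value`.
#' @param k IQR multiplier for the outlier rule (default 3).
#' @param log_transform Correlate `log1p`-transformed values instead of raw
#'   ones (default `FALSE`).
#' @return List of class `correlation_report`: `n_pairs` (before removal),
#'   `n_outliers_removed`, `removed_genes`, `r`, `df`, `t`, `p_value`.
#' @export
correlate_with_reference <- function(predictions, reference, k = 3,
                                     log_transform = FALSE) {
  pairs <- match_gene_pairs(predictions, reference)
  x <- pairs$predicted
  y <- pairs$reference
  if (isTRUE(log_transform)) {
    x <- log1p(x)
    y <- log1p(y)
  }
  keep <- intersect(remove_upper_outliers(x, k), remove_upper_outliers(y, k))
  removed <- setdiff(seq_len(nrow(pairs)), keep)
  if (length(keep) < 3L) {
    abort("fewer than 3 pairs remain after outlier removal")
  }
  test <- pearson_test(x[keep], y[keep])
  structure(
    list(n_pairs = nrow(pairs),
         n_outliers_removed = length(removed),
         removed_genes = pairs$gene[removed],
         r = test$r, df = test$df, t = test$t, p_value = test$p_value),
    class = "correlation_report"
  )
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("correlation_report: r = %.3f, t = %.3f, df = %d, p = %.3g\n",
              x$r, x$t, x$df, x$p_value))
  cat(sprintf("  %d pair(s), %d outlier(s) removed%s\n",
              x$n_pairs, x$n_outliers_removed,
              if (x$n_outliers_removed > 0)
                sprintf(" (%s)", oxford(x$removed_genes)) else ""))
  invisible(x)
}
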