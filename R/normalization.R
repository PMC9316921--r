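# Count filtering and FPKM normalisation. The pipeline order is fixed:
# low-count genes are removed first and per-sample totals are recomputed on
# the filtered matrix, so FPKM always refers to the reads the matrix holds.

#' Filter genes by total read count
#'
#' Retains exactly the genes whose summed count across all samples reaches
#' `min_total`; the sample set is unchanged. The number of removed genes is
#' reported via a message and the `"n_removed"` attribute.
#'
#' @param x A [count_matrix()].
#' @param min_total Non-negative integer; minimum summed count across all
#'   samples for a gene to be kept. Default 10, a conventional low-count
#'   floor.
#' @return The filtered `count_matrix`, gene order preserved, with attribute
#'   `n_removed`.
#' @export
filter_low_count_genes <- function(x, min_total = 10) {
  stopifnot(inherits(x, "count_matrix"))
  if (!is_count(min_total)) {
    abort("`min_total` must be a single non-negative integer")
  }
  totals <- rowSums(x$counts)
  keep <- totals >= min_total
  n_removed <- sum(!keep)
  if (!any(keep)) {
    warning("all genes fall below min_total = ", min_total,
            "; the filtered matrix is empty", call. = FALSE)
    out <- structure(
      list(counts = x$counts[keep, , drop = FALSE],
           gene_lengths = x$gene_lengths[keep]),
      class = "count_matrix"
    )
  } else {
    out <- count_matrix(x$counts[keep, , drop = FALSE], x$gene_lengths[keep])
  }
  message(sprintf("filter_low_count_genes: removed %d of %d gene(s) (min_total = %s)",
                  n_removed, length(totals), format(min_total)))
  attr(out, "n_removed") <- n_removed
  out
}

#' FPKM-normalise a count matrix
#'
#' Fragments Per Kilobase of transcript per Million mapped reads:
#' `fpkm(g, s) = count(g, s) * 1e9 / (length_bp(g) * total(s))`, where
#' `total(s)` is the summed count of sample `s` over the genes retained in
#' the matrix. FPKM is invariant to a uniform rescaling of a sample's
#' counts.
#'
#' @param x A [count_matrix()] (filter first if low-count genes should not
#'   contribute to the totals).
#' @param metadata Optional [sample_metadata()]; when `NULL`, placeholder
#'   metadata with tissue `"unassigned"` is attached so the result is a
#'   complete [expression_matrix()].
#' @return An [expression_matrix()] of FPKM values.
#' @export
fpkm_normalize <- function(x, metadata = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  totals <- colSums(x$counts)
  zero <- totals <= 0
  if (any(zero)) {
    abort("sample(s) with zero total counts: %s",
          oxford(colnames(x$counts)[zero]))
  }
  # counts / lengths recycles the per-gene length down each column
  fpkm <- sweep(x$counts / x$gene_lengths, 2L, totals, "/") * 1e9
  if (is.null(metadata)) {
    metadata <- data.frame(
      sample_id = colnames(x$counts),
      tissue = "unassigned",
      dataset = "unassigned",
      stringsAsFactors = FALSE
    )
  }
  expression_matrix(fpkm, metadata)
}
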