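#' Construct a validated read-count matrix
#'
#' A `count_matrix` holds non-negative integer read counts per gene and
#' sample together with the transcript length of every gene, the two
#' ingredients of FPKM normalisation.
#'
#' @param counts Numeric matrix of read counts, genes in rows and samples in
#'   columns, with unique, non-empty row and column names. Values must be
#'   non-negative integers.
#' @param gene_lengths Numeric vector of transcript lengths in base pairs,
#'   one per gene. May be named (names must then match the rows of `counts`)
#'   or unnamed and aligned with the row order. All lengths must be positive
#'   integers.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (numeric matrix) and `gene_lengths` (named numeric vector).
#'
#' @examples
#' m <- matrix(c(10, 5, 0, 0, 2, 0), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' cm <- count_matrix(m, c(g1 = 1000, g2 = 2000, g3 = 500))
#' cm
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix")
  }
  ids <- rownames(counts)
  smp <- colnames(counts)
  if (is.null(ids) || is.null(smp) || !all(nzchar(ids)) || !all(nzchar(smp))) {
    abort("`counts` must have non-empty row (gene) and column (sample) names")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate gene identifier(s): %s", oxford(unique(ids[duplicated(ids)])))
  }
  if (anyDuplicated(smp)) {
    abort("duplicate sample identifier(s): %s", oxford(unique(smp[duplicated(smp)])))
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort("count for gene '%s', sample '%s' is not a non-negative integer (%s)",
          ids[bad[1L, 1L]], smp[bad[1L, 2L]],
          format(counts[bad[1L, , drop = FALSE]]))
  }
  if (!is.numeric(gene_lengths) || length(gene_lengths) != nrow(counts)) {
    abort("`gene_lengths` must be numeric with one entry per gene (%d needed, %d given)",
          nrow(counts), length(gene_lengths))
  }
  if (is.null(names(gene_lengths))) {
    names(gene_lengths) <- ids
  } else {
    missing <- setdiff(ids, names(gene_lengths))
    if (length(missing) > 0L) {
      abort("gene(s) missing from `gene_lengths`: %s", oxford(missing))
    }
    gene_lengths <- gene_lengths[ids]
  }
  bad_len <- !is.finite(gene_lengths) | gene_lengths <= 0 |
    gene_lengths != round(gene_lengths)
  if (any(bad_len)) {
    abort("gene length for %s must be a positive integer (base pairs)",
          oxford(ids[bad_len]))
  }
  structure(
    list(counts = counts, gene_lengths = gene_lengths),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  gene lengths: %d-%d bp\n",
              min(x$gene_lengths), max(x$gene_lengths)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)
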