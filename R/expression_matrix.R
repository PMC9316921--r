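#' Validate a sample metadata table
#'
#' Sample metadata links every sample identifier to a tissue label and the
#' study it came from. Every sample of an expression or count matrix must
#' have exactly one metadata row.
#'
#' @param metadata Data frame with character columns `sample_id`, `tissue`
#'   and `dataset`. `sample_id` must be unique and `tissue` non-empty.
#'
#' @return The validated data frame (invisibly classed `sample_metadata`).
#' @export
sample_metadata <- function(metadata) {
  if (!is.data.frame(metadata)) {
    abort("`metadata` must be a data frame")
  }
  needed <- c("sample_id", "tissue", "dataset")
  missing <- setdiff(needed, names(metadata))
  if (length(missing) > 0L) {
    abort("metadata is missing column(s): %s", oxford(missing))
  }
  metadata <- as.data.frame(metadata[needed])
  for (col in needed) metadata[[col]] <- as.character(metadata[[col]])
  if (anyDuplicated(metadata$sample_id)) {
    abort("duplicate sample_id in metadata: %s",
          oxford(unique(metadata$sample_id[duplicated(metadata$sample_id)])))
  }
  if (any(is.na(metadata$tissue) | !nzchar(metadata$tissue))) {
    abort("every sample needs a non-empty tissue label; offending sample(s): %s",
          oxford(metadata$sample_id[is.na(metadata$tissue) | !nzchar(metadata$tissue)]))
  }
  class(metadata) <- c("sample_metadata", "data.frame")
  metadata
}

#' Construct a validated expression matrix
#'
#' An `expression_matrix` holds non-negative expression values (FPKM) per
#' gene and sample, plus the metadata row of every sample so downstream
#' steps always know each sample's tissue.
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique dimnames; values must be finite and non-negative.
#' @param metadata Sample metadata (see [sample_metadata()]) covering exactly
#'   the columns of `values`.
#'
#' @return Object of class `expression_matrix`: list with elements `values`
#'   and `metadata` (metadata reordered to match the columns).
#' @export
expression_matrix <- function(values, metadata) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix")
  }
  ids <- rownames(values)
  smp <- colnames(values)
  if (is.null(ids) || is.null(smp)) {
    abort("`values` must have row (gene) and column (sample) names")
  }
  if (anyDuplicated(ids)) {
    abort("duplicate gene identifier(s): %s", oxford(unique(ids[duplicated(ids)])))
  }
  if (anyDuplicated(smp)) {
    abort("duplicate sample identifier(s): %s", oxford(unique(smp[duplicated(smp)])))
  }
  bad <- !is.na(values) & (!is.finite(values) | values < 0)
  if (any(bad)) {
    abort("expression values must be non-negative and finite")
  }
  metadata <- sample_metadata(metadata)
  missing <- setdiff(smp, metadata$sample_id)
  if (length(missing) > 0L) {
    abort("sample(s) missing from metadata: %s", oxford(missing))
  }
  metadata <- metadata[match(smp, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(
    list(values = values, metadata = metadata),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  tis <- table(x$metadata$tissue)
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tissue label(s))\n",
              nrow(x$values), ncol(x$values), length(tis)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

# Accept either an expression_matrix or a bare matrix + metadata, and return
# a validated expression_matrix. Internal plumbing used by several modules.
as_expression_matrix <- function(x, metadata = NULL) {
  if (inherits(x, "expression_matrix")) {
    return(x)
  }
  if (is.matrix(x)) {
    if (is.null(metadata)) {
      abort("a bare matrix needs `metadata` to become an expression_matrix")
    }
    return(expression_matrix(x, metadata))
  }
  abort("expected an expression_matrix or a numeric matrix")
}

#' Subset an expression matrix by sample
#'
#' Keeps the columns (and metadata rows) of the given samples, preserving
#' their order in the matrix.
#'
#' @param expr An [expression_matrix()].
#' @param samples Character vector of sample identifiers to keep.
#' @return An `expression_matrix` restricted to `samples`.
#' @export
subset_samples <- function(expr, samples) {
  expr <- as_expression_matrix(expr)
  missing <- setdiff(samples, colnames(expr$values))
  if (length(missing) > 0L) {
    abort("unknown sample(s): %s", oxford(missing))
  }
  keep <- colnames(expr$values)[colnames(expr$values) %in% samples]
  expression_matrix(expr$values[, keep, drop = FALSE],
                    expr$metadata[expr$metadata$sample_id %in% keep, , drop = FALSE])
}
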