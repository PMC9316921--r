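# All tabular artifacts are tab-separated UTF-8 text with a header row, '.'
# decimal separator and literal "NA" for missing values; gene identifiers are
# opaque strings compared case-sensitively. One dialect, deterministic
# round-trips.

read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    abort("file does not exist: %s", path)
  }
  read.delim(path, header = TRUE, sep = "\t", quote = "", dec = ".",
             na.strings = "NA", check.names = FALSE, colClasses = NA,
             stringsAsFactors = FALSE, comment.char = "")
}

write_tsv_strict <- function(df, path) {
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, dec = ".",
                na = "NA", row.names = FALSE, col.names = TRUE,
                fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    abort("cannot write '%s': %s", path, conditionMessage(ok))
  }
  invisible(path)
}

#' Read a gene-by-sample count table with gene lengths
#'
#' Reads two tab-separated files: a count table whose first column holds the
#' gene identifier and whose remaining columns are samples, and a two-column
#' length table (`gene`, `length_bp`). Every gene in the count table must
#' have a length.
#'
#' @param path Path to the count TSV (header row; first column gene id).
#' @param lengths_path Path to the gene length TSV (columns `gene`,
#'   `length_bp`).
#' @return A validated [count_matrix()], gene order as in the count file.
#' @export
read_count_table <- function(path, lengths_path) {
  raw <- read_tsv_strict(path)
  if (ncol(raw) < 2L) {
    abort("count table '%s' needs a gene column plus at least one sample", path)
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    abort("duplicate gene identifier(s) in '%s': %s",
          path, oxford(unique(ids[duplicated(ids)])))
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    abort("count table '%s' contains non-numeric entries", path)
  }
  rownames(m) <- ids

  len_raw <- read_tsv_strict(lengths_path)
  if (ncol(len_raw) < 2L) {
    abort("length table '%s' needs columns gene and length_bp", lengths_path)
  }
  len_ids <- as.character(len_raw[[1L]])
  if (anyDuplicated(len_ids)) {
    abort("duplicate gene identifier(s) in '%s': %s",
          lengths_path, oxford(unique(len_ids[duplicated(len_ids)])))
  }
  missing <- setdiff(ids, len_ids)
  if (length(missing) > 0L) {
    abort("gene(s) present in counts but absent from lengths: %s",
          oxford(missing))
  }
  lengths <- setNames(as.numeric(len_raw[[2L]]), len_ids)[ids]
  count_matrix(m, lengths)
}

#' Write a gene length table
#'
#' @param gene_lengths Named numeric vector of lengths in base pairs.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_length_table <- function(gene_lengths, path) {
  write_tsv_strict(
    data.frame(gene = names(gene_lengths), length_bp = as.numeric(gene_lengths),
               stringsAsFactors = FALSE),
    path
  )
}

#' Write a count matrix to TSV
#'
#' Writes the counts with the gene identifier in the first column (`gene`).
#' The companion length table is written with [write_length_table()].
#'
#' @param x A [count_matrix()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read a sample metadata table
#'
#' @param path TSV with columns `sample_id`, `tissue`, `dataset`.
#' @return A validated [sample_metadata()] data frame.
#' @export
read_sample_metadata <- function(path) {
  sample_metadata(read_tsv_strict(path))
}

#' Write a sample metadata table
#'
#' @param metadata A [sample_metadata()] data frame.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  write_tsv_strict(sample_metadata(metadata), path)
}

#' Read an expression (FPKM) table with its metadata
#'
#' @param path TSV of expression values, first column `gene`, remaining
#'   columns samples.
#' @param metadata_path TSV of sample metadata (see [read_sample_metadata()]).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, metadata_path) {
  raw <- read_tsv_strict(path)
  if (ncol(raw) < 2L) {
    abort("expression table '%s' needs a gene column plus at least one sample",
          path)
  }
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids)) {
    abort("duplicate gene identifier(s) in '%s': %s",
          path, oxford(unique(ids[duplicated(ids)])))
  }
  m <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(m) <- ids
  expression_matrix(m, read_sample_metadata(metadata_path))
}

#' Write an expression matrix and its metadata to TSV
#'
#' @param expr An [expression_matrix()].
#' @param path Output TSV path for the values.
#' @param metadata_path Optional output TSV path for the metadata.
#' @return The value path, invisibly.
#' @export
write_expression_table <- function(expr, path, metadata_path = NULL) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
  if (!is.null(metadata_path)) {
    write_sample_metadata(expr$metadata, metadata_path)
  }
  invisible(path)
}

#' Write a target prediction table
#'
#' Writes columns `gene`, `predicted_mean`, `predicted_sd`, `status`. Values
#' round-trip losslessly at (at least) 6 significant digits.
#'
#' @param predictions A `target_prediction` data frame (see
#'   [predict_unknown_tissue()]).
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_prediction_table <- function(predictions, path) {
  predictions <- target_prediction(predictions)
  write_tsv_strict(
    predictions[, c("gene", "predicted_mean", "predicted_sd", "status")],
    path
  )
}

#' Read a target prediction table
#'
#' @param path TSV written by [write_prediction_table()].
#' @return A validated `target_prediction` data frame.
#' @export
read_prediction_table <- function(path) {
  raw <- read_tsv_strict(path)
  target_prediction(raw)
}

#' Read an external reference expression table
#'
#' Two columns: `gene` (symbol, matched case-sensitively downstream) and
#' `value` (expression). Duplicate symbols are rejected because the
#' gene-pair matching is an unambiguous inner join.
#'
#' @param path TSV with columns `gene` and `value`.
#' @return Data frame with character `gene` and numeric `value`.
#' @export
read_reference_table <- function(path) {
  raw <- read_tsv_strict(path)
  missing <- setdiff(c("gene", "value"), names(raw))
  if (length(missing) > 0L) {
    abort("reference table '%s' is missing column(s): %s", path, oxford(missing))
  }
  out <- data.frame(gene = as.character(raw$gene),
                    value = as.numeric(raw$value),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene)) {
    abort("duplicate gene symbol(s) in reference table: %s",
          oxford(unique(out$gene[duplicated(out$gene)])))
  }
  out
}
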