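# Gene-wise scaling and hierarchical clustering of samples — the analysis
# behind a clustered expression heatmap. The tested artifact is the merge
# tree and the flat assignments; image rendering is left to the user
# (e.g. stats::heatmap or pheatmap on the scaled matrix).

#' Scale each gene row to mean 0, SD 1
#'
#' Standardises every gene across samples (z-score with the n - 1
#' denominator). Rows with zero variance cannot be scaled; they are set to
#' all zeros and flagged through the `"constant_genes"` attribute.
#'
#' @param expr An [expression_matrix()] or a bare numeric matrix with at
#'   least 2 columns.
#' @return Same shape as the input, scaled by row; attribute
#'   `constant_genes` lists the zero-variance gene identifiers.
#' @export
scale_genes <- function(expr) {
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`expr` must be an expression_matrix or a numeric matrix")
  }
  if (ncol(values) < 2L) {
    abort("need at least 2 samples to scale genes")
  }
  mu <- rowMeans(values)
  s <- row_sds(values)
  constant <- s == 0
  s[constant] <- 1 # avoid 0/0; constant rows become all zeros below
  scaled <- (values - mu) / s
  scaled[constant, ] <- 0
  if (inherits(expr, "expression_matrix")) {
    out <- expr
    out$values <- scaled
    # scaled values are signed, so bypass the non-negative validator
    attr(out, "scaled") <- TRUE
  } else {
    out <- scaled
  }
  attr(out, "constant_genes") <- rownames(values)[constant]
  out
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of the samples (columns) of a scaled expression
#' matrix. Samples are ordered lexicographically by identifier before
#' clustering so that equal-distance merges are always broken the same way
#' and the result is invariant to the input column order.
#'
#' @param expr An [expression_matrix()] (e.g. from [scale_genes()]) or a
#'   numeric matrix, genes in rows, samples in columns.
#' @param metric `"euclidean"` (distance between sample columns) or
#'   `"correlation"` (one minus the Pearson correlation of the columns).
#' @param linkage `"complete"`, `"average"` or `"ward"` (Ward's criterion on
#'   squared distances, `hclust`'s `"ward.D2"`).
#' @param k Optional number of flat clusters to cut the tree into.
#' @return List of class `sample_clustering`: `labels` (lexicographic
#'   sample order used as input), `merge` and `height` (the agglomeration
#'   tree), `order` (leaf order for display), `clusters` (named integer
#'   assignment, when `k` was given), `metric`, `linkage`, and the
#'   underlying `hclust` object.
#' @export
cluster_samples <- function(expr,
                            metric = c("euclidean", "correlation"),
                            linkage = c("complete", "average", "ward"),
                            k = NULL) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  values <- if (inherits(expr, "expression_matrix")) expr$values else expr
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`expr` must be an expression_matrix or a numeric matrix")
  }
  if (ncol(values) < 2L) {
    abort("need at least 2 samples to cluster")
  }
  values <- values[, order(colnames(values)), drop = FALSE]
  d <- switch(metric,
    euclidean = dist(t(values), method = "euclidean"),
    correlation = {
      if (any(row_sds(t(values)) == 0)) {
        abort("correlation metric undefined for zero-variance sample(s)")
      }
      as.dist(1 - cor(values))
    }
  )
  method <- switch(linkage, complete = "complete", average = "average",
                   ward = "ward.D2")
  hc <- hclust(d, method = method)
  clusters <- if (!is.null(k)) {
    if (!is_count(k) || k < 1 || k > ncol(values)) {
      abort("`k` must be an integer between 1 and the number of samples")
    }
    cutree(hc, k = k)
  } else {
    NULL
  }
  structure(
    list(labels = colnames(values),
         merge = hc$merge,
         height = hc$height,
         order = colnames(values)[hc$order],
         clusters = clusters,
         metric = metric,
         linkage = linkage,
         hclust = hc),
    class = "sample_clustering"
  )
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat(sprintf("sample_clustering: %d samples, %s distance, %s linkage\n",
              length(x$labels), x$metric, x$linkage))
  if (!is.null(x$clusters)) {
    cat(sprintf("  flat assignment into %d cluster(s)\n",
                length(unique(x$clusters))))
  }
  invisible(x)
}
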