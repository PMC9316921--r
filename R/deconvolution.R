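# Single-unknown-tissue linear unmixing.
#
# Model: the pooled sample's FPKM for gene i is the equal-proportion average
# of the per-tissue expected expressions,
#     G_i = sum_j p * a_ij + e_i,          p = 1/T,
# so the one tissue without reference data (the target) is estimated by
#     H_i = G_i / p - sum_{j != target} a_ij ,
# using reference tissue means for the known a_ij and the per-gene median of
# the known means where a mix tissue has no reference data. Genes whose raw
# estimate is <= 0 are removed (status "dropped_negative"); genes absent
# from the mix sample cannot be estimated ("dropped_no_mix").

#' Construct a per-tissue expression profile table
#'
#' Long-format table with one row per (gene, tissue): the mean FPKM, the
#' sample standard deviation across that tissue's replicates, the replicate
#' count `n`, and whether the row was imputed rather than observed.
#'
#' @param df Data frame with columns `gene`, `tissue`, `mean`, `sd`, `n`,
#'   and optionally `imputed` (default `FALSE`). Means and SDs must be
#'   non-negative; `n >= 1` (or `NA` for analytic/population rows) and
#'   `sd == 0` wherever `n == 1` since a single replicate carries no spread.
#' @return The validated data frame, classed `tissue_profiles`.
#' @export
tissue_profiles <- function(df) {
  if (inherits(df, "tissue_profiles")) {
    return(df) # already validated by this constructor
  }
  if (!is.data.frame(df)) {
    abort("`df` must be a data frame")
  }
  needed <- c("gene", "tissue", "mean", "sd", "n")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort("profile table is missing column(s): %s", oxford(missing))
  }
  if (!"imputed" %in% names(df)) {
    df$imputed <- FALSE
  }
  df <- as.data.frame(df[c(needed, "imputed")])
  df$gene <- as.character(df$gene)
  df$tissue <- as.character(df$tissue)
  key <- paste(df$gene, df$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[which(duplicated(key))[1L], ]
    abort("duplicate (gene, tissue) profile row(s), e.g. ('%s', '%s')",
          dup$gene, dup$tissue)
  }
  if (any(!is.finite(df$mean) | df$mean < 0)) {
    abort("profile means must be non-negative and finite")
  }
  if (any(!is.finite(df$sd) | df$sd < 0)) {
    abort("profile SDs must be non-negative and finite")
  }
  n_known <- !is.na(df$n)
  if (any(n_known & (df$n < 1 | df$n != round(df$n)))) {
    abort("replicate counts `n` must be integers >= 1 (or NA for population rows)")
  }
  if (any(n_known & df$n == 1 & df$sd != 0)) {
    abort("rows with n = 1 must have sd = 0")
  }
  rownames(df) <- NULL
  class(df) <- c("tissue_profiles", "data.frame")
  df
}

#' Compute per-tissue mean/SD expression profiles
#'
#' For every tissue label in the metadata, computes the arithmetic mean and
#' the sample standard deviation (n - 1 denominator; 0 when a tissue has a
#' single sample) of each gene's expression over that tissue's samples.
#'
#' @param expr An [expression_matrix()], or a bare numeric matrix combined
#'   with `metadata`.
#' @param metadata Optional [sample_metadata()] when `expr` is a bare matrix.
#' @param tissues Optional character vector restricting which tissue labels
#'   to profile; requesting a tissue with no samples is an error.
#' @return A [tissue_profiles()] table covering every requested tissue.
#' @export
compute_tissue_profiles <- function(expr, metadata = NULL, tissues = NULL) {
  expr <- as_expression_matrix(expr, metadata)
  labels <- expr$metadata$tissue
  if (is.null(tissues)) {
    tissues <- unique(labels)
  } else {
    absent <- setdiff(tissues, labels)
    if (length(absent) > 0L) {
      abort("tissue(s) with zero samples requested: %s", oxford(absent))
    }
  }
  pieces <- lapply(tissues, function(t) {
    cols <- which(labels == t)
    sub <- expr$values[, cols, drop = FALSE]
    data.frame(
      gene = rownames(expr$values),
      tissue = t,
      mean = rowMeans(sub),
      sd = row_sds(sub),
      n = length(cols),
      imputed = FALSE,
      stringsAsFactors = FALSE
    )
  })
  tissue_profiles(do.call(rbind, pieces))
}

#' Describe a uniform tissue mix and its unknown component
#'
#' The mix design declares which `T` tissues were pooled, the uniform pool
#' proportion `p` (which must satisfy `p * T = 1`), which pooled tissue is
#' the unknown target, and how every other pooled tissue is matched to a
#' reference tissue profile. A mix tissue may map to the token `"IMPUTE"`,
#' meaning its mean is imputed as the per-gene median of the known
#' reference-tissue means.
#'
#' @param mix_tissues Character vector of the `T` pooled tissue labels.
#' @param unknown_tissue The pooled tissue to be predicted; must be one of
#'   `mix_tissues` and must not appear in `mapping`.
#' @param p Uniform pool proportion, default `1 / length(mix_tissues)`.
#' @param mapping Optional named character vector: names are the non-target
#'   mix tissues, values are reference tissue labels or `"IMPUTE"`. When
#'   `NULL` (the default), mix tissues are matched to reference profiles by
#'   identical name and the rest are imputed.
#' @param mix_label Tissue label identifying pooled samples in the metadata
#'   (default `"mix"`).
#' @return Object of class `mix_design`.
#' @export
mix_design <- function(mix_tissues, unknown_tissue,
                       p = 1 / length(mix_tissues),
                       mapping = NULL, mix_label = "mix") {
  if (!is.character(mix_tissues) || length(mix_tissues) < 2L) {
    abort("`mix_tissues` must list at least two tissue labels")
  }
  if (anyDuplicated(mix_tissues)) {
    abort("duplicate mix tissue(s): %s",
          oxford(unique(mix_tissues[duplicated(mix_tissues)])))
  }
  if (!is_string(unknown_tissue) || !unknown_tissue %in% mix_tissues) {
    abort("`unknown_tissue` must be one of the mix tissues")
  }
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0 || p > 1) {
    abort("`p` must be a single proportion in (0, 1]")
  }
  if (abs(p * length(mix_tissues) - 1) > 1e-8) {
    abort("`p` must equal 1/T for T = %d mix tissues (got %s)",
          length(mix_tissues), format(p))
  }
  if (!is_string(mix_label) || mix_label %in% mix_tissues) {
    abort("`mix_label` must be a non-empty label distinct from the mix tissues")
  }
  others <- setdiff(mix_tissues, unknown_tissue)
  if (!is.null(mapping)) {
    if (!is.character(mapping) || is.null(names(mapping))) {
      abort("`mapping` must be a named character vector")
    }
    if (unknown_tissue %in% names(mapping)) {
      abort("the unknown tissue '%s' must not be mapped", unknown_tissue)
    }
    bad <- setdiff(names(mapping), others)
    if (length(bad) > 0L) {
      abort("mapping names are not non-target mix tissues: %s", oxford(bad))
    }
    unmapped <- setdiff(others, names(mapping))
    if (length(unmapped) > 0L) {
      abort("mix tissue(s) without a mapping entry: %s", oxford(unmapped))
    }
    if (anyDuplicated(names(mapping))) {
      abort("duplicate mapping entries for: %s",
            oxford(unique(names(mapping)[duplicated(names(mapping))])))
    }
  }
  structure(
    list(mix_tissues = mix_tissues, unknown_tissue = unknown_tissue,
         p = p, mapping = mapping, mix_label = mix_label),
    class = "mix_design"
  )
}

#' @export
print.mix_design <- function(x, ...) {
  cat(sprintf("mix_design: %d tissues pooled at p = 1/%d; unknown = '%s'\n",
              length(x$mix_tissues), length(x$mix_tissues), x$unknown_tissue))
  if (is.null(x$mapping)) {
    cat("  mapping: by identical name, IMPUTE elsewhere\n")
  } else {
    cat(sprintf("  mapping: %d explicit entries (%d IMPUTE)\n",
                length(x$mapping), sum(x$mapping == "IMPUTE")))
  }
  invisible(x)
}

# Resolve the design's mapping against the tissues that actually have
# profiles: NULL mapping becomes name-identical matching with IMPUTE
# elsewhere; explicit mappings are checked for dangling reference labels.
resolve_mapping <- function(design, profiles) {
  stopifnot(inherits(design, "mix_design"))
  available <- setdiff(unique(profiles$tissue), design$mix_label)
  others <- setdiff(design$mix_tissues, design$unknown_tissue)
  if (is.null(design$mapping)) {
    mapping <- setNames(ifelse(others %in% available, others, "IMPUTE"), others)
  } else {
    mapping <- design$mapping[others]
    dangling <- setdiff(setdiff(unique(mapping), "IMPUTE"), available)
    if (length(dangling) > 0L) {
      abort("mapping points at reference tissue(s) with no profile: %s",
            oxford(dangling))
    }
  }
  mapping
}

#' Impute profiles for mix tissues lacking reference data
#'
#' Every mix tissue mapped to `"IMPUTE"` receives, for each gene, a mean
#' equal to the median of that gene's known reference-tissue means and an SD
#' equal to the median of the known reference-tissue SDs (so imputed terms
#' still contribute uncertainty). Imputed rows carry the mix tissue's own
#' label and `imputed = TRUE`. With an even number of known tissues the
#' median is the midpoint of the two central values.
#'
#' @param profiles A [tissue_profiles()] table of observed reference
#'   profiles.
#' @param design A [mix_design()].
#' @return The profile table extended with imputed rows; attribute
#'   `imputed_tissues` lists which mix tissues were imputed.
#' @export
impute_missing_tissue_means <- function(profiles, design) {
  profiles <- tissue_profiles(profiles)
  mapping <- resolve_mapping(design, profiles)
  to_impute <- names(mapping)[mapping == "IMPUTE"]
  if (length(to_impute) == 0L) {
    attr(profiles, "imputed_tissues") <- character(0)
    return(profiles)
  }
  known_tissues <- setdiff(unique(mapping), "IMPUTE")
  known <- profiles[profiles$tissue %in% known_tissues, , drop = FALSE]
  all_genes <- unique(profiles$gene)
  if (nrow(known) == 0L) {
    abort("no known reference means to impute from for gene(s): %s",
          oxford(all_genes))
  }
  med_mean <- tapply(known$mean, known$gene, median)
  med_sd <- tapply(known$sd, known$gene, median)
  uncovered <- setdiff(all_genes, names(med_mean))
  if (length(uncovered) > 0L) {
    abort("gene(s) with no known reference means: %s", oxford(uncovered))
  }
  genes <- names(med_mean)
  rows <- lapply(to_impute, function(t) {
    data.frame(gene = genes, tissue = t,
               mean = as.numeric(med_mean), sd = as.numeric(med_sd),
               n = NA_real_, imputed = TRUE, stringsAsFactors = FALSE)
  })
  out <- tissue_profiles(rbind(as.data.frame(profiles), do.call(rbind, rows)))
  attr(out, "imputed_tissues") <- to_impute
  out
}

#' Validate a target prediction table
#'
#' @param df Data frame with columns `gene`, `predicted_mean`,
#'   `predicted_sd`, `status`. Status is one of `"predicted"`,
#'   `"dropped_negative"`, `"dropped_no_mix"`. Predicted genes must have a
#'   positive mean; dropped-negative genes keep their raw (non-positive)
#'   estimate for audit.
#' @return The validated data frame, classed `target_prediction`.
#' @export
target_prediction <- function(df) {
  if (!is.data.frame(df)) {
    abort("`df` must be a data frame")
  }
  needed <- c("gene", "predicted_mean", "predicted_sd", "status")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L) {
    abort("prediction table is missing column(s): %s", oxford(missing))
  }
  df <- as.data.frame(df[needed])
  df$gene <- as.character(df$gene)
  df$predicted_mean <- as.numeric(df$predicted_mean)
  df$predicted_sd <- as.numeric(df$predicted_sd)
  df$status <- as.character(df$status)
  if (anyDuplicated(df$gene)) {
    abort("duplicate gene(s) in prediction table: %s",
          oxford(unique(df$gene[duplicated(df$gene)])))
  }
  ok_status <- c("predicted", "dropped_negative", "dropped_no_mix")
  if (!all(df$status %in% ok_status)) {
    abort("invalid status value(s): %s",
          oxford(unique(setdiff(df$status, ok_status))))
  }
  bad <- df$status == "predicted" &
    (!is.finite(df$predicted_mean) | df$predicted_mean <= 0)
  if (any(bad)) {
    abort("status 'predicted' requires predicted_mean > 0; offending gene(s): %s",
          oxford(df$gene[bad]))
  }
  bad_neg <- df$status == "dropped_negative" &
    (!is.finite(df$predicted_mean) | df$predicted_mean > 0)
  if (any(bad_neg)) {
    abort("status 'dropped_negative' must record the raw non-positive estimate; offending gene(s): %s",
          oxford(df$gene[bad_neg]))
  }
  if (any(!is.na(df$predicted_sd) & df$predicted_sd < 0)) {
    abort("predicted_sd must be non-negative")
  }
  rownames(df) <- NULL
  class(df) <- c("target_prediction", "data.frame")
  df
}

# Build the gene x mapped-source mean (or sd) matrix used by the estimator:
# one column per non-target mix tissue, holding the profile value of the
# tissue it maps to (imputed rows carry the mix tissue's own label). A
# reference tissue mapped by several mix tissues is counted once per mix
# tissue, as the mixture model requires.
mapped_profile_matrix <- function(profiles, design, field = "mean") {
  mapping <- resolve_mapping(design, profiles)
  sources <- ifelse(mapping == "IMPUTE", names(mapping), mapping)
  unresolved <- setdiff(unique(sources), unique(profiles$tissue))
  if (length(unresolved) > 0L) {
    abort("no profile rows for mix tissue(s) %s; run impute_missing_tissue_means() first",
          oxford(unresolved))
  }
  genes <- unique(profiles$gene)
  wide <- matrix(NA_real_, nrow = length(genes), ncol = length(sources),
                 dimnames = list(genes, names(mapping)))
  rows_by_tissue <- split(seq_len(nrow(profiles)), profiles$tissue)
  vals <- profiles[[field]]
  gene_col <- profiles$gene
  for (k in seq_along(sources)) {
    idx <- rows_by_tissue[[sources[k]]]
    wide[gene_col[idx], k] <- vals[idx]
  }
  wide
}

#' Predict the unknown tissue's expression from the mix mean
#'
#' Inverts the uniform mixture model: for each gene, the raw estimate is
#' `H = mix_mean / p - sum` of the mapped reference means over the `T - 1`
#' non-target mix tissues. Genes with `H > 0` get status `"predicted"`;
#' genes with `H <= 0` are `"dropped_negative"` (the raw estimate is kept
#' for audit); genes present in the profiles but absent from the mix (or
#' with a missing mix value) are `"dropped_no_mix"`.
#'
#' @param mix_mean Named numeric vector of per-gene mean FPKM in the pooled
#'   sample(s); `NA` marks a gene without usable mix data.
#' @param profiles A [tissue_profiles()] table containing (possibly imputed)
#'   means for all non-target mix tissues.
#' @param design A [mix_design()].
#' @return A [target_prediction()] data frame (`predicted_sd` is `NA`; see
#'   [propagate_prediction_sd()]).
#' @export
predict_unknown_tissue <- function(mix_mean, profiles, design) {
  stopifnot(inherits(design, "mix_design"))
  profiles <- tissue_profiles(profiles)
  if (!is.numeric(mix_mean) || is.null(names(mix_mean))) {
    abort("`mix_mean` must be a named numeric vector (names = genes)")
  }
  if (anyDuplicated(names(mix_mean))) {
    abort("duplicate gene(s) in `mix_mean`: %s",
          oxford(unique(names(mix_mean)[duplicated(names(mix_mean))])))
  }
  means <- mapped_profile_matrix(profiles, design, "mean")
  genes <- union(names(mix_mean), rownames(means))
  g_mix <- setNames(rep(NA_real_, length(genes)), genes)
  g_mix[names(mix_mean)] <- mix_mean

  has_mix <- !is.na(g_mix)
  need <- intersect(genes[has_mix], rownames(means))
  if (length(setdiff(genes[has_mix], rownames(means))) > 0L) {
    abort("gene(s) in the mix without any reference profile: %s",
          oxford(setdiff(genes[has_mix], rownames(means))))
  }
  incomplete <- need[rowSums(is.na(means[need, , drop = FALSE])) > 0L]
  if (length(incomplete) > 0L) {
    abort("gene(s) lacking a mean for some mix tissue: %s", oxford(incomplete))
  }

  ref_sum <- setNames(rep(NA_real_, length(genes)), genes)
  ref_sum[rownames(means)] <- rowSums(means)
  raw <- g_mix / design$p - ref_sum

  status <- ifelse(!has_mix, "dropped_no_mix",
                   ifelse(raw > 0, "predicted", "dropped_negative"))
  target_prediction(data.frame(
    gene = genes,
    predicted_mean = ifelse(has_mix, raw, NA_real_),
    predicted_sd = NA_real_,
    status = status,
    stringsAsFactors = FALSE
  ))
}

#' Propagate the prediction's standard deviation
#'
#' Treating the mix mean and every reference mean as independent, the
#' estimator's standard deviation is
#' `SD(H) = sqrt(mix_sd^2 / p^2 + sum_j sd_j^2)` over the `T - 1` non-target
#' mix tissues (imputed tissues contribute their imputed SD rather than 0).
#'
#' @param mix_sd Named numeric vector of per-gene SDs of the pooled
#'   sample(s); must be non-negative.
#' @param profiles A [tissue_profiles()] table with (possibly imputed) SDs
#'   for all non-target mix tissues.
#' @param design A [mix_design()].
#' @return Named numeric vector of propagated SDs, one per gene of
#'   `mix_sd`; `NA` where the mix SD is missing.
#' @export
propagate_prediction_sd <- function(mix_sd, profiles, design) {
  stopifnot(inherits(design, "mix_design"))
  profiles <- tissue_profiles(profiles)
  if (!is.numeric(mix_sd) || is.null(names(mix_sd))) {
    abort("`mix_sd` must be a named numeric vector (names = genes)")
  }
  if (any(!is.na(mix_sd) & mix_sd < 0)) {
    abort("negative mix SD for gene(s): %s",
          oxford(names(mix_sd)[!is.na(mix_sd) & mix_sd < 0]))
  }
  sds <- mapped_profile_matrix(profiles, design, "sd")
  if (any(!is.na(sds) & sds < 0)) {
    abort("negative reference SD in profiles")
  }
  out <- setNames(rep(NA_real_, length(mix_sd)), names(mix_sd))
  covered <- intersect(names(mix_sd), rownames(sds))
  ref_var <- rowSums(sds[covered, , drop = FALSE]^2)
  out[covered] <- sqrt(mix_sd[covered]^2 / design$p^2 + ref_var)
  out
}

# Run one pipeline stage, tagging any error with the stage name.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort("[%s] %s", stage, conditionMessage(e))
  })
}

#' Run the full prediction pipeline
#'
#' Orchestrates: low-count filtering and FPKM normalisation (when starting
#' from counts), per-tissue profile computation, median imputation for mix
#' tissues without reference data, mixture inversion, negative-prediction
#' removal, and SD propagation. Deterministic given inputs.
#'
#' @param x A [count_matrix()] (filtered and normalised internally) or an
#'   [expression_matrix()] of FPKM values (used as is).
#' @param metadata [sample_metadata()] covering all samples; pooled samples
#'   carry the design's `mix_label` as their tissue. Ignored (taken from the
#'   object) when `x` is an `expression_matrix`.
#' @param design A [mix_design()].
#' @param min_total Low-count filter threshold, passed to
#'   [filter_low_count_genes()] when `x` is a count matrix. Default 10.
#' @return A list of class `prediction_run`: `predictions` (a
#'   [target_prediction()] table) and `report` (gene counts per stage, the
#'   imputed tissues and key parameters).
#' @export
run_prediction_pipeline <- function(x, metadata = NULL, design, min_total = 10) {
  stopifnot(inherits(design, "mix_design"))
  if (inherits(x, "count_matrix")) {
    n_input <- nrow(x$counts)
    filtered <- run_stage("filter", suppressMessages(
      filter_low_count_genes(x, min_total)
    ))
    n_removed <- attr(filtered, "n_removed")
    expr <- run_stage("normalize", fpkm_normalize(filtered, metadata))
  } else {
    expr <- run_stage("validate", as_expression_matrix(x, metadata))
    n_input <- nrow(expr$values)
    n_removed <- 0L
  }

  if (!design$mix_label %in% expr$metadata$tissue) {
    abort("[profiles] no sample carries the mix label '%s'", design$mix_label)
  }
  profiles_all <- run_stage("profiles", compute_tissue_profiles(expr))

  is_mix <- profiles_all$tissue == design$mix_label
  mix_rows <- profiles_all[is_mix, , drop = FALSE]
  mix_mean <- setNames(mix_rows$mean, mix_rows$gene)
  mix_sd <- setNames(mix_rows$sd, mix_rows$gene)
  ref <- profiles_all[!is_mix & profiles_all$tissue != design$unknown_tissue, ,
                      drop = FALSE]

  imputed <- run_stage("impute", impute_missing_tissue_means(ref, design))
  predictions <- run_stage("predict",
                           predict_unknown_tissue(mix_mean, imputed, design))
  sds <- run_stage("propagate_sd",
                   propagate_prediction_sd(mix_sd, imputed, design))
  idx <- match(predictions$gene, names(sds))
  predictions$predicted_sd <- ifelse(predictions$status == "dropped_no_mix",
                                     NA_real_, sds[idx])
  predictions <- target_prediction(predictions)

  report <- list(
    n_input = n_input,
    n_low_count_removed = n_removed,
    n_predicted = sum(predictions$status == "predicted"),
    n_dropped_negative = sum(predictions$status == "dropped_negative"),
    n_dropped_no_mix = sum(predictions$status == "dropped_no_mix"),
    imputed_tissues = attr(imputed, "imputed_tissues"),
    p = design$p,
    unknown_tissue = design$unknown_tissue,
    min_total = if (inherits(x, "count_matrix")) min_total else NA
  )
  structure(list(predictions = predictions, report = report),
            class = "prediction_run")
}

#' @export
print.prediction_run <- function(x, ...) {
  r <- x$report
  cat(sprintf("prediction_run for '%s' (p = %s)\n",
              r$unknown_tissue, format(r$p)))
  cat(sprintf("  genes: %d in -> %d low-count removed -> %d predicted, %d dropped_negative, %d dropped_no_mix\n",
              r$n_input, r$n_low_count_removed, r$n_predicted,
              r$n_dropped_negative, r$n_dropped_no_mix))
  if (length(r$imputed_tissues) > 0L) {
    cat(sprintf("  imputed tissue(s): %s\n", oxford(r$imputed_tissues)))
  }
  invisible(x)
}
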