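# Ground-truth simulator for the uniform-mixture model. Two gene classes
# mirror the structure the prediction exploits: tissue-exclusive genes
# (non-zero mean in exactly one tissue, log-normal home-tissue expression)
# and ubiquitous genes (independent log-normal means in every tissue, at a
# lower expression scale). Replicate noise is multiplicative log-normal and
# mean-one, so expected sample values equal the true means; mix samples
# apply the noise per tissue component before the p-weighted summation.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the geometry of a 43-tissue uniform pool with one
#' unreplicated target tissue (`"cardiac_muscle"`), a handful of pooled
#' tissues lacking reference data (imputed downstream), fewer pooled-mix
#' libraries than reference replicates, and an ion-channel-like gene panel
#' dominated by tissue-restricted genes expressed well above the ubiquitous
#' background.
#'
#' @param n_genes Number of genes (default 1000).
#' @param tissues Either a tissue count `T` (labels are then generated, the
#'   first being `"cardiac_muscle"`) or a character vector of labels.
#'   Default 43.
#' @param unknown_tissue The pooled tissue without reference samples whose
#'   profile is to be recovered; defaults to the first tissue label.
#' @param n_replicates Reference samples per tissue (default 4).
#' @param n_mix_samples Pooled-mix samples (default 2; may be 0 when only
#'   tissue samples are needed).
#' @param meanlog_specific,sdlog_specific Log-scale mean and SD of the
#'   home-tissue expression of tissue-exclusive genes (defaults 3 and 1.5:
#'   median ~20 FPKM with a heavy upper tail).
#' @param meanlog_shared,sdlog_shared Log-scale mean and SD of ubiquitous
#'   genes' per-tissue means, drawn independently per tissue (defaults 0
#'   and 1: median 1 FPKM).
#' @param specificity_fraction Share of genes exclusive to one tissue
#'   (default 0.9); exclusive genes are assigned to tissues round-robin so
#'   every tissue receives some.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise (default 0.2).
#' @param missing_reference Tissues present in the pool but lacking
#'   reference data (imputed downstream). Default: the last 5 tissue labels
#'   when there are at least 8 tissues, otherwise none. Must not contain
#'   the unknown tissue.
#' @param mix_label Metadata tissue label of pooled samples (default
#'   `"mix"`).
#' @param library_size Total read count per sample used when converting
#'   FPKM back to integer counts (default 3e7).
#' @param seed Integer fixing all randomness (default 1).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 1000,
                             tissues = 43,
                             unknown_tissue = NULL,
                             n_replicates = 4,
                             n_mix_samples = 2,
                             meanlog_specific = 3,
                             sdlog_specific = 1.5,
                             meanlog_shared = 0,
                             sdlog_shared = 1,
                             specificity_fraction = 0.9,
                             noise_cv = 0.2,
                             missing_reference = NULL,
                             mix_label = "mix",
                             library_size = 3e7,
                             seed = 1) {
  if (!is_count(n_genes) || n_genes < 1) {
    abort("`n_genes` must be a positive integer")
  }
  if (is.numeric(tissues) && length(tissues) == 1L) {
    if (!is_count(tissues) || tissues < 2) {
      abort("`tissues` as a count must be an integer >= 2")
    }
    tissues <- c("cardiac_muscle",
                 sprintf("tissue_%02d", seq_len(tissues)[-1L]))
  }
  if (!is.character(tissues) || length(tissues) < 2L ||
      anyDuplicated(tissues) || !all(nzchar(tissues))) {
    abort("`tissues` must be >= 2 unique non-empty labels (or a count)")
  }
  if (is.null(unknown_tissue)) {
    unknown_tissue <- tissues[1L]
  }
  if (!is_string(unknown_tissue) || !unknown_tissue %in% tissues) {
    abort("`unknown_tissue` must be one of the tissue labels")
  }
  if (!is_count(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer")
  }
  if (!is_count(n_mix_samples)) {
    abort("`n_mix_samples` must be a non-negative integer")
  }
  for (nm in c("meanlog_specific", "meanlog_shared")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort("`%s` must be a single finite number", nm)
    }
  }
  for (nm in c("sdlog_specific", "sdlog_shared")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort("`%s` must be a single non-negative number", nm)
    }
  }
  if (!is.numeric(specificity_fraction) || length(specificity_fraction) != 1L ||
      is.na(specificity_fraction) || specificity_fraction < 0 ||
      specificity_fraction > 1) {
    abort("`specificity_fraction` must be in [0, 1]")
  }
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || !is.finite(noise_cv) ||
      noise_cv < 0) {
    abort("`noise_cv` must be a single non-negative number")
  }
  if (is.null(missing_reference)) {
    missing_reference <- if (length(tissues) >= 8L) {
      utils::tail(setdiff(tissues, unknown_tissue), 5L)
    } else {
      character(0)
    }
  }
  if (!is.character(missing_reference) ||
      !all(missing_reference %in% tissues)) {
    abort("`missing_reference` must be a subset of the tissue labels")
  }
  if (unknown_tissue %in% missing_reference) {
    abort("the unknown tissue is withheld by construction; do not list it in `missing_reference`")
  }
  if (length(setdiff(tissues, c(unknown_tissue, missing_reference))) < 1L) {
    abort("at least one tissue must retain reference data")
  }
  if (!is_string(mix_label) || mix_label %in% tissues) {
    abort("`mix_label` must be a non-empty label distinct from the tissues")
  }
  if (!is.numeric(library_size) || length(library_size) != 1L ||
      !is.finite(library_size) || library_size <= 0) {
    abort("`library_size` must be a single positive number")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed) ||
      seed != round(seed) || abs(seed) >= 2^31 - 10000) {
    abort("`seed` must be an integer below 2^31 - 10000 in magnitude")
  }
  structure(
    list(n_genes = as.integer(n_genes),
         tissues = tissues,
         p = 1 / length(tissues),
         unknown_tissue = unknown_tissue,
         n_replicates = as.integer(n_replicates),
         n_mix_samples = as.integer(n_mix_samples),
         meanlog_specific = meanlog_specific,
         sdlog_specific = sdlog_specific,
         meanlog_shared = meanlog_shared,
         sdlog_shared = sdlog_shared,
         specificity_fraction = specificity_fraction,
         noise_cv = noise_cv,
         missing_reference = missing_reference,
         mix_label = mix_label,
         library_size = library_size,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("synthetic_config: %d genes, %d tissues (p = 1/%d), unknown = '%s'\n",
              x$n_genes, length(x$tissues), length(x$tissues),
              x$unknown_tissue))
  cat(sprintf("  specificity %.2f, noise CV %.2f, %d replicate(s)/tissue, %d mix sample(s), %d tissue(s) unreferenced, seed %d\n",
              x$specificity_fraction, x$noise_cv, x$n_replicates,
              x$n_mix_samples, length(x$missing_reference), x$seed))
  invisible(x)
}

#' Generate the ground-truth tissue profiles
#'
#' Draws the true per-tissue, per-gene mean FPKM matrix: the configured
#' fraction of genes is exclusive to one tissue (assigned round-robin, home
#' expression log-normal), the remainder get independent log-normal means
#' in every tissue. Gene lengths (for count-level simulation) are drawn
#' uniformly between 200 and 10000 bp. Deterministic given the seed.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `synthetic_truth`: `means` (gene x tissue
#'   matrix), `home_tissue` (named vector, `NA` for ubiquitous genes),
#'   `gene_lengths`, and the `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tissues <- config$tissues
  n_genes <- config$n_genes
  gene_ids <- sprintf("gene_%05d", seq_len(n_genes))
  with_seed(config$seed, {
    n_spec <- round(config$specificity_fraction * n_genes)
    means <- matrix(0, nrow = n_genes, ncol = length(tissues),
                    dimnames = list(gene_ids, tissues))
    home <- setNames(rep(NA_character_, n_genes), gene_ids)
    if (n_spec > 0L) {
      home_idx <- rep_len(seq_along(tissues), n_spec)
      home[seq_len(n_spec)] <- tissues[home_idx]
      means[cbind(seq_len(n_spec), home_idx)] <-
        rlnorm(n_spec, config$meanlog_specific, config$sdlog_specific)
    }
    if (n_spec < n_genes) {
      shared <- (n_spec + 1L):n_genes
      means[shared, ] <- rlnorm(length(shared) * length(tissues),
                                config$meanlog_shared, config$sdlog_shared)
    }
    gene_lengths <- setNames(sample(200:10000, n_genes, replace = TRUE),
                             gene_ids)
    structure(
      list(means = means, home_tissue = home, gene_lengths = gene_lengths,
           config = config),
      class = "synthetic_truth"
    )
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d genes x %d tissues; %d tissue-exclusive gene(s)\n",
              nrow(x$means), ncol(x$means), sum(!is.na(x$home_tissue))))
  invisible(x)
}

# Mean-one multiplicative log-normal noise factors: exp(N(-s^2/2, s)) with
# s^2 = log(1 + CV^2), so E[factor] = 1 and SD[factor] = CV exactly.
noise_factors <- function(n, cv) {
  if (cv == 0) {
    return(rep(1, n))
  }
  s <- sqrt(log(1 + cv^2))
  exp(rnorm(n, -s^2 / 2, s))
}

#' Simulate replicate and pooled-mix samples from the truth
#'
#' Tissue samples are `true mean x noise` with mean-one multiplicative
#' log-normal noise of the configured CV; each pooled-mix sample is the
#' p-weighted sum of all tissues' means, the noise applied per tissue
#' component before summation so the pool's expectation is exactly the
#' uniform average of the tissue means. Reference samples are generated for
#' every tissue except the unknown tissue and those in
#' `missing_reference`; set `include_unknown = TRUE` to also emit samples
#' of the unknown tissue (for validation fixtures).
#'
#' @param truth A [generate_truth()] result.
#' @param include_unknown Also simulate replicate samples of the unknown
#'   tissue (default `FALSE`, matching the study design).
#' @param rng_seed Seed for the noise draws; defaults to `config$seed + 1`.
#'   Replicate experiments pass varying seeds to redraw noise around the
#'   same truth.
#' @return An [expression_matrix()] whose metadata labels tissue samples by
#'   tissue and pooled samples with the configured `mix_label`.
#' @export
simulate_samples <- function(truth, include_unknown = FALSE, rng_seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  config <- truth$config
  if (is.null(rng_seed)) {
    rng_seed <- config$seed + 1L
  }
  sampled <- setdiff(config$tissues,
                     c(if (!include_unknown) config$unknown_tissue,
                       config$missing_reference))
  n_genes <- nrow(truth$means)
  with_seed(rng_seed, {
    blocks <- list()
    meta <- list()
    for (t in sampled) {
      m <- truth$means[, t] *
        matrix(noise_factors(n_genes * config$n_replicates, config$noise_cv),
               nrow = n_genes)
      colnames(m) <- sprintf("%s_r%d", t, seq_len(config$n_replicates))
      blocks[[t]] <- m
      meta[[t]] <- data.frame(sample_id = colnames(m), tissue = t,
                              dataset = "synthetic", stringsAsFactors = FALSE)
    }
    if (config$n_mix_samples > 0L) {
      mix <- vapply(seq_len(config$n_mix_samples), function(k) {
        e <- matrix(noise_factors(length(truth$means), config$noise_cv),
                    nrow = n_genes)
        rowSums(truth$means * e) * config$p
      }, numeric(n_genes))
      colnames(mix) <- sprintf("mix_%d", seq_len(config$n_mix_samples))
      blocks[["..mix"]] <- mix
      meta[["..mix"]] <- data.frame(sample_id = colnames(mix),
                                    tissue = config$mix_label,
                                    dataset = "synthetic",
                                    stringsAsFactors = FALSE)
    }
    values <- do.call(cbind, unname(blocks))
    rownames(values) <- rownames(truth$means)
    expression_matrix(values, do.call(rbind, unname(meta)))
  })
}

#' Convert FPKM values back to integer read counts
#'
#' Inverts the FPKM formula at a stated library size and rounds:
#' `count = round(fpkm * length_bp * library_size / 1e9)`. Because of the
#' rounding, re-normalising recovers the input FPKM only approximately; the
#' conversion exists to exercise the count-level entry of the pipeline.
#'
#' @param expr An [expression_matrix()] of FPKM values.
#' @param gene_lengths Named numeric vector of lengths (base pairs) covering
#'   all genes of `expr`.
#' @param library_size Total mapped reads per sample (default 3e7).
#' @return A [count_matrix()].
#' @export
expression_to_counts <- function(expr, gene_lengths, library_size = 3e7) {
  expr <- as_expression_matrix(expr)
  missing <- setdiff(rownames(expr$values), names(gene_lengths))
  if (length(missing) > 0L) {
    abort("gene(s) without a length: %s", oxford(missing))
  }
  len <- gene_lengths[rownames(expr$values)]
  counts <- round(expr$values * len * library_size / 1e9)
  count_matrix(counts, len)
}

#' Parameter-recovery experiment
#'
#' Generates truth, simulates samples with the target tissue's reference
#' data withheld, runs the full prediction pipeline, and scores the
#' predictions against the known target means. The headline recovery
#' correlation is computed over the genes whose true target expression
#' alone contributes at least `expressed_threshold` FPKM to the mix mean
#' (`p * true target mean >= threshold`) — the regime in which the pool
#' carries a usable target signal.
#'
#' @param config A [synthetic_config()].
#' @param expressed_threshold Minimum true target contribution to the mix
#'   mean, in FPKM (default 0.5).
#' @return Object of class `recovery_report`: the `predictions` table, the
#'   true target means, the pipeline `report`, and `metrics`:
#'   `r_expressed` (Pearson r, predicted vs true, over the expressed set),
#'   `n_expressed`, `max_rel_error` (over predicted genes with positive
#'   truth), `drop_rate_zero_truth` (referenced-home genes only),
#'   `fp_rate_imputed_home` (genes exclusive to an unreferenced tissue that
#'   were nevertheless "predicted"), and `coverage_2sd`.
#' @export
recovery_experiment <- function(config, expressed_threshold = 0.5) {
  stopifnot(inherits(config, "synthetic_config"))
  truth <- generate_truth(config)
  if (config$n_mix_samples < 1L) {
    abort("recovery needs at least one mix sample")
  }
  sim <- simulate_samples(truth)
  design <- mix_design(config$tissues, config$unknown_tissue,
                       mix_label = config$mix_label)
  run <- run_prediction_pipeline(sim, design = design)
  pred <- run$predictions
  truth_target <- truth$means[, config$unknown_tissue]
  stopifnot(all(pred$gene %in% names(truth_target)))
  tt <- truth_target[pred$gene]

  predicted <- pred$status == "predicted"
  expressed <- config$p * tt >= expressed_threshold
  sel <- predicted & expressed
  r_expressed <- if (sum(sel) >= 3L) {
    cor(pred$predicted_mean[sel], tt[sel])
  } else {
    NA_real_
  }
  pos <- predicted & tt > 0
  rel_err <- abs(pred$predicted_mean[pos] - tt[pos]) / tt[pos]

  home <- truth$home_tissue[pred$gene]
  zero_truth <- !is.na(home) & home != config$unknown_tissue
  ref_home <- zero_truth & !(home %in% config$missing_reference)
  imp_home <- zero_truth & home %in% config$missing_reference
  cover <- pos & !is.na(pred$predicted_sd)
  metrics <- list(
    r_expressed = r_expressed,
    n_expressed = sum(sel),
    max_rel_error = if (any(pos)) max(rel_err) else NA_real_,
    drop_rate_zero_truth = if (any(ref_home)) {
      mean(pred$status[ref_home] == "dropped_negative")
    } else {
      NA_real_
    },
    fp_rate_imputed_home = if (any(imp_home)) {
      mean(pred$status[imp_home] == "predicted")
    } else {
      NA_real_
    },
    coverage_2sd = if (any(cover)) {
      mean(abs(pred$predicted_mean[cover] - tt[cover]) <=
             2 * pred$predicted_sd[cover])
    } else {
      NA_real_
    }
  )
  structure(
    list(predictions = pred, truth_target = truth_target,
         report = run$report, metrics = metrics, config = config,
         expressed_threshold = expressed_threshold),
    class = "recovery_report"
  )
}

#' @export
print.recovery_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("recovery_report (%d genes, %d tissues, CV %.2f, seed %d)\n",
              x$config$n_genes, length(x$config$tissues),
              x$config$noise_cv, x$config$seed))
  cat(sprintf("  r(predicted, truth) = %s over %d expressed gene(s) (p*truth >= %s FPKM)\n",
              format(m$r_expressed, digits = 4), m$n_expressed,
              format(x$expressed_threshold)))
  cat(sprintf("  max relative error %s; zero-truth drop rate %s; imputed-home false-positive rate %s\n",
              format(m$max_rel_error, digits = 3),
              format(m$drop_rate_zero_truth, digits = 3),
              format(m$fp_rate_imputed_home, digits = 3)))
  invisible(x)
}

#' Monte-Carlo calibration of the propagated standard deviation
#'
#' Checks the independence-based propagation formula against the empirical
#' spread of the estimator. Each Monte-Carlo replicate draws one pooled-mix
#' observation (noise per tissue component) and one observation per
#' non-target tissue, forms the estimate `H = mix/p - sum(refs)`, and the
#' empirical per-gene SD over replicates is compared with
#' [propagate_prediction_sd()] fed the population SDs (`true mean x CV` per
#' tissue; `p x CV x sqrt(sum of squared means)` for the mix). All
#' non-target tissues are treated as referenced here — the experiment
#' calibrates the propagation formula, which presumes observed spreads for
#' every term.
#'
#' @param config A [synthetic_config()] with `noise_cv > 0`.
#' @param n_reps Monte-Carlo replicates (default 500).
#' @return Object of class `sd_calibration_report`: per-gene `propagated`
#'   and `empirical` SDs, their `ratio`, `median_ratio`, and
#'   `frac_within_15` (share of genes with a ratio within 15% of 1).
#' @export
sd_calibration_experiment <- function(config, n_reps = 500) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$noise_cv <= 0) {
    abort("SD calibration needs `noise_cv` > 0")
  }
  if (!is_count(n_reps) || n_reps < 10) {
    abort("`n_reps` must be an integer >= 10")
  }
  truth <- generate_truth(config)
  alpha <- truth$means
  others <- setdiff(config$tissues, config$unknown_tissue)
  cv <- config$noise_cv
  p <- config$p
  n_genes <- nrow(alpha)

  profiles <- tissue_profiles(data.frame(
    gene = rep(rownames(alpha), times = length(others)),
    tissue = rep(others, each = n_genes),
    mean = as.numeric(alpha[, others]),
    sd = as.numeric(alpha[, others]) * cv,
    n = NA_real_,
    imputed = FALSE,
    stringsAsFactors = FALSE
  ))
  design <- mix_design(config$tissues, config$unknown_tissue,
                       mix_label = config$mix_label)
  mix_sd_true <- setNames(p * cv * sqrt(rowSums(alpha^2)), rownames(alpha))
  propagated <- propagate_prediction_sd(mix_sd_true, profiles, design)

  H <- with_seed(config$seed + 2L, {
    vapply(seq_len(n_reps), function(rep) {
      e_mix <- matrix(noise_factors(length(alpha), cv), nrow = n_genes)
      mix_value <- rowSums(alpha * e_mix) * p
      e_ref <- matrix(noise_factors(n_genes * length(others), cv),
                      nrow = n_genes)
      mix_value / p - rowSums(alpha[, others, drop = FALSE] * e_ref)
    }, numeric(n_genes))
  })
  empirical <- row_sds(H)
  ratio <- propagated[rownames(alpha)] / empirical
  structure(
    list(propagated = propagated, empirical = empirical, ratio = ratio,
         median_ratio = median(ratio),
         frac_within_15 = mean(abs(ratio - 1) <= 0.15),
         n_reps = n_reps, config = config),
    class = "sd_calibration_report"
  )
}

#' @export
print.sd_calibration_report <- function(x, ...) {
  cat(sprintf("sd_calibration_report: %d replicates, %d genes\n",
              x$n_reps, length(x$ratio)))
  cat(sprintf("  propagated/empirical SD ratio: median %.3f; %.1f%% of genes within 15%%\n",
              x$median_ratio, 100 * x$frac_within_15))
  invisible(x)
}

#' Drop behaviour for genes with zero target expression
#'
#' Re-simulates the noisy samples many times around a fixed truth and runs
#' the full prediction pipeline each time, recording how often genes whose
#' true target expression is zero end up `dropped_negative`. The frequency
#' is pooled over all such genes whose home tissue has reference data (for
#' those the estimator is zero-mean, so the drop rule should fire about
#' half the time or more); genes exclusive to an unreferenced (imputed)
#' tissue have a positively biased estimator and are reported separately as
#' a false-positive rate.
#'
#' @param config A [synthetic_config()] with at least one tissue-exclusive
#'   non-target gene and `noise_cv > 0`.
#' @param n_reps Number of noisy re-simulations (default 200).
#' @return Object of class `zero_expression_report`: `drop_rate` (pooled
#'   over referenced-home zero-truth genes and replicates),
#'   `fp_rate_imputed_home`, `n_zero_genes`, `n_imputed_home_genes`,
#'   `n_reps`.
#' @export
zero_expression_experiment <- function(config, n_reps = 200) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$noise_cv <= 0) {
    abort("the zero-expression experiment needs `noise_cv` > 0")
  }
  if (!is_count(n_reps) || n_reps < 1) {
    abort("`n_reps` must be a positive integer")
  }
  truth <- generate_truth(config)
  home <- truth$home_tissue
  zero_truth <- !is.na(home) & home != config$unknown_tissue
  ref_home <- names(home)[zero_truth & !(home %in% config$missing_reference)]
  imp_home <- names(home)[zero_truth & home %in% config$missing_reference]
  if (length(ref_home) == 0L) {
    abort("no zero-truth gene with a referenced home tissue; raise `specificity_fraction`")
  }
  design <- mix_design(config$tissues, config$unknown_tissue,
                       mix_label = config$mix_label)
  drops <- 0L
  fps <- 0L
  for (rep in seq_len(n_reps)) {
    sim <- simulate_samples(truth, rng_seed = config$seed + 1000L + rep)
    run <- run_prediction_pipeline(sim, design = design)
    st <- setNames(run$predictions$status, run$predictions$gene)
    drops <- drops + sum(st[ref_home] == "dropped_negative")
    fps <- fps + sum(st[imp_home] == "predicted")
  }
  structure(
    list(drop_rate = drops / (n_reps * length(ref_home)),
         fp_rate_imputed_home = if (length(imp_home) > 0L) {
           fps / (n_reps * length(imp_home))
         } else {
           NA_real_
         },
         n_zero_genes = length(ref_home),
         n_imputed_home_genes = length(imp_home),
         n_reps = n_reps,
         config = config),
    class = "zero_expression_report"
  )
}

#' @export
print.zero_expression_report <- function(x, ...) {
  cat(sprintf("zero_expression_report: %d replicates, %d zero-truth gene(s)\n",
              x$n_reps, x$n_zero_genes))
  cat(sprintf("  dropped_negative rate %.3f; imputed-home false-positive rate %s\n",
              x$drop_rate, format(x$fp_rate_imputed_home, digits = 3)))
  invisible(x)
}
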