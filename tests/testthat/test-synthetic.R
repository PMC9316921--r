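test_that("the generator is bit-reproducible under a fixed seed", {
  cfg <- synthetic_config(n_genes = 50, tissues = 6, seed = 1)
  t1 <- generate_truth(cfg)
  t2 <- generate_truth(cfg)
  expect_identical(t1$means, t2$means)
  expect_identical(t1$gene_lengths, t2$gene_lengths)
  s1 <- simulate_samples(t1)
  s2 <- simulate_samples(t2)
  expect_identical(s1$values, s2$values)
  # generation must not disturb the caller's RNG stream
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(generate_truth(cfg))
  expect_identical(rnorm(3), before)
})

test_that("the specificity fraction controls tissue exclusivity", {
  cfg1 <- synthetic_config(n_genes = 40, tissues = 5,
                           specificity_fraction = 1, seed = 2)
  t1 <- generate_truth(cfg1)
  expect_true(all(rowSums(t1$means > 0) == 1))
  expect_true(all(table(t1$home_tissue) > 0)) # round-robin covers all tissues

  cfg0 <- synthetic_config(n_genes = 40, tissues = 5,
                           specificity_fraction = 0, sdlog_shared = 0,
                           meanlog_shared = 1.5, seed = 2)
  t0 <- generate_truth(cfg0)
  expect_true(all(t0$means == exp(1.5)))
  expect_true(all(is.na(t0$home_tissue)))
})

test_that("noise-free samples equal the truth and mixes the p-weighted sum", {
  cfg <- synthetic_config(n_genes = 30, tissues = 4, noise_cv = 0,
                          missing_reference = character(0), seed = 3)
  truth <- generate_truth(cfg)
  sim <- simulate_samples(truth, include_unknown = TRUE)
  for (t in cfg$tissues) {
    cols <- sim$metadata$sample_id[sim$metadata$tissue == t]
    for (col in cols) {
      expect_equal(unname(sim$values[, col]), unname(truth$means[, t]))
    }
  }
  mix_cols <- sim$metadata$sample_id[sim$metadata$tissue == cfg$mix_label]
  expected_mix <- rowSums(truth$means) * cfg$p
  for (col in mix_cols) {
    expect_equal(unname(sim$values[, col]), unname(expected_mix))
  }
})

test_that("replicate noise is mean-preserving", {
  # one tissue observed many times; empirical means within 3 standard errors
  cfg <- synthetic_config(n_genes = 20, tissues = 2, n_replicates = 1000,
                          n_mix_samples = 0, noise_cv = 0.3,
                          specificity_fraction = 0, seed = 3)
  truth <- generate_truth(cfg)
  sim <- simulate_samples(truth)
  t <- setdiff(cfg$tissues, cfg$unknown_tissue)
  cols <- sim$metadata$sample_id[sim$metadata$tissue == t]
  emp <- rowMeans(sim$values[, cols])
  se <- truth$means[, t] * cfg$noise_cv / sqrt(length(cols))
  expect_true(all(abs(emp - truth$means[, t]) <= 3 * se))
})

test_that("count conversion inverts FPKM up to a per-sample scale", {
  cfg <- synthetic_config(n_genes = 80, tissues = 4, noise_cv = 0.1, seed = 6)
  truth <- generate_truth(cfg)
  sim <- simulate_samples(truth)
  cm <- expression_to_counts(sim, truth$gene_lengths, library_size = 1e8)
  expect_true(all(cm$counts == round(cm$counts)))
  back <- fpkm_normalize(cm, sim$metadata)
  # FPKM only retains within-sample proportions: the recovered values match
  # the originals up to one multiplicative constant per sample
  for (s in colnames(sim$values)) {
    pos <- sim$values[, s] > 0 & cm$counts[, s] > 0
    expect_gt(cor(back$values[pos, s], sim$values[pos, s]), 0.999)
    # the scale factor is constant where rounding is negligible
    solid <- pos & cm$counts[, s] >= 20
    ratio <- back$values[solid, s] / sim$values[solid, s]
    expect_lt(sd(ratio) / mean(ratio), 0.02)
  }
})

test_that("recovery error shrinks as the number of mix samples grows", {
  err <- sapply(c(1L, 8L), function(nm) {
    cfg <- synthetic_config(n_genes = 400, tissues = 10, n_mix_samples = nm,
                            noise_cv = 0.3, missing_reference = character(0),
                            seed = 13)
    rec <- recovery_experiment(cfg, expressed_threshold = 0.2)
    pred <- rec$predictions
    tt <- rec$truth_target[pred$gene]
    sel <- pred$status == "predicted" & cfg$p * tt >= 0.2
    median(abs(pred$predicted_mean[sel] - tt[sel]) / tt[sel])
  })
  expect_lt(err[2], err[1])
})

test_that("the recovery experiment reports the pipeline's gene accounting", {
  cfg <- synthetic_config(n_genes = 200, tissues = 10, seed = 4)
  rec <- recovery_experiment(cfg)
  expect_s3_class(rec, "recovery_report")
  r <- rec$report
  expect_identical(r$n_predicted + r$n_dropped_negative + r$n_dropped_no_mix,
                   cfg$n_genes)
  expect_identical(sort(r$imputed_tissues), sort(cfg$missing_reference))
  expect_true(is.finite(rec$metrics$r_expressed) ||
                is.na(rec$metrics$r_expressed))
})

test_that("single-draw estimator used for SD calibration matches the predictor", {
  cfg <- synthetic_config(n_genes = 25, tissues = 5, noise_cv = 0.2,
                          missing_reference = character(0), seed = 8)
  truth <- generate_truth(cfg)
  others <- setdiff(cfg$tissues, cfg$unknown_tissue)
  set.seed(31)
  s <- sqrt(log(1 + cfg$noise_cv^2))
  e_mix <- matrix(exp(rnorm(length(truth$means), -s^2 / 2, s)),
                  nrow = nrow(truth$means))
  mix_value <- rowSums(truth$means * e_mix) * cfg$p
  e_ref <- matrix(exp(rnorm(nrow(truth$means) * length(others), -s^2 / 2, s)),
                  nrow = nrow(truth$means))
  ref_draw <- truth$means[, others, drop = FALSE] * e_ref

  # route A: direct single-draw arithmetic (as in the calibration loop)
  direct <- mix_value / cfg$p - rowSums(ref_draw)

  # route B: the package predictor fed the same draws as profiles
  prof <- tissue_profiles(data.frame(
    gene = rep(rownames(truth$means), times = length(others)),
    tissue = rep(others, each = nrow(truth$means)),
    mean = as.numeric(ref_draw), sd = 0, n = 1, imputed = FALSE
  ))
  design <- mix_design(cfg$tissues, cfg$unknown_tissue,
                       mix_label = cfg$mix_label)
  pred <- predict_unknown_tissue(setNames(mix_value, rownames(truth$means)),
                                 prof, design)
  expect_equal(setNames(pred$predicted_mean, pred$gene),
               setNames(direct, rownames(truth$means)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(tissues = 1), ">= 2")
  expect_error(synthetic_config(specificity_fraction = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(noise_cv = -0.1), "non-negative")
  expect_error(synthetic_config(tissues = 5, missing_reference = "nope"),
               "subset")
  expect_error(
    synthetic_config(tissues = 5, unknown_tissue = "cardiac_muscle",
                     missing_reference = "cardiac_muscle"),
    "withheld"
  )
  expect_error(synthetic_config(seed = 2^31), "seed")
})
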