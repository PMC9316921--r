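test_that("tissue profiles use the n-1 standard deviation convention", {
  meta <- toy_metadata(c("a1", "a2", "b1", "c1", "c2", "c3"),
                       c("A", "A", "B", "C", "C", "C"))
  vals <- rbind(
    g1 = c(2, 4, 5, 7, 7, 7),
    g2 = c(0, 0, 1, 2, 3, 4)
  )
  colnames(vals) <- meta$sample_id
  prof <- compute_tissue_profiles(expression_matrix(vals, meta))

  a <- prof[prof$tissue == "A" & prof$gene == "g1", ]
  expect_equal(a$mean, 3)
  expect_equal(a$sd, sqrt(2))
  expect_identical(a$n, 2L)

  b <- prof[prof$tissue == "B" & prof$gene == "g1", ]
  expect_equal(b$mean, 5)
  expect_identical(b$sd, 0) # single replicate carries no spread

  c1 <- prof[prof$tissue == "C" & prof$gene == "g1", ]
  expect_identical(c1$sd, 0) # identical replicates

  expect_error(compute_tissue_profiles(expression_matrix(vals, meta),
                                       tissues = c("A", "Z")),
               "zero samples.*Z")
})

test_that("median imputation fills unreferenced mix tissues per gene", {
  prof <- toy_profiles(list(
    A = c(g1 = 1, g2 = 1, g3 = 0),
    B = c(g1 = 3, g2 = 3, g3 = 0),
    C = c(g1 = 5, g2 = 10, g3 = 4)
  ))
  d3 <- mix_design(c("target", "A", "B", "C", "M1"), "target", p = 1 / 5)
  imp <- impute_missing_tissue_means(prof, d3)
  expect_identical(attr(imp, "imputed_tissues"), "M1")
  m1 <- imp[imp$tissue == "M1", ]
  expect_true(all(m1$imputed))
  expect_equal(m1$mean[m1$gene == "g1"], 3)   # odd-count median of {1,3,5}
  expect_equal(m1$mean[m1$gene == "g3"], 0)   # median of {0,0,4}

  # even-count median is the midpoint of the two central values
  d2 <- mix_design(c("target", "A", "B", "M1"), "target", p = 1 / 4)
  prof2 <- toy_profiles(list(A = c(g1 = 1), B = c(g1 = 3)))
  imp2 <- impute_missing_tissue_means(prof2, d2)
  expect_equal(imp2$mean[imp2$tissue == "M1"], 2)

  # two imputed tissues receive the same per-gene median
  d4 <- mix_design(c("target", "A", "B", "C", "M1", "M2"), "target", p = 1 / 6)
  imp4 <- impute_missing_tissue_means(prof, d4)
  expect_equal(imp4$mean[imp4$tissue == "M1" & imp4$gene == "g3"], 0)
  expect_equal(imp4$mean[imp4$tissue == "M2" & imp4$gene == "g3"], 0)

  # imputed SD is the median of the known SDs, not zero
  profs <- toy_profiles(list(A = c(g1 = 1), B = c(g1 = 3), C = c(g1 = 5)),
                        sds = list(A = c(g1 = 0.1), B = c(g1 = 0.3),
                                   C = c(g1 = 0.5)))
  imps <- impute_missing_tissue_means(profs, d3)
  expect_equal(imps$sd[imps$tissue == "M1"], 0.3)
})

test_that("the mix design enforces its invariants up front", {
  expect_error(mix_design(c("A", "B"), "A", p = 0.4), "1/T")
  expect_error(mix_design(c("A", "B"), "C"), "unknown_tissue")
  expect_error(mix_design(c("A", "A", "B"), "A"), "duplicate")
  expect_error(mix_design(c("A", "B", "C"), "A",
                          mapping = c(A = "ref1", B = "ref2", C = "ref3")),
               "must not be mapped")
  expect_error(mix_design(c("A", "B", "C"), "A", mapping = c(B = "ref1")),
               "without a mapping.*C")
})

test_that("the estimator inverts the uniform mixture", {
  # target-exclusive gene: T = 43, p = 1/43, mix mean 1, all other means 0
  others <- sprintf("t%02d", 1:42)
  prof <- toy_profiles(setNames(
    lapply(others, function(t) c(gX = 0)), others
  ))
  d43 <- mix_design(c("target", others), "target")
  pred <- predict_unknown_tissue(c(gX = 1), prof, d43)
  expect_equal(pred$predicted_mean, 43)
  expect_identical(pred$status, "predicted")

  # forward-simulate a 3-tissue mix noise-free, then invert: exact recovery
  d3 <- mix_design(c("target", "A", "B"), "target", p = 1 / 3)
  truth <- c(target = 6, A = 2, B = 4)
  mix_mean <- c(gY = mean(truth)) # 4 = (6+2+4)/3
  prof3 <- toy_profiles(list(A = c(gY = 2), B = c(gY = 4)))
  pred3 <- predict_unknown_tissue(mix_mean, prof3, d3)
  expect_equal(pred3$predicted_mean, 6)

  # zero mix signal with positive reference means is dropped, raw kept
  pred0 <- predict_unknown_tissue(c(gY = 0), prof3, d3)
  expect_identical(pred0$status, "dropped_negative")
  expect_equal(pred0$predicted_mean, -6)

  # genes absent from the mix cannot be estimated
  predna <- predict_unknown_tissue(c(gY = NA_real_), prof3, d3)
  expect_identical(predna$status, "dropped_no_mix")
  expect_true(is.na(predna$predicted_mean))
})

test_that("the estimator is linear in the mix mean and reference means", {
  d3 <- mix_design(c("target", "A", "B"), "target", p = 1 / 3)
  prof <- toy_profiles(list(A = c(g = 2), B = c(g = 4)))
  base <- predict_unknown_tissue(c(g = 4), prof, d3)$predicted_mean
  delta <- 0.25
  up <- predict_unknown_tissue(c(g = 4 + delta), prof, d3)$predicted_mean
  expect_equal(up - base, delta * 3) # delta / p
  prof_up <- toy_profiles(list(A = c(g = 2 + delta), B = c(g = 4)))
  down <- predict_unknown_tissue(c(g = 4), prof_up, d3)$predicted_mean
  expect_equal(base - down, delta)
})

test_that("a many-to-one mapping counts the shared reference once per mix tissue", {
  # cerebrum and cerebellum both mapped to the single 'brain' reference
  d <- mix_design(c("heart", "cerebrum", "cerebellum", "liver"), "heart",
                  p = 1 / 4,
                  mapping = c(cerebrum = "brain", cerebellum = "brain",
                              liver = "liver"))
  prof <- toy_profiles(list(brain = c(g = 5), liver = c(g = 1)))
  pred <- predict_unknown_tissue(c(g = 4), prof, d)
  expect_equal(pred$predicted_mean, 4 * 4 - (5 + 5 + 1))
})

test_that("SD propagation follows independence-based quadrature", {
  d2 <- mix_design(c("target", "A"), "target", p = 1 / 2)
  prof <- toy_profiles(list(A = c(g = 1)), sds = list(A = c(g = 0.2)))
  out <- propagate_prediction_sd(c(g = 0.1), prof, d2)
  expect_equal(unname(out), sqrt(0.1^2 / 0.25 + 0.2^2)) # sqrt(0.08)

  zero <- propagate_prediction_sd(
    c(g = 0),
    toy_profiles(list(A = c(g = 1)), sds = list(A = c(g = 0))),
    d2
  )
  expect_identical(unname(zero), 0)

  doubled <- propagate_prediction_sd(
    c(g = 0.2),
    toy_profiles(list(A = c(g = 1)), sds = list(A = c(g = 0.4))),
    d2
  )
  expect_equal(unname(doubled), 2 * unname(out)) # homogeneity

  expect_error(propagate_prediction_sd(c(g = -0.1), prof, d2), "negative")
})

test_that("noise-free conservation holds to 1e-12 relative tolerance", {
  for (seed in c(1, 42)) {
    cfg <- synthetic_config(n_genes = 120, tissues = 6, noise_cv = 0,
                            missing_reference = character(0), seed = seed)
    truth <- generate_truth(cfg)
    sim <- simulate_samples(truth)
    design <- mix_design(cfg$tissues, cfg$unknown_tissue,
                         mix_label = cfg$mix_label)
    prof_all <- compute_tissue_profiles(sim)
    mix_rows <- prof_all[prof_all$tissue == cfg$mix_label, ]
    mix_mean <- setNames(mix_rows$mean, mix_rows$gene)
    ref <- prof_all[prof_all$tissue != cfg$mix_label, ]
    pred <- predict_unknown_tissue(mix_mean, ref, design)

    # independent reconstruction of the reference sum from the long table
    ref_sum <- tapply(ref$mean, ref$gene, sum)
    lhs <- cfg$p * (pred$predicted_mean + ref_sum[pred$gene])
    rel <- abs(lhs - mix_mean[pred$gene]) /
      pmax(abs(mix_mean[pred$gene]), .Machine$double.eps)
    expect_lt(max(rel), 1e-12)
  }
})

test_that("pipeline stage counts always sum to the input gene count", {
  cfg <- synthetic_config(n_genes = 150, tissues = 8, noise_cv = 0.3,
                          seed = 3)
  truth <- generate_truth(cfg)
  sim <- simulate_samples(truth)
  counts <- expression_to_counts(sim, truth$gene_lengths)
  design <- mix_design(cfg$tissues, cfg$unknown_tissue,
                       mix_label = cfg$mix_label)
  run <- run_prediction_pipeline(counts, sim$metadata, design, min_total = 10)
  r <- run$report
  expect_identical(
    r$n_input,
    r$n_low_count_removed + r$n_predicted + r$n_dropped_negative +
      r$n_dropped_no_mix
  )
  expect_identical(nrow(run$predictions), r$n_input - r$n_low_count_removed)
  expect_identical(sort(r$imputed_tissues), sort(cfg$missing_reference))
})

test_that("pipeline errors carry the failing stage's name", {
  cfg <- synthetic_config(n_genes = 30, tissues = 4, noise_cv = 0,
                          n_mix_samples = 0, seed = 2)
  sim <- simulate_samples(generate_truth(cfg))
  design <- mix_design(cfg$tissues, cfg$unknown_tissue,
                       mix_label = cfg$mix_label)
  expect_error(run_prediction_pipeline(sim, design = design),
               "\\[profiles\\]")
})
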