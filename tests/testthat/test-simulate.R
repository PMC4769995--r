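test_that("simulation is deterministic under a fixed configuration", {
  cfg <- small_config(9)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
})

test_that("category labels are consistent with per-sample occurrence", {
  cohort <- small_cohort(42)
  occ <- dplyr::summarise(
    dplyr::group_by(cohort$changes, .data$patient_id, .data$chrom, .data$pos,
                    .data$ref, .data$alt),
    n = dplyr::n_distinct(.data$sample_id),
    fixatives = paste(sort(unique(.data$fixative)), collapse = ","),
    .groups = "drop"
  )
  j <- dplyr::inner_join(cohort$truth, occ,
                         by = c("patient_id", "chrom", "pos", "ref", "alt"))
  expect_equal(nrow(j), nrow(cohort$truth))
  n_samples <- length(unique(cohort$changes$sample_id)) /
    length(unique(cohort$changes$patient_id))
  common <- j[j$label == "common", ]
  expect_true(all(common$n == n_samples))
  uniq <- j[j$label != "common", ]
  expect_true(all(uniq$n == 1))
  expect_equal(sub("-unique", "", uniq$label), uniq$fixatives)
})

test_that("emitted changes match the channel they were sampled from", {
  cohort <- small_cohort(42)
  ann <- annotate_channels(cohort$truth, cohort$reference)
  expect_equal(attr(ann, "n_dropped"), 0L)
  expect_equal(ann$channel, cohort$truth$channel)
})

test_that("burden limit cases produce pure common or pure unique tables", {
  ref <- generate_reference(20000, seed = 3)
  cfg0 <- sim_config(n_patients = 2, reference_length = 20000,
                     burden_common = 40, burden_unique = 0, seed = 3)
  bc <- simulate_base_changes(cfg0, ref)
  expect_true(all(bc$truth$label == "common"))
  cfg1 <- sim_config(n_patients = 2, reference_length = 20000,
                     burden_common = 0, burden_unique = 40, seed = 3)
  bc1 <- simulate_base_changes(cfg1, ref)
  expect_true(all(bc1$truth$label != "common"))
  keys <- paste(bc1$changes$patient_id, bc1$changes$pos)
  expect_false(any(duplicated(keys)))
})

test_that("a one-hot common signature yields only that channel, at Poisson rate", {
  sig <- matrix(0, 96, 2)
  sig[, 1] <- 1 / 96
  sig[sbs_channels() == "A[C>T]G", 2] <- 1
  ref <- generate_reference(20000, seed = 5)
  totals <- vapply(1:200, function(s) {
    cfg <- sim_config(
      n_patients = 1, sample_types = "surgical", reference_length = 20000,
      planted_signatures = sig, common_signature_index = 2L,
      fixative_noise_weights = matrix(1, 3, 1,
                                      dimnames = list(c("SF", "UMFIX", "NBF"))),
      burden_common = 50, burden_unique = 0, burden_dispersion = 0, seed = s
    )
    bc <- simulate_base_changes(cfg, ref)
    expect_true(all(bc$truth$channel == "A[C>T]G"))
    nrow(bc$truth)
  }, 0)
  # empirical mean of Poisson(50) over 200 seeds, within 3 standard errors
  expect_lt(abs(mean(totals) - 50), 3 * sqrt(50 / 200))
})

test_that("an unrepresentable channel fails naming the channel", {
  sig <- matrix(0, 96, 2)
  sig[, 1] <- 1 / 96
  sig[sbs_channels() == "A[C>T]G", 2] <- 1
  ref <- paste(rep("A", 2000), collapse = "")  # no ACG context anywhere
  cfg <- sim_config(
    n_patients = 1, reference_length = 2000, planted_signatures = sig,
    common_signature_index = 2L,
    fixative_noise_weights = matrix(1, 3, 1,
                                    dimnames = list(c("SF", "UMFIX", "NBF"))),
    burden_common = 10, burden_unique = 0, seed = 1
  )
  expect_error(simulate_base_changes(cfg, ref), "A\\[C>T\\]G")
})

test_that("noiseless copy-number counts are exactly piecewise-constant", {
  cfg <- sim_config(n_patients = 2, sample_types = "surgical",
                    cn_n_bins = 50, cn_n_segments = 3,
                    cn_noise_sd = c(SF = 0, UMFIX = 0, NBF = 0), seed = 4)
  cn <- simulate_cn_counts(cfg)
  one <- cn$counts[cn$counts$sample_id == cn$counts$sample_id[1], ]
  tr <- cn$truth[cn$truth$patient_id == one$patient_id[1], ]
  expect_equal(one$count, cfg$read_depth_mean * tr$state / 2)
})

test_that("per-fixative copy-number noise reproduces the configured ordering", {
  sds <- sapply(1:5, function(r) {
    cfg <- sim_config(n_patients = 4, sample_types = "surgical",
                      cn_n_bins = 100, seed = 100 + r)
    cn <- simulate_cn_counts(cfg)
    j <- dplyr::inner_join(cn$counts, cn$truth, by = c("patient_id", "bin"))
    j$dev <- log2(j$count / cfg$read_depth_mean) - j$logratio_truth
    tapply(j$dev, j$fixative, stats::sd)[c("SF", "UMFIX", "NBF")]
  })
  med <- apply(sds, 1, stats::median)
  expect_lt(med["SF"], med["UMFIX"])
  expect_lt(med["UMFIX"], med["NBF"])
})

test_that("noiseless qPCR tables reproduce the configured means exactly", {
  cfg <- sim_config(n_patients = 2, qpcr_noise_sd = 0, seed = 6)
  qp <- simulate_qpcr(cfg)
  expect_equal(qp$cq,
               cfg$qpcr_mean_cq[cbind(qp$fixative, as.character(qp$amplicon_bp))])
})

test_that("the default preset orders long-amplicon loss NBF > UMFIX", {
  cfg <- sim_config(seed = 8)
  qp <- simulate_qpcr(cfg)
  d305 <- tapply(qp$cq[qp$amplicon_bp == 305], qp$fixative[qp$amplicon_bp == 305],
                 mean) - cfg$qpcr_control_cq[["305"]]
  expect_gt(d305[["NBF"]], d305[["UMFIX"]])
  expect_gt(d305[["UMFIX"]], d305[["SF"]])
})

test_that("the blacklist contains real keys and decoys", {
  cohort <- small_cohort(42)
  truth_keys <- paste(cohort$truth$chrom, cohort$truth$pos,
                      cohort$truth$ref, cohort$truth$alt)
  bl_keys <- paste(cohort$blacklist$chrom, cohort$blacklist$pos,
                   cohort$blacklist$ref, cohort$blacklist$alt)
  n_hit <- sum(bl_keys %in% truth_keys)
  expect_gt(n_hit, 0)
  expect_gt(length(bl_keys) - n_hit, 0)
})
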