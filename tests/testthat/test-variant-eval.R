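toy_truth <- function(n_panel = 100, n_true = 10) {
  list(panel = tibble::tibble(chrom = "chr1", pos = seq_len(n_panel)),
       variants = tibble::tibble(chrom = "chr1", pos = seq_len(n_true),
                                 ref = "A", alt = "T"))
}

test_that("perfect and empty call sets give the boundary confusion counts", {
  tr <- toy_truth()
  perfect <- classify_calls(tr$variants, tr)
  expect_equal(perfect[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 10L, fp = 0L, fn = 0L, tn = 90L))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  none <- classify_calls(tr$variants[0, ], tr)
  expect_equal(none[, c("tp", "fp", "fn", "tn")],
               tibble::tibble(tp = 0L, fp = 0L, fn = 10L, tn = 90L))
})

test_that("9 found + 2 spurious give sensitivity 0.9 and specificity 88/90", {
  tr <- toy_truth()
  calls <- dplyr::bind_rows(
    tr$variants[1:9, ],
    tibble::tibble(chrom = "chr1", pos = c(50L, 60L), ref = "C", alt = "G")
  )
  res <- classify_calls(calls, tr)
  expect_equal(res$sensitivity, 0.9)
  expect_equal(res$specificity, 88 / 90)
})

test_that("out-of-panel and duplicate calls are handled with warnings", {
  tr <- toy_truth()
  calls <- dplyr::bind_rows(
    tr$variants[1, ],
    tibble::tibble(chrom = "chr1", pos = 999L, ref = "A", alt = "T"),
    tr$variants[1, ]
  )
  expect_warning(expect_warning(res <- classify_calls(calls, tr),
                                "outside the assayed panel"),
                 "duplicate")
  expect_equal(res$tp, 1)
  expect_equal(res$fp, 0)
})

test_that("confusion identities hold under fuzzing", {
  set.seed(77)
  for (i in 1:30) {
    n_panel <- sample(20:200, 1)
    n_true <- sample(0:10, 1)
    tr <- list(
      panel = tibble::tibble(chrom = "chr1", pos = seq_len(n_panel)),
      variants = tibble::tibble(chrom = "chr1",
                                pos = sample(n_panel, n_true),
                                ref = "A", alt = "T")
    )
    n_calls <- sample(0:20, 1)
    calls <- tibble::tibble(chrom = "chr1",
                            pos = sample(n_panel, min(n_calls, n_panel)),
                            ref = "A",
                            alt = sample(c("T", "G"), min(n_calls, n_panel),
                                         replace = TRUE))
    res <- classify_calls(calls, tr)
    expect_equal(res$tp + res$fn, n_true)
    expect_equal(res$fp + res$tn, n_panel - n_true)
    expect_true(res$sensitivity >= 0 || is.na(res$sensitivity))
    expect_true(res$specificity <= 1)
  }
})

test_that("the t-based confidence interval matches its closed form", {
  res <- tibble::tibble(sample_id = c("a", "b"), fixative = "SF",
                        sensitivity = c(0.8, 1.0), specificity = c(1, 1))
  s <- summarize_by_fixative(res)
  sens <- s[s$metric == "sensitivity", ]
  half <- qt(0.975, 1) * sd(c(0.8, 1.0)) / sqrt(2)
  expect_equal(sens$mean, 0.9)
  expect_equal(sens$ci_hi - sens$mean, half)
  # cross-check against an independent implementation
  ref_ci <- t.test(c(0.8, 1.0))$conf.int
  expect_equal(c(sens$ci_lo, sens$ci_hi), as.vector(ref_ci))
  # identical values collapse the interval
  spec <- s[s$metric == "specificity", ]
  expect_equal(spec$ci_lo, spec$ci_hi)
  expect_equal(spec$ci_lo, 1)
})

test_that("single-sample groups report a point estimate without a CI", {
  res <- tibble::tibble(sample_id = "a", fixative = "NBF",
                        sensitivity = 0.7, specificity = 0.9)
  s <- summarize_by_fixative(res)
  expect_false(any(s$ci_available))
  expect_true(all(is.na(s$ci_lo)))
})

test_that("planted per-fixative error rates order mean sensitivity", {
  ref <- generate_reference(20000, seed = 2)
  means <- replicate(20, {
    cfg <- sim_config(n_patients = 6, sample_types = "surgical",
                      reference_length = 20000,
                      seed = sample.int(1e6, 1))
    snv <- simulate_variant_calls(cfg, ref)
    ev <- evaluate_cohort_calls(snv$calls, snv$panel, snv$truth)
    tapply(ev$sensitivity, ev$fixative, mean)
  })
  med <- apply(means, 1, median)
  expect_lt(med[["NBF"]], med[["UMFIX"]])
  expect_lt(med[["NBF"]], med[["SF"]])
})
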