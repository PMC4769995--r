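bin_tbl <- function(counts, chrom = "chr1") {
  n <- length(counts)
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * 10,
                 end = seq_len(n) * 10, count = counts)
}

test_that("median normalization gives the documented log-ratios", {
  p <- normalize_counts(bin_tbl(c(100, 100, 200, 100, 100)))
  expect_equal(p$logratio, c(0, 0, 1, 0, 0))
  # scale invariance
  p10 <- normalize_counts(bin_tbl(10 * c(100, 100, 200, 100, 100)))
  expect_equal(p10$logratio, p$logratio)
  # all equal -> all zero
  expect_equal(normalize_counts(bin_tbl(rep(7, 5)))$logratio, rep(0, 5))
})

test_that("zero bins are masked and the median recomputed", {
  p <- normalize_counts(bin_tbl(c(0, 100, 100, 400, 100)))
  expect_true(p$masked[1])
  expect_true(is.na(p$logratio[1]))
  expect_equal(p$logratio[-1], c(0, 0, 2, 0))
  expect_error(normalize_counts(bin_tbl(c(0, 0))), "zero")
})

test_that("a noiseless step splits exactly at the boundary", {
  p <- normalize_counts(bin_tbl(c(100, 100, 100, 200, 200, 200)))
  seg <- segment_profile(p, min_bins = 1, n_perm = 100, seed = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$end_bin[1], 3)
  expect_equal(seg$variance, c(0, 0))
})

test_that("a constant profile stays one segment per chromosome", {
  two <- dplyr::bind_rows(bin_tbl(rep(100, 12), "chr1"),
                          bin_tbl(rep(100, 12), "chr2"))
  seg <- segment_profile(normalize_counts(two), n_perm = 100, seed = 1)
  expect_equal(nrow(seg), 2)
  expect_setequal(seg$chrom, c("chr1", "chr2"))
})

test_that("segment means conserve the overall bin mean", {
  set.seed(4)
  p <- normalize_counts(bin_tbl(rpois(80, 200)))
  seg <- segment_profile(p, n_perm = 200, seed = 2)
  overall <- mean(p$logratio)
  weighted <- sum(seg$mean * seg$n_bins) / sum(seg$n_bins)
  expect_equal(weighted, overall, tolerance = 1e-9)
})

test_that("segmentation is deterministic given the seed", {
  set.seed(11)
  p <- normalize_counts(bin_tbl(rpois(60, c(rep(100, 30), rep(220, 30)))))
  s1 <- segment_profile(p, n_perm = 200, seed = 5)
  s2 <- segment_profile(p, n_perm = 200, seed = 5)
  expect_identical(s1, s2)
})

test_that("short segments are merged into the nearer neighbour", {
  x <- c(rep(0, 10), 3, rep(2.8, 10))
  segs <- tibble::tibble(chrom = "chr1", start_bin = c(1L, 11L, 12L),
                         end_bin = c(10L, 11L, 21L))
  merged <- fixsig:::.merge_short_segments(segs, x, min_bins = 3)
  expect_equal(nrow(merged), 2)
  expect_equal(merged$start_bin[2], 11)
})

test_that("true breakpoints are recovered within 2 bins under moderate noise", {
  hits <- replicate(20, {
    r <- sample.int(1e6, 1)
    truth_bounds <- c(25, 50, 75)
    states <- c(1, 2, 4, 2)
    x <- rep(log2(states / 2), times = c(25, 25, 25, 25)) + rnorm(100, 0, 0.1)
    p <- bin_tbl(round(500 * 2^x))
    seg <- segment_profile(normalize_counts(p), n_perm = 200, seed = r)
    found <- utils::head(seg$end_bin, -1)
    length(found) == 3 && all(abs(sort(found) - truth_bounds) <= 2)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("spearman correlation behaves as a rank statistic", {
  a <- normalize_counts(bin_tbl(c(100, 120, 140, 160, 180)))
  expect_equal(profile_correlation(a, a), 1)
  b <- normalize_counts(bin_tbl(rev(c(100, 120, 140, 160, 180))))
  expect_equal(profile_correlation(a, b), -1)
  # worked 5-bin example: rho = 1 - 6*4/(5*24) = 0.8
  c2 <- normalize_counts(bin_tbl(c(120, 100, 160, 140, 180)))
  expect_equal(profile_correlation(a, c2), 0.8)
  # invariance under strictly monotone transforms
  mono <- normalize_counts(bin_tbl(as.integer(c(100, 120, 140, 160, 180)^1.7)))
  expect_equal(profile_correlation(mono, c2), 0.8)
})

test_that("correlation requires a shared grid and enough joint bins", {
  a <- normalize_counts(bin_tbl(c(100, 120, 140, 160, 180)))
  short <- normalize_counts(bin_tbl(c(100, 120, 140)))
  expect_error(profile_correlation(a, short), "bin grid")
  sparse <- normalize_counts(bin_tbl(c(0, 0, 0, 160, 180)))
  expect_error(profile_correlation(a, sparse), "fewer than 3")
})

test_that("concordance counts UMFIX-superior pairs and ties", {
  cfg <- sim_config(n_patients = 5, sample_types = "surgical",
                    cn_n_bins = 120, seed = 21)
  cn <- simulate_cn_counts(cfg)
  conc <- concordance_summary(cn$counts)
  expect_equal(conc$summary$n_pairs, 5)
  expect_equal(conc$summary$umfix_superior + conc$summary$ties +
                 sum(conc$summary$n_pairs - conc$summary$umfix_superior -
                       conc$summary$ties), 5)
  expect_equal(nrow(conc$per_sample), 10)  # UMFIX + NBF rho per patient
  # noiseless: all rhos 1, ties = all
  cfg0 <- sim_config(n_patients = 3, sample_types = "surgical",
                     cn_noise_sd = c(SF = 0, UMFIX = 0, NBF = 0), seed = 2)
  conc0 <- concordance_summary(simulate_cn_counts(cfg0)$counts)
  expect_equal(conc0$summary$ties, 3)
  expect_equal(conc0$summary$umfix_superior, 0)
})

test_that("segment variance summary orders fixatives by planted noise", {
  cfg <- sim_config(n_patients = 6, sample_types = "surgical",
                    cn_n_bins = 120, seed = 31)
  sv <- segment_variance_summary(simulate_cn_counts(cfg)$counts,
                                 n_perm = 150, seed = 4)
  med <- setNames(sv$medians$median_variance, sv$medians$fixative)
  expect_lt(med[["SF"]], med[["UMFIX"]])
  expect_lt(med[["UMFIX"]], med[["NBF"]])
  expect_equal(nrow(sv$tests), 3)
})
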