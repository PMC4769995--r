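test_that("delta-Cq is plain subtraction with strict missing handling", {
  expect_equal(delta_cq(27, 25), 2)
  expect_equal(delta_cq(25, 25), 0)
  expect_equal(-delta_cq(27, 25), -2)  # display convention negates
  expect_error(delta_cq(NA, 25), "missing")
})

test_that("Q-ratios follow the efficiency-corrected closed form", {
  expect_equal(q_ratio(25, 25), 1)
  expect_equal(q_ratio(25, 26), 0.5)
  expect_equal(q_ratio(25, 26, efficiency = 0.9), 1.9^-1)
  expect_error(q_ratio(25, NA), "missing")
  expect_error(q_ratio(25, 26, efficiency = 1.2), "efficiency")
  # monotone decreasing in the long-fragment Cq
  expect_true(q_ratio(25, 27) < q_ratio(25, 26))
})

test_that("small-sample p-values are exact and match the textbook example", {
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 20)
  # statistic is the rank sum of x
  expect_equal(r$statistic, 6)
})

test_that("identical groups give a p-value of ~1 at the null mean", {
  x <- c(1, 2, 3, 4)
  r <- wilcoxon_rank_sum(x, x)
  expect_equal(r$p_value, 1)
  expect_equal(r$statistic, length(x) * (2 * length(x) + 1) / 2)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("two-sided p-values are symmetric in the two groups", {
  set.seed(3)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1))
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcoxon_rank_sum(y, x)$p_value, tolerance = 1e-12)
  }
})

test_that("the exact branch agrees with stats::wilcox.test off by no ties", {
  set.seed(9)
  for (i in 1:30) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    v <- sample(1000, nx + ny)  # tie-free pooled draw
    x <- v[seq_len(nx)]; y <- v[nx + seq_len(ny)]
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("the approximation agrees with enumeration just past the exact branch", {
  # 12 observations run the exact branch; 13 switch to the approximation.
  # Exhaustively over every tie-free configuration at n = 13, the
  # continuity-corrected approximation stays within 0.015 of the enumerated
  # p (worst case 0.0135), and within 0.01 for the median configuration.
  devs <- c()
  for (nx in c(6, 7)) {
    ny <- 13 - nx
    subs <- utils::combn(13, nx)
    all_w <- colSums(subs)
    for (j in seq_len(ncol(subs))) {
      x <- subs[, j]
      y <- setdiff(1:13, x)
      r <- wilcoxon_rank_sum(x, y)
      expect_equal(r$method, "normal")
      W <- r$statistic
      p_exact <- min(1, 2 * min(mean(all_w <= W), mean(all_w >= W)))
      devs <- c(devs, abs(r$p_value - p_exact))
    }
  }
  expect_lt(max(devs), 0.015)
  expect_lt(median(devs), 0.01)
})

test_that("the qc report computes metrics, medians and starred tests", {
  cfg <- sim_config(seed = 5)
  rep <- qc_report(simulate_qpcr(cfg), cfg$qpcr_control_cq)
  expect_setequal(unique(rep$metrics$metric),
                  c("delta_cq_90", "q_ratio_129_41", "q_ratio_305_41"))
  t305 <- rep$tests[rep$tests$metric == "q_ratio_305_41" &
                      rep$tests$group_a %in% c("UMFIX", "NBF") &
                      rep$tests$group_b %in% c("UMFIX", "NBF"), ]
  expect_lt(t305$p_value, 0.05)
  expect_true(nchar(t305$stars) >= 1)
})

test_that("identical group distributions earn no stars", {
  qp <- tibble::tibble(
    sample_id = rep(paste0("s", 1:6), each = 4),
    fixative = rep(c("SF", "UMFIX", "NBF"), each = 8),
    amplicon_bp = rep(c(41, 90, 129, 305), 6),
    cq = rep(c(25, 25.5, 26, 27), 6)
  )
  rep <- qc_report(qp, c(`41` = 25, `90` = 25, `129` = 25, `305` = 25))
  expect_true(all(rep$tests$stars == ""))
  expect_true(all(rep$tests$p_value > 0.9))
})

test_that("empty and incomplete qPCR tables degrade gracefully", {
  rep <- qc_report(tibble::tibble(sample_id = character(0),
                                  fixative = character(0),
                                  amplicon_bp = numeric(0),
                                  cq = numeric(0)),
                   c(`90` = 25))
  expect_equal(nrow(rep$metrics), 0)
  qp <- tibble::tibble(sample_id = c("a", "a", "b"),
                       fixative = c("SF", "SF", "NBF"),
                       amplicon_bp = c(41, 305, 305),
                       cq = c(25, 26, 30))
  expect_warning(rep2 <- qc_report(qp, c(`41` = 25, `90` = 25, `129` = 25,
                                         `305` = 25)),
                 "missing Cq")
  expect_equal(nrow(rep2$metrics[rep2$metrics$metric == "q_ratio_305_41", ]), 1)
})
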