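#' Median-normalize binned read counts into copy-number log-ratios
#'
#' `logratio = log2(count / median(count))`, with the median taken over
#' un-masked bins. Zero-count bins are masked (log-ratio undefined) and the
#' median is recomputed after masking.
#'
#' @param counts Tibble with columns `chrom`, `start`, `end`, `count`
#'   (one sample), in genomic order.
#' @return The tibble with `masked` (logical) and `logratio` (NA where
#'   masked) columns added.
#' @export
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = 0:4 * 10, end = 1:5 * 10,
#'                     count = c(100, 100, 200, 100, 100))
#' normalize_counts(x)$logratio
normalize_counts <- function(counts) {
  if (all(counts$count == 0)) {
    stop("all bins have zero count; cannot normalize", call. = FALSE)
  }
  out <- counts
  out$masked <- out$count == 0
  med <- stats::median(out$count[!out$masked])
  out$logratio <- ifelse(out$masked, NA_real_, log2(out$count / med))
  out
}

# max two-sample t statistic over all splits of x (no NA); returns
# list(stat, split) where split k means boundary between x[k] and x[k+1].
# Degenerate splits (zero pooled variance) give +Inf when the means differ.
.max_split_t <- function(x) {
  n <- length(x)
  if (n < 2L) return(list(stat = -Inf, split = NA_integer_))
  cs <- cumsum(x)
  css <- cumsum(x^2)
  k <- seq_len(n - 1L)
  n1 <- k
  n2 <- n - k
  m1 <- cs[k] / n1
  m2 <- (cs[n] - cs[k]) / n2
  ss1 <- css[k] - n1 * m1^2
  ss2 <- (css[n] - css[k]) - n2 * m2^2
  sp2 <- pmax((ss1 + ss2) / pmax(n - 2L, 1L), 0)
  se2 <- sp2 * (1 / n1 + 1 / n2)
  diff <- abs(m1 - m2)
  # degeneracy tolerance relative to the data's mean-square scale, so that
  # cancellation error in the cumulative sums cannot disguise a perfect
  # (zero-residual) split as a merely large finite statistic
  tol <- 1e-10 * max(css[n] / n, 1e-300)
  t <- ifelse(se2 > tol, diff / sqrt(se2), ifelse(diff > sqrt(tol), Inf, 0))
  t[is.na(t)] <- -Inf
  best <- which.max(t)
  list(stat = t[best], split = best)
}

.segment_recursive <- function(x, offset, alpha, n_perm, min_seg) {
  n <- length(x)
  if (n < 2L * min_seg) return(integer(0))
  cand <- .max_split_t(x)
  if (!is.finite(cand$stat)) {
    if (is.infinite(cand$stat) && cand$stat > 0) {
      # perfect split: both sides constant, means differ; no permutation
      # test can certify it at small n, accept outright
      accept <- TRUE
    } else {
      return(integer(0))
    }
  } else if (cand$stat <= 0) {
    return(integer(0))
  } else {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      perm <- .max_split_t(x[sample.int(n)])
      if (perm$stat >= cand$stat) exceed <- exceed + 1L
    }
    p <- (1 + exceed) / (1 + n_perm)
    accept <- p < alpha
  }
  if (!accept) return(integer(0))
  k <- cand$split
  c(.segment_recursive(x[seq_len(k)], offset, alpha, n_perm, min_seg),
    offset + k,
    .segment_recursive(x[(k + 1L):n], offset + k, alpha, n_perm, min_seg))
}

#' Segment a copy-number profile by recursive binary splitting
#'
#' Per chromosome, recursively finds the split maximizing the two-sample
#' t-statistic on bin log-ratios and accepts it when its permutation
#' p-value is below `alpha` (a noiseless split — zero variance on both
#' sides with distinct means — is accepted outright, since no permutation
#' test on a handful of bins can reach any useful level). Accepted segments
#' shorter than `min_bins` are merged into the neighbouring segment with
#' the closer mean. Masked bins are excluded; segment statistics are the
#' mean and unbiased variance of the member bins' log-ratios.
#'
#' @param profile Output of [normalize_counts()] (columns chrom, bin order,
#'   logratio, masked).
#' @param alpha Permutation significance level for accepting a split.
#' @param n_perm Number of permutations per candidate split.
#' @param min_bins Minimum segment length in bins.
#' @param seed Integer seed for the permutation test.
#' @return Tibble of class `fixsig_segments`: chrom, start_bin, end_bin
#'   (indices into the un-masked bins of that chromosome), n_bins, mean,
#'   variance.
#' @export
segment_profile <- function(profile, alpha = 0.01, n_perm = 1000,
                            min_bins = 3, seed = 1L) {
  usable <- profile[!profile$masked & !is.na(profile$logratio), ]
  if (nrow(usable) == 0L) stop("no usable bins to segment", call. = FALSE)
  res <- withr::with_seed(seed, {
    dplyr::bind_rows(lapply(split(usable, usable$chrom), function(df) {
      x <- df$logratio
      n <- length(x)
      flagged <- n < min_bins
      breaks <- if (flagged) integer(0) else
        .segment_recursive(x, 0L, alpha, n_perm, min_seg = 1L)
      bounds <- c(0L, breaks, n)
      segs <- tibble::tibble(
        chrom = df$chrom[1],
        start_bin = utils::head(bounds, -1) + 1L,
        end_bin = utils::tail(bounds, -1)
      )
      segs <- .merge_short_segments(segs, x, min_bins)
      segs$n_bins <- segs$end_bin - segs$start_bin + 1L
      segs$mean <- vapply(seq_len(nrow(segs)), function(i)
        mean(x[segs$start_bin[i]:segs$end_bin[i]]), 0)
      segs$variance <- vapply(seq_len(nrow(segs)), function(i) {
        xs <- x[segs$start_bin[i]:segs$end_bin[i]]
        if (length(xs) > 1) stats::var(xs) else 0
      }, 0)
      segs$flagged <- flagged
      segs
    }))
  })
  structure(tibble::as_tibble(res), class = c("fixsig_segments", class(res)))
}

# merge segments shorter than min_bins into the neighbour whose mean is
# closer; repeat until none remain (or only one segment is left)
.merge_short_segments <- function(segs, x, min_bins) {
  repeat {
    len <- segs$end_bin - segs$start_bin + 1L
    if (nrow(segs) <= 1L || all(len >= min_bins)) return(segs)
    i <- which(len < min_bins)[1]
    m <- function(j) mean(x[segs$start_bin[j]:segs$end_bin[j]])
    left_ok <- i > 1L
    right_ok <- i < nrow(segs)
    into <- if (left_ok && right_ok) {
      if (abs(m(i) - m(i - 1L)) <= abs(m(i) - m(i + 1L))) i - 1L else i + 1L
    } else if (left_ok) i - 1L else i + 1L
    lo <- min(i, into); hi <- max(i, into)
    segs$end_bin[lo] <- segs$end_bin[hi]
    segs <- segs[-hi, , drop = FALSE]
  }
}

#' Spearman correlation between two copy-number profiles
#'
#' Rank correlation (average-rank ties) of bin log-ratios over the bins
#' that are un-masked in both profiles; requires a shared bin grid.
#'
#' @param profile_a,profile_b Outputs of [normalize_counts()] on the same
#'   bin grid.
#' @return Spearman's rho (single number).
#' @export
profile_correlation <- function(profile_a, profile_b) {
  if (nrow(profile_a) != nrow(profile_b) ||
      !all(profile_a$start == profile_b$start & profile_a$chrom == profile_b$chrom)) {
    stop("profiles must share the same bin grid", call. = FALSE)
  }
  ok <- !profile_a$masked & !profile_b$masked
  if (sum(ok) < 3L) {
    stop("fewer than 3 jointly un-masked bins", call. = FALSE)
  }
  stats::cor(profile_a$logratio[ok], profile_b$logratio[ok],
             method = "spearman")
}

#' Per-patient fixative concordance against the snap-frozen gold standard
#'
#' For every patient and sample type with a complete matched triplet,
#' computes Spearman's rho of each fixed sample's profile against the
#' matched gold-standard (default SF) profile, and counts how often the
#' UMFIX sample correlates better than the NBF one. Ties count as
#' non-superior and are reported separately.
#'
#' @param counts Tidy bin-count tibble for the cohort (columns sample_id,
#'   patient_id, fixative, sample_type, chrom, start, end, count).
#' @param gold Fixative treated as gold standard.
#' @return List with `per_sample` (patient, sample_type, fixative, rho) and
#'   `summary` (per sample type: n pairs, UMFIX-superior count, ties).
#' @export
concordance_summary <- function(counts, gold = "SF") {
  profiles <- lapply(split(counts, counts$sample_id), normalize_counts)
  meta <- dplyr::distinct(counts[, c("sample_id", "patient_id", "fixative",
                                     "sample_type")])
  others <- setdiff(unique(meta$fixative), gold)
  rows <- list()
  for (pt in unique(meta$patient_id)) {
    for (st in unique(meta$sample_type)) {
      sub <- meta[meta$patient_id == pt & meta$sample_type == st, ]
      gold_id <- sub$sample_id[sub$fixative == gold]
      if (length(gold_id) != 1L) next
      for (fx in others) {
        fid <- sub$sample_id[sub$fixative == fx]
        if (length(fid) != 1L) {
          warning("no matched ", fx, " sample for ", pt, "/", st,
                  "; pair dropped", call. = FALSE)
          next
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pt, sample_type = st, fixative = fx,
          rho = profile_correlation(profiles[[fid]], profiles[[gold_id]])
        )
      }
    }
  }
  per_sample <- dplyr::bind_rows(rows)
  wide <- tidyr::pivot_wider(per_sample, names_from = "fixative",
                             values_from = "rho")
  summary <- NULL
  if (all(c("UMFIX", "NBF") %in% names(wide))) {
    summary <- dplyr::summarise(
      dplyr::group_by(wide, .data$sample_type),
      n_pairs = sum(!is.na(.data$UMFIX) & !is.na(.data$NBF)),
      umfix_superior = sum(.data$UMFIX > .data$NBF, na.rm = TRUE),
      ties = sum(.data$UMFIX == .data$NBF, na.rm = TRUE),
      .groups = "drop"
    )
  }
  list(per_sample = per_sample, summary = summary)
}

#' Per-fixative distributions of per-segment variances
#'
#' Normalizes and segments every sample, pools the per-segment variances by
#' fixative, and compares fixatives pairwise with the package's Wilcoxon
#' rank-sum test.
#'
#' @param counts Tidy bin-count tibble for the cohort.
#' @param alpha,n_perm,min_bins,seed Passed to [segment_profile()].
#' @return List with `variances` (fixative, sample_id, chrom, variance per
#'   segment), `medians` (per fixative) and `tests` (pairwise two-sided
#'   Wilcoxon p-values).
#' @export
segment_variance_summary <- function(counts, alpha = 0.01, n_perm = 1000,
                                     min_bins = 3, seed = 1L) {
  meta <- dplyr::distinct(counts[, c("sample_id", "fixative")])
  segs <- dplyr::bind_rows(lapply(seq_len(nrow(meta)), function(i) {
    prof <- normalize_counts(counts[counts$sample_id == meta$sample_id[i], ])
    out <- segment_profile(prof, alpha = alpha, n_perm = n_perm,
                           min_bins = min_bins, seed = seed + i)
    dplyr::bind_cols(meta[rep(i, nrow(out)), ], out)
  }))
  medians <- dplyr::summarise(dplyr::group_by(segs, .data$fixative),
                              median_variance = stats::median(.data$variance),
                              n_segments = dplyr::n(), .groups = "drop")
  fx <- unique(meta$fixative)
  pairs <- utils::combn(fx, 2, simplify = FALSE)
  tests <- dplyr::bind_rows(lapply(pairs, function(pr) {
    w <- wilcoxon_rank_sum(segs$variance[segs$fixative == pr[1]],
                           segs$variance[segs$fixative == pr[2]])
    tibble::tibble(group_a = pr[1], group_b = pr[2],
                   statistic = w$statistic, p_value = w$p_value)
  }))
  list(variances = segs, medians = medians, tests = tests)
}
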