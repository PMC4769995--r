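#' Amplifiable-DNA yield as a Cq difference
#'
#' `delta_cq = sample_cq - control_cq`: the number of extra qPCR cycles a
#' sample needs relative to the kit's control template for the same
#' amplicon. Larger values mean less amplifiable DNA. Reports conventionally
#' display the negated value; storage is un-negated.
#'
#' @param sample_cq,control_cq Quantification cycles (vectorised).
#' @return Numeric vector of Cq differences.
#' @export
#' @examples
#' delta_cq(27, 25) # 2: four-fold less amplifiable template
delta_cq <- function(sample_cq, control_cq) {
  if (any(is.na(sample_cq)) || any(is.na(control_cq))) {
    stop("missing Cq value", call. = FALSE)
  }
  sample_cq - control_cq
}

#' DNA integrity Q-ratio from a long and a short amplicon
#'
#' `Q = (1 + efficiency)^(cq_short - cq_long)`; with perfect amplification
#' efficiency (1 per cycle) this is `2^(cq_41 - cq_long)`. Q near 1 means
#' long fragments amplify as well as short ones (intact DNA); Q well below
#' 1 indicates fragmentation.
#'
#' @param cq_short Cq of the short (41 bp) amplicon.
#' @param cq_long Cq of the long (129 or 305 bp) amplicon.
#' @param efficiency Amplification efficiency per cycle, in (0, 1].
#' @return Numeric vector of ratios in (0, Inf).
#' @export
#' @examples
#' q_ratio(25, 26) # 0.5: long fragments one cycle behind
q_ratio <- function(cq_short, cq_long, efficiency = 1) {
  if (any(is.na(cq_short)) || any(is.na(cq_long))) {
    stop("missing Cq value", call. = FALSE)
  }
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    stop("`efficiency` must be in (0, 1]", call. = FALSE)
  }
  (1 + efficiency)^(cq_short - cq_long)
}

# null distribution of the rank-sum of `nx` ranks drawn from 1..n, as
# cumulative counts via the classic shift algorithm (tie-free case)
.ranksum_null_counts <- function(nx, n) {
  max_w <- sum((n - nx + 1L):n)
  counts <- matrix(0, nrow = nx + 1L, ncol = max_w + 1L)  # [k+1, w+1]
  counts[1, 1] <- 1
  for (j in seq_len(n)) {
    for (k in rev(seq_len(min(nx, j)))) {
      w <- which(counts[k, ] > 0)
      if (length(w)) {
        tgt <- w + j
        keep <- tgt <= max_w + 1L
        counts[k + 1L, tgt[keep]] <- counts[k + 1L, tgt[keep]] + counts[k, w[keep]]
      }
    }
  }
  counts[nx + 1L, ]
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Statistic is the sum of the ranks of `x` in the pooled sample
#' (average-rank ties). The p-value is exact — computed from the full null
#' distribution of the rank-sum — when `length(x) + length(y) <= 12` and
#' there are no ties; otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (alternatives refer to the location of `x` relative to `y`).
#' @return List with `statistic` (rank-sum of x), `p_value`, `method`
#'   (`"exact"` or `"normal"`).
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p_value
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(nx)])
  ties <- any(duplicated(pooled))
  if (!ties && n <= 12L) {
    counts <- .ranksum_null_counts(nx, n)
    total <- sum(counts)
    w_vals <- seq_along(counts) - 1L
    p_le <- sum(counts[w_vals <= W]) / total
    p_ge <- sum(counts[w_vals >= W]) / total
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge
    )
    return(list(statistic = W, p_value = p, method = "exact"))
  }
  mu <- nx * (n + 1) / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab)
  sigma2 <- nx * ny * (n + 1) / 12 - nx * ny * tie_term / (12 * n * (n - 1))
  sigma <- sqrt(sigma2)
  if (sigma == 0) {
    # all observations identical: statistic sits at its null mean
    p <- if (alternative == "two.sided") 1 else 1
    return(list(statistic = W, p_value = p, method = "normal"))
  }
  z_cc <- function(shift) (W - mu + shift) / sigma
  p <- switch(alternative,
    two.sided = min(1, 2 * min(stats::pnorm(z_cc(0.5)),
                               stats::pnorm(z_cc(-0.5), lower.tail = FALSE))),
    less = stats::pnorm(z_cc(0.5)),
    greater = stats::pnorm(z_cc(-0.5), lower.tail = FALSE)
  )
  list(statistic = W, p_value = p, method = "normal")
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.0005 ~ "***",
    p < 0.005 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' qPCR quality-control report
#'
#' Per-sample delta-Cq for the 90 bp amplicon and Q-ratios for 129/41 and
#' 305/41 bp, summarized per fixative, with pairwise two-sided Wilcoxon
#' rank-sum tests and significance stars at 0.05 / 0.005 / 0.0005. Samples
#' missing an amplicon are excluded from the affected metric with a
#' warning.
#'
#' @param qpcr Tidy Cq tibble (sample_id, fixative, amplicon_bp, cq).
#' @param control_cq Named vector of control-template Cq per amplicon
#'   (names "41", "90", "129", "305").
#' @param efficiency Amplification efficiency passed to [q_ratio()].
#' @return List with `metrics` (per-sample metric values), `summary`
#'   (per-fixative medians) and `tests` (pairwise Wilcoxon results per
#'   metric with stars).
#' @export
qc_report <- function(qpcr, control_cq, efficiency = 1) {
  if (nrow(qpcr) == 0L) {
    return(list(metrics = tibble::tibble(), summary = tibble::tibble(),
                tests = tibble::tibble()))
  }
  wide <- tidyr::pivot_wider(
    qpcr[, c("sample_id", "fixative", "amplicon_bp", "cq")],
    names_from = "amplicon_bp", values_from = "cq", names_prefix = "cq_"
  )
  metric_one <- function(value, name) {
    tibble::tibble(sample_id = wide$sample_id, fixative = wide$fixative,
                   metric = name, value = value)
  }
  need <- function(cols, name) {
    ok <- rowSums(is.na(wide[, cols, drop = FALSE])) == 0
    if (any(!ok)) {
      warning(sum(!ok), " sample(s) missing Cq for ", name, "; excluded",
              call. = FALSE)
    }
    ok
  }
  metrics <- list()
  if ("cq_90" %in% names(wide)) {
    ok <- need("cq_90", "delta_cq_90")
    m <- metric_one(NA_real_, "delta_cq_90")
    m$value[ok] <- delta_cq(wide$cq_90[ok], control_cq[["90"]])
    metrics <- c(metrics, list(m[ok, ]))
  }
  for (long in c("129", "305")) {
    cols <- c("cq_41", paste0("cq_", long))
    if (all(cols %in% names(wide))) {
      nm <- paste0("q_ratio_", long, "_41")
      ok <- need(cols, nm)
      m <- metric_one(NA_real_, nm)
      m$value[ok] <- q_ratio(wide$cq_41[ok], wide[[paste0("cq_", long)]][ok],
                             efficiency)
      metrics <- c(metrics, list(m[ok, ]))
    }
  }
  metrics <- dplyr::bind_rows(metrics)
  summary <- dplyr::summarise(
    dplyr::group_by(metrics, .data$metric, .data$fixative),
    n = dplyr::n(), median = stats::median(.data$value),
    .groups = "drop"
  )
  fx <- unique(metrics$fixative)
  tests <- tibble::tibble()
  if (length(fx) >= 2) {
    pairs <- utils::combn(fx, 2, simplify = FALSE)
    tests <- dplyr::bind_rows(lapply(unique(metrics$metric), function(mt) {
      dplyr::bind_rows(lapply(pairs, function(pr) {
        xa <- metrics$value[metrics$metric == mt & metrics$fixative == pr[1]]
        xb <- metrics$value[metrics$metric == mt & metrics$fixative == pr[2]]
        if (length(xa) == 0 || length(xb) == 0) return(NULL)
        w <- wilcoxon_rank_sum(xa, xb)
        tibble::tibble(metric = mt, group_a = pr[1], group_b = pr[2],
                       statistic = w$statistic, p_value = w$p_value,
                       stars = significance_stars(w$p_value))
      }))
    }))
  }
  list(metrics = metrics, summary = summary, tests = tests)
}
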