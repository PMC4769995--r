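#' Classify SNV calls against a curated truth set
#'
#' Confusion counts over a finite assayed panel: a call matching a true
#' variant (position and alleles) is a true positive; a call at an assayed
#' position with no matching truth is a false positive; a true variant with
#' no matching call is a false negative; assayed positions with neither are
#' true negatives. Calls outside the panel are dropped with a warning, as
#' are duplicate calls at one position (first kept).
#'
#' @param calls Tibble of calls (chrom, pos, ref, alt) for one sample.
#' @param truth List with `panel` (tibble chrom, pos of assayed positions)
#'   and `variants` (tibble chrom, pos, ref, alt of true variants, a subset
#'   of the panel).
#' @return One-row tibble: tp, fp, fn, tn, sensitivity, specificity.
#' @export
#' @examples
#' truth <- list(panel = tibble::tibble(chrom = "chr1", pos = 1:100),
#'               variants = tibble::tibble(chrom = "chr1", pos = 1:10,
#'                                         ref = "A", alt = "T"))
#' calls <- truth$variants[1:9, ]
#' classify_calls(calls, truth)
classify_calls <- function(calls, truth) {
  panel_key <- paste(truth$panel$chrom, truth$panel$pos)
  truth_key <- change_key(truth$variants)
  if (!all(paste(truth$variants$chrom, truth$variants$pos) %in% panel_key)) {
    stop("true variants must lie within the assayed panel", call. = FALSE)
  }
  in_panel <- paste(calls$chrom, calls$pos) %in% panel_key
  if (any(!in_panel)) {
    warning(sum(!in_panel), " call(s) outside the assayed panel dropped",
            call. = FALSE)
    calls <- calls[in_panel, , drop = FALSE]
  }
  dup <- duplicated(paste(calls$chrom, calls$pos))
  if (any(dup)) {
    warning(sum(dup), " duplicate call(s) at one position; keeping first",
            call. = FALSE)
    calls <- calls[!dup, , drop = FALSE]
  }
  call_key <- change_key(calls)
  truth_pos <- paste(truth$variants$chrom, truth$variants$pos)
  tp <- sum(call_key %in% truth_key)
  fp <- nrow(calls) - tp
  fn <- nrow(truth$variants) - tp
  # specificity is per assayed position: its denominator is the panel minus
  # the truth positions, and every non-matching call is charged against it
  n_nonvariant <- length(panel_key) - length(unique(truth_pos))
  tn <- n_nonvariant - fp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (n_nonvariant > 0) tn / n_nonvariant else NA_real_
  )
}

#' Evaluate every sample of a cohort against its patient's truth set
#'
#' @param calls Tibble of calls with sample metadata (sample_id,
#'   patient_id, fixative, sample_type, chrom, pos, ref, alt).
#' @param panel Tibble of assayed positions (chrom, pos).
#' @param truth Tibble of per-patient true variants (patient_id, chrom,
#'   pos, ref, alt).
#' @return Tibble: one row per sample with confusion counts and rates.
#' @export
evaluate_cohort_calls <- function(calls, panel, truth) {
  meta <- dplyr::distinct(calls[, c("sample_id", "patient_id", "fixative",
                                    "sample_type")])
  dplyr::bind_rows(lapply(seq_len(nrow(meta)), function(i) {
    s <- meta[i, ]
    tr <- list(panel = panel,
               variants = truth[truth$patient_id == s$patient_id,
                                c("chrom", "pos", "ref", "alt")])
    dplyr::bind_cols(s, classify_calls(
      calls[calls$sample_id == s$sample_id,
            c("chrom", "pos", "ref", "alt")], tr))
  }))
}

#' Per-fixative mean sensitivity and specificity with t-based 95% CI
#'
#' Group means of the per-sample proportions with `mean +/- t[0.975, n-1] *
#' sd/sqrt(n)` confidence limits; single-sample groups report the point
#' estimate with the CI flagged unavailable; empty groups are omitted with
#' a warning.
#'
#' @param results Per-sample evaluation tibble from
#'   [evaluate_cohort_calls()].
#' @param conf_level Confidence level of the interval.
#' @return Tibble: fixative, metric (sensitivity/specificity), n, mean,
#'   ci_lo, ci_hi, ci_available.
#' @export
summarize_by_fixative <- function(results, conf_level = 0.95) {
  long <- tidyr::pivot_longer(
    results[, c("sample_id", "fixative", "sensitivity", "specificity")],
    cols = c("sensitivity", "specificity"),
    names_to = "metric", values_to = "value"
  )
  long <- long[!is.na(long$value), ]
  if (nrow(long) == 0L) {
    warning("no evaluable samples", call. = FALSE)
    return(tibble::tibble())
  }
  dplyr::summarise(
    dplyr::group_by(long, .data$fixative, .data$metric),
    n = dplyr::n(),
    mean = mean(.data$value),
    ci_lo = if (dplyr::n() >= 2)
      mean(.data$value) - stats::qt(1 - (1 - conf_level) / 2, dplyr::n() - 1) *
        stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
    ci_hi = if (dplyr::n() >= 2)
      mean(.data$value) + stats::qt(1 - (1 - conf_level) / 2, dplyr::n() - 1) *
        stats::sd(.data$value) / sqrt(dplyr::n()) else NA_real_,
    ci_available = dplyr::n() >= 2,
    .groups = "drop"
  )
}
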