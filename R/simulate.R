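.base_at <- function(reference, pos) {
  if (length(pos) == 0L) return(character(0))
  substring(reference, pos, pos)
}

channel_context <- function(channel) {
  paste0(substr(channel, 1, 1), substr(channel, 3, 3), substr(channel, 7, 7))
}

# sample distinct reference positions for the given channels, avoiding
# positions already flagged in the logical mask `used`; errors if a channel
# has no matching reference position
.place_changes <- function(channels, ctx_index, used) {
  pos <- integer(length(channels))
  if (length(channels) > 0L) {
    ctx <- channel_context(channels)
    for (i in seq_along(channels)) {
      cand <- ctx_index[[ctx[i]]]
      if (is.null(cand) || length(cand) == 0L) {
        stop("no reference position matches channel ", channels[i],
             call. = FALSE)
      }
      p <- cand[sample.int(length(cand), 1L)]
      tries <- 0L
      while (used[p]) {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("could not place change for channel ", channels[i],
               ": positions exhausted", call. = FALSE)
        }
        p <- cand[sample.int(length(cand), 1L)]
      }
      pos[i] <- p
      used[p] <- TRUE
    }
  }
  list(pos = pos, used = used)
}

# translate channel + reference position into emitted ref/alt on the
# reference strand (the channel is pyrimidine-collapsed; the reference base
# at the chosen position may be the purine partner)
.emit_alleles <- function(channels, pos, reference) {
  if (length(pos) == 0L) {
    return(tibble::tibble(ref = character(0), alt = character(0)))
  }
  ref_base <- substring(reference, pos, pos)
  ch_ref <- substr(channels, 3, 3)
  ch_alt <- substr(channels, 5, 5)
  purine <- ref_base %in% c("A", "G")
  ref <- ifelse(purine, unname(.COMPLEMENT[ch_ref]), ch_ref)
  alt <- ifelse(purine, unname(.COMPLEMENT[ch_alt]), ch_alt)
  stopifnot(all(ref == ref_base))
  tibble::tibble(ref = ref, alt = alt)
}

#' Simulate matched per-patient base-change tables with planted signatures
#'
#' For every patient, draws a Poisson number (`burden_common`) of shared
#' changes from the common (true-somatic-like) signature — present in every
#' sample of that patient — and, per sample, a Poisson number
#' (`burden_unique`) of fixative-specific noise changes from that fixative's
#' mixture of the remaining planted signatures; burdens are modulated by
#' mean-preserving log-normal per-patient and per-sample multipliers
#' (`burden_dispersion`), emulating the wide spread of mutation burden and
#' artefact load seen across real samples. Each change is placed at a
#' reference position whose pyrimidine-collapsed trinucleotide matches the
#' sampled channel (uniform over a precomputed per-context position index;
#' collisions within a patient are re-drawn, so labels are exact: a common
#' change occurs in all samples of its patient, a unique change in exactly
#' one).
#'
#' @param config A [sim_config()].
#' @param reference Reference sequence string satisfying trinucleotide
#'   coverage (see [generate_reference()]).
#' @return A list with `changes` (one row per observed change per sample:
#'   chrom, pos, ref, alt, sample/patient metadata, assay) and `truth` (one
#'   row per distinct change key with its ground-truth category label).
#' @export
simulate_base_changes <- function(config, reference) {
  ctx_index <- context_position_index(reference)
  sheet <- sample_sheet(config)
  channels <- sbs_channels()
  sig <- config$planted_signatures
  k_common <- config$common_signature_index
  noise_sig <- sig[, -k_common, drop = FALSE]
  p_common <- sig[, k_common]

  withr::with_seed(config$seed + 101L, {
    per_patient <- lapply(split(sheet, sheet$patient_id), function(samples) {
      patient <- samples$patient_id[1]
      used <- logical(nchar(reference))

      disp <- config$burden_dispersion
      mult_common <- exp(stats::rnorm(1, -disp^2 / 2, disp))
      n_common <- stats::rpois(1, config$burden_common * mult_common)
      ch_common <- channels[sample.int(96, n_common, replace = TRUE, prob = p_common)]
      placed <- .place_changes(ch_common, ctx_index, used)
      pos_common <- placed$pos
      used <- placed$used
      al <- .emit_alleles(ch_common, pos_common, reference)
      truth <- tibble::tibble(
        patient_id = patient, chrom = "chr1", pos = pos_common,
        ref = al$ref, alt = al$alt, channel = ch_common, label = "common"
      )
      rows <- dplyr::cross_join(
        samples,
        tibble::tibble(chrom = "chr1", pos = pos_common, ref = al$ref, alt = al$alt)
      )

      for (i in seq_len(nrow(samples))) {
        fx <- samples$fixative[i]
        w <- config$fixative_noise_weights[fx, ]
        p_noise <- as.vector(noise_sig %*% w)
        mult_uni <- exp(stats::rnorm(1, -disp^2 / 2, disp))
        n_uni <- stats::rpois(1, config$burden_unique * mult_uni)
        ch_uni <- channels[sample.int(96, n_uni, replace = TRUE, prob = p_noise)]
        placed <- .place_changes(ch_uni, ctx_index, used)
        pos_uni <- placed$pos
        used <- placed$used
        al_u <- .emit_alleles(ch_uni, pos_uni, reference)
        truth <- dplyr::bind_rows(truth, tibble::tibble(
          patient_id = patient, chrom = "chr1", pos = pos_uni,
          ref = al_u$ref, alt = al_u$alt, channel = ch_uni,
          label = paste0(fx, "-unique")
        ))
        rows <- dplyr::bind_rows(rows, dplyr::cross_join(
          samples[i, ],
          tibble::tibble(chrom = "chr1", pos = pos_uni, ref = al_u$ref, alt = al_u$alt)
        ))
      }
      list(rows = rows, truth = truth)
    })
  })

  changes <- dplyr::bind_rows(lapply(per_patient, `[[`, "rows"))
  changes$assay <- "sWGS"
  changes <- dplyr::arrange(
    changes[, c("chrom", "pos", "ref", "alt", "sample_id", "patient_id",
                "fixative", "sample_type", "assay")],
    .data$sample_id, .data$pos
  )
  truth <- dplyr::arrange(dplyr::bind_rows(lapply(per_patient, `[[`, "truth")),
                          .data$patient_id, .data$pos)
  list(changes = tibble::as_tibble(changes), truth = tibble::as_tibble(truth))
}

#' Build a germline-like blacklist from simulated changes
#'
#' Flags a configured fraction of the cohort's distinct change keys as
#' germline-like (these keys are meant to be removed by
#' [filter_blacklist()]), and adds an equal number of decoy keys at
#' positions where no change was generated, so the filter is exercised with
#' both hits and misses.
#'
#' @param truth Truth table from [simulate_base_changes()].
#' @param config A [sim_config()].
#' @param reference Reference sequence string.
#' @return A tibble (chrom, pos, ref, alt) of blacklisted keys.
#' @export
simulate_blacklist <- function(truth, config, reference) {
  withr::with_seed(config$seed + 211L, {
    n_flag <- round(config$blacklist_fraction * nrow(truth))
    flagged <- truth[sample.int(nrow(truth), n_flag), c("chrom", "pos", "ref", "alt")]
    n <- nchar(reference)
    decoy_pos <- integer(0)
    while (length(decoy_pos) < n_flag) {
      cand <- sample(2:(n - 1L), n_flag * 2L, replace = FALSE)
      cand <- setdiff(cand, c(truth$pos, decoy_pos))
      cand <- cand[.base_at(reference, cand) %in% .BASES]
      decoy_pos <- c(decoy_pos, utils::head(cand, n_flag - length(decoy_pos)))
    }
    ref_b <- .base_at(reference, decoy_pos)
    alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L), "")
    decoys <- tibble::tibble(chrom = "chr1", pos = decoy_pos,
                             ref = ref_b, alt = unname(alt_b))
  })
  dplyr::arrange(dplyr::bind_rows(flagged, decoys), .data$pos)
}

#' Simulate binned read counts with a shared per-patient copy-number truth
#'
#' Each patient gets one piecewise-constant copy-number profile (segment
#' boundaries drawn without replacement, states from `cn_states`, adjacent
#' segments forced to differ). Every sample of the patient observes counts
#' with expectation `read_depth_mean * state/2 * 2^eps`, where `eps` is
#' Gaussian log2-ratio noise with the fixative's standard deviation, and
#' Poisson counting noise on top. A fixative with noise sd exactly 0 emits
#' the deterministic expected counts — the exact noiseless limit used for
#' validation.
#'
#' @param config A [sim_config()].
#' @param bin_width Genomic width of a bin in bases (cosmetic; bins are
#'   contiguous on one chromosome).
#' @return A list with `counts` (sample x bin rows: chrom, start, end, bin,
#'   count + metadata) and `truth` (patient x bin rows: segment id, state,
#'   true log2 ratio).
#' @export
simulate_cn_counts <- function(config, bin_width = 50000L) {
  sheet <- sample_sheet(config)
  nb <- config$cn_n_bins
  bins <- tibble::tibble(
    chrom = "chr1",
    start = (seq_len(nb) - 1L) * bin_width,
    end = seq_len(nb) * bin_width,
    bin = seq_len(nb)
  )
  withr::with_seed(config$seed + 307L, {
    truth <- dplyr::bind_rows(lapply(unique(sheet$patient_id), function(patient) {
      ns <- config$cn_n_segments
      bounds <- if (ns > 1) sort(sample(2:nb, ns - 1L)) else integer(0)
      starts <- c(1L, bounds)
      ends <- c(bounds - 1L, nb)
      states <- numeric(ns)
      for (s in seq_len(ns)) {
        repeat {
          st <- sample(config$cn_states, 1L)
          if (s == 1L || st != states[s - 1L]) break
        }
        states[s] <- st
      }
      seg_of_bin <- rep(seq_len(ns), times = ends - starts + 1L)
      tibble::tibble(
        patient_id = patient, bin = seq_len(nb), segment = seg_of_bin,
        state = states[seg_of_bin], logratio_truth = log2(states[seg_of_bin] / 2)
      )
    }))
    counts <- dplyr::bind_rows(lapply(seq_len(nrow(sheet)), function(i) {
      s <- sheet[i, ]
      tr <- truth[truth$patient_id == s$patient_id, ]
      sd_fx <- config$cn_noise_sd[[s$fixative]]
      lambda <- config$read_depth_mean * (tr$state / 2)
      if (sd_fx > 0) {
        lambda <- lambda * 2^stats::rnorm(nb, 0, sd_fx)
        cnt <- stats::rpois(nb, lambda)
      } else {
        cnt <- lambda
      }
      dplyr::bind_cols(s[rep(1L, nb), ], bins, tibble::tibble(count = cnt))
    }))
  })
  list(counts = tibble::as_tibble(counts), truth = truth)
}

#' Simulate a qPCR Cq table with fixative-dependent fragment-length loss
#'
#' Cq values are the configured per-fixative, per-amplicon means plus
#' Gaussian measurement noise. Under the default preset SF amplifies long
#' fragments best (lowest Cq) and NBF worst, encoding formalin-induced
#' fragmentation.
#'
#' @param config A [sim_config()].
#' @return Tibble (sample_id, patient_id, fixative, sample_type,
#'   amplicon_bp, cq). The control-template Cq per amplicon lives in
#'   `config$qpcr_control_cq`.
#' @export
simulate_qpcr <- function(config) {
  sheet <- sample_sheet(config)
  amps <- c(41L, 90L, 129L, 305L)
  grid <- dplyr::cross_join(sheet, tibble::tibble(amplicon_bp = amps))
  mu <- config$qpcr_mean_cq[cbind(grid$fixative, as.character(grid$amplicon_bp))]
  withr::with_seed(config$seed + 401L, {
    grid$cq <- mu + stats::rnorm(nrow(grid), 0, config$qpcr_noise_sd)
  })
  tibble::as_tibble(grid)
}

#' Simulate an amplicon panel, per-patient SNV truth and per-sample calls
#'
#' A fixed panel of assayed positions is drawn once; each patient receives
#' true variants within it. Every sample detects each true variant of its
#' patient with the fixative's sensitivity and calls false positives at
#' assayed non-variant positions at the fixative's per-position rate.
#'
#' @param config A [sim_config()].
#' @param reference Reference sequence string.
#' @return List with `panel` (chrom, pos), `truth` (per-patient true
#'   variants) and `calls` (per-sample call sets with metadata).
#' @export
simulate_variant_calls <- function(config, reference) {
  sheet <- sample_sheet(config)
  n <- nchar(reference)
  withr::with_seed(config$seed + 503L, {
    panel_pos <- sort(sample(2:(n - 1L), config$snv_panel_size))
    panel <- tibble::tibble(chrom = "chr1", pos = panel_pos)
    truth <- dplyr::bind_rows(lapply(unique(sheet$patient_id), function(patient) {
      pos <- sort(sample(panel_pos, config$snv_n_true))
      ref_b <- .base_at(reference, pos)
      alt_b <- vapply(ref_b, function(b) sample(setdiff(.BASES, b), 1L), "")
      tibble::tibble(patient_id = patient, chrom = "chr1", pos = pos,
                     ref = ref_b, alt = unname(alt_b))
    }))
    calls <- dplyr::bind_rows(lapply(seq_len(nrow(sheet)), function(i) {
      s <- sheet[i, ]
      tr <- truth[truth$patient_id == s$patient_id, ]
      hit <- stats::runif(nrow(tr)) < config$snv_sensitivity[[s$fixative]]
      tp <- tr[hit, c("chrom", "pos", "ref", "alt")]
      fp_pos <- setdiff(panel_pos, tr$pos)
      fp_pos <- fp_pos[stats::runif(length(fp_pos)) < config$snv_fp_rate[[s$fixative]]]
      fp <- tibble::tibble(
        chrom = "chr1", pos = fp_pos,
        ref = .base_at(reference, fp_pos),
        alt = vapply(.base_at(reference, fp_pos),
                     function(b) sample(setdiff(.BASES, b), 1L), "",
                     USE.NAMES = FALSE)
      )
      dplyr::bind_cols(s[rep(1L, nrow(tp) + nrow(fp)), ],
                       dplyr::arrange(dplyr::bind_rows(tp, fp), .data$pos))
    }))
  })
  list(panel = panel, truth = truth, calls = tibble::as_tibble(calls))
}

#' Simulate a complete matched-fixative cohort
#'
#' Runs every generator under seeds derived from the configuration's master
#' seed, so an identical configuration reproduces the cohort exactly.
#'
#' @param config A [sim_config()].
#' @return An object of class `fixsig_cohort`: list with `config`,
#'   `reference`, `changes`, `truth`, `blacklist`, `cn` (counts + truth),
#'   `qpcr` and `snv` (panel, truth, calls).
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(sim_config(n_patients = 2, burden_common = 50,
#'                                      burden_unique = 50, seed = 1))
#' }
simulate_cohort <- function(config = sim_config()) {
  reference <- generate_reference(config$reference_length, config$seed)
  bc <- simulate_base_changes(config, reference)
  blacklist <- simulate_blacklist(bc$truth, config, reference)
  cn <- simulate_cn_counts(config)
  qpcr <- simulate_qpcr(config)
  snv <- simulate_variant_calls(config, reference)
  structure(
    list(config = config, reference = reference,
         changes = bc$changes, truth = bc$truth, blacklist = blacklist,
         cn = cn, qpcr = qpcr, snv = snv),
    class = "fixsig_cohort"
  )
}
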