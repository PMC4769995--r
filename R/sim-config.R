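FIXATIVES <- c("SF", "UMFIX", "NBF")

#' Default planted trinucleotide signatures
#'
#' Three 96-channel probability vectors used by the synthetic cohort
#' generator, loosely modelled on the processes seen in fixation studies of
#' matched tumour samples:
#'
#' * `noise_a` — non-CpG C>A transversions and C>T transitions (3' flank C/T),
#'   a processing-noise profile.
#' * `noise_b` — T>A changes plus C>A and C>T in an NCA-like context
#'   (3' flank A), a second processing-noise profile.
#' * `cpg_deamination` — C>T at CpG dinucleotides plus diffuse T>C, the
#'   ageing-associated cytosine-deamination profile that dominates true
#'   somatic changes.
#'
#' The three supports are deliberately disjoint so that planted ground truth
#' is unambiguous; real mutational signatures overlap substantially more.
#'
#' @return A 96 x 3 matrix; rows follow [sbs_channels()], columns sum to 1.
#' @export
planted_signatures_default <- function() {
  ch <- sbs_channels()
  cls <- substr(ch, 3, 5)
  f3 <- substr(ch, 7, 7)
  sig <- matrix(0, 96, 3, dimnames = list(ch, c("noise_a", "noise_b", "cpg_deamination")))
  # noise_a: C>A and C>T away from both CpG (3'G) and NCA (3'A) contexts
  sig[cls == "C>A" & f3 %in% c("C", "T"), 1] <- 0.60 / 8
  sig[cls == "C>T" & f3 %in% c("C", "T"), 1] <- 0.40 / 8
  # noise_b: T>A everywhere, C>A and C>T restricted to 3' flank A
  sig[cls == "T>A", 2] <- 0.30 / 16
  sig[cls == "C>A" & f3 == "A", 2] <- 0.30 / 4
  sig[cls == "C>T" & f3 == "A", 2] <- 0.40 / 4
  # cpg_deamination: CpG C>T plus diffuse T>C
  sig[cls == "C>T" & f3 == "G", 3] <- 0.70 / 4
  sig[cls == "T>C", 3] <- 0.30 / 16
  sig
}

#' Build a synthetic-cohort simulation configuration
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults form the package's matched-cohort preset: 12 patients, biopsy
#' and surgical samples each fixed in SF, UMFIX and NBF, three planted
#' trinucleotide signatures of which the CpG-deamination-like one is shared
#' (true somatic) across all samples of a patient, copy-number noise ordered
#' SF < UMFIX < NBF, and qPCR Cq means encoding fixative-dependent loss of
#' long amplifiable fragments.
#'
#' @param n_patients Number of patients.
#' @param sample_types Subset of `c("biopsy", "surgical")`.
#' @param fixatives Ordered fixative labels (default SF, UMFIX, NBF).
#' @param reference_length Reference sequence length in bases.
#' @param planted_signatures 96 x K matrix of signature probability vectors
#'   (each column sums to 1).
#' @param common_signature_index Column of `planted_signatures` used for the
#'   shared (true-SNV-like) changes.
#' @param fixative_noise_weights Matrix (fixatives x remaining signatures) of
#'   mixture weights for fixative-specific noise changes; rows sum to 1.
#' @param burden_common Expected shared changes per patient (Poisson mean).
#' @param burden_unique Expected fixative-unique changes per sample.
#' @param burden_dispersion Log-normal standard deviation (log scale) of the
#'   mean-preserving per-patient (common) and per-sample (unique) burden
#'   multipliers. Real cohorts show order-of-magnitude spread in both tumour
#'   mutation burden and artefact load; this spread is also what renders the
#'   signature factorization identifiable. 0 gives flat burdens.
#' @param cn_n_bins,cn_n_segments Bins and true segments of the copy-number
#'   truth profile.
#' @param cn_states Integer copy-number levels the truth can take.
#' @param cn_noise_sd Named per-fixative standard deviation of bin log2
#'   ratios around the truth.
#' @param read_depth_mean Expected read count of a copy-neutral bin.
#' @param qpcr_mean_cq Matrix (fixatives x amplicons "41","90","129","305")
#'   of mean sample Cq values.
#' @param qpcr_control_cq Named vector of control-template Cq per amplicon.
#' @param qpcr_noise_sd Gaussian Cq measurement noise (cycles).
#' @param blacklist_fraction Fraction of generated change keys flagged as
#'   germline-like (plus an equal number of decoy positions).
#' @param snv_panel_size Assayed positions of the synthetic amplicon panel.
#' @param snv_n_true True somatic variants per patient within the panel.
#' @param snv_sensitivity,snv_fp_rate Named per-fixative detection
#'   probability for true variants and per-position false-positive rate.
#' @param seed Integer master seed.
#' @return A validated list of class `fixsig_sim_config`.
#' @export
sim_config <- function(n_patients = 12,
                       sample_types = c("biopsy", "surgical"),
                       fixatives = FIXATIVES,
                       reference_length = 5e5,
                       planted_signatures = planted_signatures_default(),
                       common_signature_index = 3L,
                       fixative_noise_weights = rbind(
                         SF = c(0.9, 0.1),
                         UMFIX = c(0.5, 0.5),
                         NBF = c(0.1, 0.9)
                       ),
                       burden_common = 1000,
                       burden_unique = 1000,
                       burden_dispersion = 1.0,
                       cn_n_bins = 250,
                       cn_n_segments = 6,
                       cn_states = 1:4,
                       cn_noise_sd = c(SF = 0.10, UMFIX = 0.15, NBF = 0.30),
                       read_depth_mean = 500,
                       qpcr_mean_cq = rbind(
                         SF    = c(`41` = 25.5, `90` = 25.7, `129` = 25.9, `305` = 26.3),
                         UMFIX = c(`41` = 25.8, `90` = 25.9, `129` = 26.6, `305` = 27.6),
                         NBF   = c(`41` = 26.5, `90` = 27.5, `129` = 28.5, `305` = 30.5)
                       ),
                       qpcr_control_cq = c(`41` = 25, `90` = 25, `129` = 25, `305` = 25),
                       qpcr_noise_sd = 0.3,
                       blacklist_fraction = 0.05,
                       snv_panel_size = 300,
                       snv_n_true = 10,
                       snv_sensitivity = c(SF = 0.95, UMFIX = 0.95, NBF = 0.85),
                       snv_fp_rate = c(SF = 0.002, UMFIX = 0.002, NBF = 0.010),
                       seed = 1L) {
  stopifnot(
    n_patients >= 1,
    all(sample_types %in% c("biopsy", "surgical")), length(sample_types) >= 1,
    length(fixatives) >= 2,
    reference_length >= 1000,
    is.matrix(planted_signatures), nrow(planted_signatures) == 96,
    common_signature_index >= 1,
    common_signature_index <= ncol(planted_signatures),
    cn_n_segments <= cn_n_bins,
    burden_common >= 0, burden_unique >= 0, burden_dispersion >= 0,
    qpcr_noise_sd >= 0, blacklist_fraction >= 0, blacklist_fraction <= 1
  )
  if (any(planted_signatures < 0) ||
      any(abs(colSums(planted_signatures) - 1) > 1e-9)) {
    stop("each planted signature must be non-negative and sum to 1",
         call. = FALSE)
  }
  fixative_noise_weights <- as.matrix(fixative_noise_weights)
  if (nrow(fixative_noise_weights) != length(fixatives) ||
      ncol(fixative_noise_weights) != ncol(planted_signatures) - 1L) {
    stop("`fixative_noise_weights` must be (n fixatives) x (n signatures - 1)",
         call. = FALSE)
  }
  if (any(abs(rowSums(fixative_noise_weights) - 1) > 1e-9)) {
    stop("`fixative_noise_weights` rows must sum to 1", call. = FALSE)
  }
  if (is.null(rownames(fixative_noise_weights))) {
    rownames(fixative_noise_weights) <- fixatives
  }
  for (nm in list(cn_noise_sd, snv_sensitivity, snv_fp_rate)) {
    if (!all(fixatives %in% names(nm))) {
      stop("per-fixative parameters must be named for every fixative",
           call. = FALSE)
    }
  }
  if (!all(fixatives %in% rownames(qpcr_mean_cq)) ||
      !all(c("41", "90", "129", "305") %in% colnames(qpcr_mean_cq))) {
    stop("`qpcr_mean_cq` needs one row per fixative and columns 41/90/129/305",
         call. = FALSE)
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      sample_types = sample_types,
      fixatives = fixatives,
      reference_length = as.integer(reference_length),
      planted_signatures = planted_signatures,
      common_signature_index = as.integer(common_signature_index),
      fixative_noise_weights = fixative_noise_weights,
      burden_common = burden_common,
      burden_unique = burden_unique,
      burden_dispersion = burden_dispersion,
      cn_n_bins = as.integer(cn_n_bins),
      cn_n_segments = as.integer(cn_n_segments),
      cn_states = cn_states,
      cn_noise_sd = cn_noise_sd,
      read_depth_mean = read_depth_mean,
      qpcr_mean_cq = qpcr_mean_cq,
      qpcr_control_cq = qpcr_control_cq,
      qpcr_noise_sd = qpcr_noise_sd,
      blacklist_fraction = blacklist_fraction,
      snv_panel_size = as.integer(snv_panel_size),
      snv_n_true = as.integer(snv_n_true),
      snv_sensitivity = snv_sensitivity,
      snv_fp_rate = snv_fp_rate,
      seed = as.integer(seed)
    ),
    class = "fixsig_sim_config"
  )
}

# sample ids follow {patient}_{sampleType}_{fixative}
sample_sheet <- function(config) {
  grid <- expand.grid(
    fixative = config$fixatives,
    sample_type = config$sample_types,
    patient_id = sprintf("P%02d", seq_len(config$n_patients)),
    stringsAsFactors = FALSE
  )
  tibble::tibble(
    sample_id = paste(grid$patient_id, grid$sample_type, grid$fixative, sep = "_"),
    patient_id = grid$patient_id,
    sample_type = grid$sample_type,
    fixative = grid$fixative
  )
}
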