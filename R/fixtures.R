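vcf_header <- function() {
  c("##fileformat=VCFv4.2",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample the change was observed in\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

write_changes_vcf <- function(changes, path) {
  body <- if (nrow(changes)) {
    paste(changes$chrom, changes$pos, ".", changes$ref, changes$alt, ".",
          ".", paste0("SAMPLE=", changes$sample_id), sep = "\t")
  } else character(0)
  writeLines(c(vcf_header(), body), path)
}

read_changes_vcf <- function(path, meta) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF fixtures requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          sample_id = character(0))
  } else {
    out <- tibble::tibble(
      chrom = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT,
      sample_id = sub("^SAMPLE=", "", v@fix[, "INFO"])
    )
  }
  out <- dplyr::left_join(out, meta, by = "sample_id")
  out[, c("chrom", "pos", "ref", "alt", "sample_id", "patient_id",
          "fixative", "sample_type", "assay")]
}

#' Write every fixture of a simulated cohort to disk
#'
#' Serializes the cohort as plain-text interchange files: single-record
#' FASTA reference, merged minimal VCF v4.2 of base changes (one record per
#' observed change with a `SAMPLE` info tag) plus a sample-metadata TSV
#' sidecar, BED-like TSV of bin counts, TSVs for the blacklist, ground-truth
#' labels, copy-number truth and SNV panel/truth/calls, a CSV qPCR table,
#' and — written last, atomically — a manifest listing every file with its
#' record count (so a partial write leaves no manifest).
#'
#' @param cohort A `fixsig_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble (file, n_records).
#' @export
write_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- Biostrings::DNAStringSet(cohort$reference)
  names(ref) <- "chr1"
  Biostrings::writeXStringSet(ref, file.path(dir, "reference.fasta"), width = 80)

  meta <- dplyr::distinct(cohort$changes[, c("sample_id", "patient_id",
                                             "fixative", "sample_type",
                                             "assay")])
  readr::write_tsv(meta, file.path(dir, "samples.tsv"))
  write_changes_vcf(cohort$changes, file.path(dir, "changes.vcf"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth_labels.tsv"))
  readr::write_tsv(cohort$blacklist, file.path(dir, "blacklist.tsv"))
  readr::write_tsv(cohort$cn$counts, file.path(dir, "bin_counts.tsv"))
  readr::write_tsv(cohort$cn$truth, file.path(dir, "cn_truth.tsv"))
  readr::write_csv(cohort$qpcr, file.path(dir, "qpcr.csv"))
  readr::write_tsv(cohort$snv$panel, file.path(dir, "snv_panel.tsv"))
  readr::write_tsv(cohort$snv$truth, file.path(dir, "snv_truth.tsv"))
  readr::write_tsv(cohort$snv$calls, file.path(dir, "snv_calls.tsv"))

  manifest <- tibble::tibble(
    file = c("reference.fasta", "samples.tsv", "changes.vcf",
             "truth_labels.tsv", "blacklist.tsv", "bin_counts.tsv",
             "cn_truth.tsv", "qpcr.csv", "snv_panel.tsv", "snv_truth.tsv",
             "snv_calls.tsv"),
    n_records = c(1L, nrow(meta), nrow(cohort$changes), nrow(cohort$truth),
                  nrow(cohort$blacklist), nrow(cohort$cn$counts),
                  nrow(cohort$cn$truth), nrow(cohort$qpcr),
                  nrow(cohort$snv$panel), nrow(cohort$snv$truth),
                  nrow(cohort$snv$calls))
  )
  tmp <- tempfile(tmpdir = dir, fileext = ".tsv")
  readr::write_tsv(manifest, tmp)
  file.rename(tmp, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Read a fixture directory back into memory
#'
#' Inverse of [write_fixtures()]: the returned object is field-by-field
#' equal to the cohort that was written (minus the configuration, which is
#' not serialized). The VCF is parsed with vcfR.
#'
#' @param dir Directory written by [write_fixtures()].
#' @return List with `reference`, `changes`, `truth`, `blacklist`, `cn`
#'   (counts + truth), `qpcr`, `snv` (panel, truth, calls) and `manifest`.
#' @export
read_fixtures <- function(dir) {
  if (!file.exists(file.path(dir, "manifest.tsv"))) {
    stop("no manifest.tsv in ", dir, " (incomplete fixture set?)",
         call. = FALSE)
  }
  ref <- Biostrings::readDNAStringSet(file.path(dir, "reference.fasta"))
  meta <- readr::read_tsv(file.path(dir, "samples.tsv"),
                          show_col_types = FALSE)
  tsv <- function(f, ...) readr::read_tsv(file.path(dir, f),
                                          show_col_types = FALSE, ...)
  list(
    reference = as.character(ref[[1]]),
    changes = read_changes_vcf(file.path(dir, "changes.vcf"), meta),
    truth = tsv("truth_labels.tsv"),
    blacklist = tsv("blacklist.tsv"),
    cn = list(counts = tsv("bin_counts.tsv"), truth = tsv("cn_truth.tsv")),
    qpcr = readr::read_csv(file.path(dir, "qpcr.csv"),
                           show_col_types = FALSE),
    snv = list(panel = tsv("snv_panel.tsv"), truth = tsv("snv_truth.tsv"),
               calls = tsv("snv_calls.tsv")),
    manifest = tsv("manifest.tsv")
  )
}

#' Reference signature profiles shipped with the package
#'
#' Loads the packaged synthetic reference-signature TSV (96 channels x
#' profiles). These are constructed stand-ins — a CpG cytosine-deamination
#' C>T profile and two processing-noise profiles — for matching fitted
#' signatures by cosine similarity, not measured human signatures.
#'
#' @return 96 x K numeric matrix, rows in [sbs_channels()] order.
#' @export
reference_signatures <- function() {
  path <- system.file("extdata", "reference_signatures_synthetic.tsv",
                      package = "fixsig", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat[sbs_channels(), , drop = FALSE]
}
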