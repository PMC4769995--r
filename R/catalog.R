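change_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Remove blacklisted (germline-like) changes from a base-change table
#'
#' Drops rows whose (chrom, pos, ref, alt) key appears in the blacklist —
#' the in-silico analogue of excluding known germline SNPs before noise
#' analysis. Row order is preserved.
#'
#' @param changes Base-change tibble (chrom, pos, ref, alt, ...).
#' @param blacklist Tibble of keys (chrom, pos, ref, alt); may be empty.
#' @return The filtered tibble, with attribute `n_removed` giving the number
#'   of rows dropped.
#' @export
filter_blacklist <- function(changes, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0L) {
    out <- changes
    attr(out, "n_removed") <- 0L
    return(out)
  }
  hit <- change_key(changes) %in% change_key(blacklist)
  out <- changes[!hit, , drop = FALSE]
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Annotate base changes with trinucleotide context and 96-channel label
#'
#' Looks up both reference flanks of every change, collapses onto the
#' pyrimidine strand and assigns the canonical channel. Changes at the
#' sequence edge or with a non-ACGT base in the window cannot be annotated:
#' they are dropped and counted.
#'
#' @param changes Base-change tibble.
#' @param reference Reference sequence string (single chromosome).
#' @return The tibble with a `channel` column added; attribute `n_dropped`
#'   counts changes without an annotatable context.
#' @export
annotate_channels <- function(changes, reference) {
  reference <- toupper(as.character(reference))
  n <- nchar(reference)
  if (nrow(changes) == 0L) {
    out <- changes
    out$channel <- character(0)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  pos <- changes$pos
  ok <- pos >= 2L & pos <= n - 1L
  f5 <- rep(NA_character_, nrow(changes))
  f3 <- rep(NA_character_, nrow(changes))
  f5[ok] <- substring(reference, pos[ok] - 1L, pos[ok] - 1L)
  f3[ok] <- substring(reference, pos[ok] + 1L, pos[ok] + 1L)
  ok <- ok & f5 %in% .BASES & f3 %in% .BASES &
    changes$ref %in% .BASES & changes$alt %in% .BASES
  out <- changes[ok, , drop = FALSE]
  out$channel <- collapse_strand(out$ref, out$alt, f5[ok], f3[ok])
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Partition one patient's changes into common / fixative-unique categories
#'
#' A change key observed in every sample of the patient is `common`;
#' a key observed in exactly one sample is unique to that sample's fixative
#' (`SF-unique`, `UMFIX-unique`, `NBF-unique`); keys present in a strict
#' subset of two or more samples are `unassigned` and excluded from
#' signature-category analyses. Both sample types of a fixative count as
#' separate samples.
#'
#' @param changes Base-change tibble for a single patient (columns chrom,
#'   pos, ref, alt, sample_id, fixative). At least two samples required.
#' @return Tibble of distinct keys with columns chrom, pos, ref, alt,
#'   n_samples and `category`.
#' @export
partition_categories <- function(changes) {
  if (length(unique(changes$patient_id)) > 1L) {
    stop("`partition_categories()` expects changes from a single patient; ",
         "use `partition_cohort()` for many", call. = FALSE)
  }
  samples <- unique(changes$sample_id)
  if (length(samples) < 2L) {
    stop("category partition is undefined for a patient with fewer than ",
         "two samples", call. = FALSE)
  }
  keys <- dplyr::summarise(
    dplyr::group_by(changes, .data$chrom, .data$pos, .data$ref, .data$alt),
    n_samples = dplyr::n_distinct(.data$sample_id),
    fixative = if (dplyr::n_distinct(.data$sample_id) == 1L)
      .data$fixative[1] else NA_character_,
    .groups = "drop"
  )
  keys$category <- dplyr::case_when(
    keys$n_samples == length(samples) ~ "common",
    keys$n_samples == 1L ~ paste0(keys$fixative, "-unique"),
    TRUE ~ "unassigned"
  )
  dplyr::arrange(keys[, c("chrom", "pos", "ref", "alt", "n_samples", "category")],
                 .data$pos)
}

#' Partition every patient of a cohort into change categories
#'
#' Applies [partition_categories()] per patient and binds the results.
#'
#' @param changes Base-change tibble with a `patient_id` column.
#' @return Tibble with patient_id + the per-key category assignment.
#' @export
partition_cohort <- function(changes) {
  dplyr::bind_rows(lapply(split(changes, changes$patient_id), function(df) {
    out <- partition_categories(df)
    dplyr::bind_cols(tibble::tibble(patient_id = df$patient_id[1]), out)
  }))
}

#' Build a 96-channel mutation catalog
#'
#' Counts channel occurrences per group (per sample, or per change
#' category). Multiplicity is preserved: one row of the input is one
#' observed change event. Changes without an annotatable context are dropped
#' and reported via the `n_dropped` attribute. Column order is
#' deterministic (sorted group names); the 96 rows follow [sbs_channels()].
#'
#' @param changes Base-change tibble.
#' @param reference Reference sequence string.
#' @param group_by Column that defines catalog columns, `"sample_id"` or
#'   `"category"` (any column of `changes` works).
#' @return A 96 x n integer matrix of class `mutation_catalog`.
#' @export
#' @examples
#' ref <- "TTACGTT"
#' x <- tibble::tibble(chrom = "chr1", pos = 4, ref = "C", alt = "T",
#'                     sample_id = "s1")
#' build_catalog(x, ref)
build_catalog <- function(changes, reference, group_by = "sample_id") {
  stopifnot(group_by %in% names(changes) || nrow(changes) == 0L)
  ann <- annotate_channels(changes, reference)
  groups <- if (nrow(ann)) sort(unique(ann[[group_by]])) else character(0)
  mat <- matrix(0L, nrow = 96, ncol = length(groups),
                dimnames = list(sbs_channels(), groups))
  if (nrow(ann)) {
    tab <- table(factor(ann$channel, levels = sbs_channels()),
                 factor(ann[[group_by]], levels = groups))
    mat[] <- as.integer(tab)
  }
  structure(mat, class = c("mutation_catalog", "matrix", "array"),
            n_dropped = attr(ann, "n_dropped"))
}

#' Build per-category catalogs for a whole cohort
#'
#' Filters the blacklist, partitions each patient's keys into categories,
#' attaches the category to every change row (distinct keys per patient) and
#' builds one catalog column per category, pooling patients. Unassigned keys
#' are excluded.
#'
#' @param changes Base-change tibble for the cohort.
#' @param reference Reference sequence string.
#' @param blacklist Optional blacklist tibble.
#' @return A `mutation_catalog` with columns `common`, `SF-unique`,
#'   `UMFIX-unique`, `NBF-unique` (those present).
#' @export
build_category_catalog <- function(changes, reference, blacklist = NULL) {
  kept <- filter_blacklist(changes, blacklist)
  part <- partition_cohort(kept)
  part <- part[part$category != "unassigned", ]
  keyed <- dplyr::distinct(kept[, c("patient_id", "chrom", "pos", "ref", "alt")])
  keyed <- dplyr::inner_join(
    keyed, part,
    by = c("patient_id", "chrom", "pos", "ref", "alt")
  )
  build_catalog(keyed, reference, group_by = "category")
}
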