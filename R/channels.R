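#' Canonical 96-channel trinucleotide substitution labels
#'
#' The six pyrimidine-centric substitution classes (C>A, C>G, C>T, T>A, T>C,
#' T>G) crossed with the 16 flank pairs, flanks ordered lexicographically
#' (5' flank varying slowest) within each class. This order is frozen so that
#' catalogs written by different runs are byte-comparable.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`, `"A[C>A]C"`, ...
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  bases <- c("A", "C", "G", "T")
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(classes, function(cl) {
    ref <- substr(cl, 1, 1)
    as.vector(t(outer(bases, bases, function(f5, f3) {
      paste0(f5, "[", cl, "]", f3)
    })))
  }), use.names = FALSE)
}

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Extract the reference trinucleotide context at a position
#'
#' Reads the three reference bases centred on `pos` (1-based). Positions at
#' the sequence edge have no flank and raise an error; windows containing a
#' non-ACGT base (e.g. N) raise a context-unavailable error so the caller can
#' exclude and log the change.
#'
#' @param reference A single character string or `Biostrings::DNAString` of
#'   the reference sequence (one chromosome).
#' @param pos 1-based position of the central base.
#' @return Character vector `c(flank5, ref, flank3)`, uppercase.
#' @export
#' @examples
#' extract_context("TACGT", 3)
extract_context <- function(reference, pos) {
  reference <- toupper(as.character(reference))
  n <- nchar(reference)
  if (length(pos) != 1L || is.na(pos) || pos != as.integer(pos)) {
    stop("`pos` must be a single integer position", call. = FALSE)
  }
  if (pos < 2L || pos > n - 1L) {
    stop("position ", pos, " is at the sequence edge (need both flanks, ",
         "valid range 2..", n - 1L, ")", call. = FALSE)
  }
  tri <- strsplit(substr(reference, pos - 1L, pos + 1L), "")[[1]]
  if (!all(tri %in% .BASES)) {
    stop("context unavailable at position ", pos,
         ": non-ACGT base in window ", paste(tri, collapse = ""),
         call. = FALSE)
  }
  tri
}

#' Collapse a base change onto the pyrimidine strand
#'
#' Maps an observed substitution and its trinucleotide context onto one of
#' the 96 canonical channels. Changes whose reference base is a purine are
#' reverse-complemented (flanks swap and complement) so every channel has a
#' central pyrimidine.
#'
#' Vectorised over `ref`, `alt`, `flank5`, `flank3`.
#'
#' @param ref,alt Reference and alternate bases (single characters, A/C/G/T,
#'   `ref != alt`).
#' @param flank5,flank3 The 5' and 3' reference flanks of the change.
#' @return Channel label(s), e.g. `"A[C>T]G"`.
#' @export
#' @examples
#' collapse_strand("C", "T", "A", "G") # "A[C>T]G"
#' collapse_strand("G", "A", "C", "T") # same channel, opposite strand
collapse_strand <- function(ref, alt, flank5, flank3) {
  ref <- toupper(ref); alt <- toupper(alt)
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  ok <- ref %in% .BASES & alt %in% .BASES &
    flank5 %in% .BASES & flank3 %in% .BASES
  if (!all(ok)) stop("bases must be one of A, C, G, T", call. = FALSE)
  if (any(ref == alt)) stop("`ref` and `alt` must differ", call. = FALSE)
  purine <- ref %in% c("A", "G")
  r <- ifelse(purine, .COMPLEMENT[ref], ref)
  a <- ifelse(purine, .COMPLEMENT[alt], alt)
  f5 <- ifelse(purine, .COMPLEMENT[flank3], flank5)
  f3 <- ifelse(purine, .COMPLEMENT[flank5], flank3)
  paste0(f5, "[", r, ">", a, "]", f3)
}
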