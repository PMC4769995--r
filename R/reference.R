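#' Generate a random reference sequence covering all trinucleotide contexts
#'
#' Draws an i.i.d. uniform A/C/G/T sequence and guarantees that every one of
#' the 32 pyrimidine-centric trinucleotides (central C or T, after strand
#' collapse) occurs at least once: any context absent after the initial draw
#' is patched in deterministically by overwriting a dedicated 3-base window
#' near the start of the sequence. Sequences shorter than 1000 bases are
#' refused because patching would dominate the composition.
#'
#' @param length Sequence length in bases (>= 1000).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @return A single uppercase character string of length `length`.
#' @export
#' @examples
#' ref <- generate_reference(2000, seed = 7)
generate_reference <- function(length, seed = 1L) {
  if (length < 1000) {
    stop("`length` must be >= 1000 to guarantee trinucleotide coverage ",
         "(got ", length, ")", call. = FALSE)
  }
  bases <- .BASES
  seq <- withr::with_seed(seed,
    sample(bases, length, replace = TRUE))

  # 32 collapsed contexts: 5' x {C,T} x 3'
  wanted <- as.vector(outer(bases, c("C", "T"), paste0))
  wanted <- as.vector(outer(wanted, bases, paste0))
  missing_ctx <- setdiff(wanted, unique(.collapsed_trinucleotides(seq)))
  if (length(missing_ctx) > 0L) {
    # deterministic patch: write each missing context into its own window,
    # windows spaced 4 apart starting at position 2 so they never overlap
    for (i in seq_along(missing_ctx)) {
      at <- 2L + (i - 1L) * 4L
      seq[at:(at + 2L)] <- strsplit(missing_ctx[i], "")[[1]]
    }
    still <- setdiff(wanted, unique(.collapsed_trinucleotides(seq)))
    if (length(still) > 0L) {
      stop("could not achieve trinucleotide coverage; missing: ",
           paste(still, collapse = ", "), call. = FALSE)
    }
  }
  paste(seq, collapse = "")
}

# pyrimidine-collapsed trinucleotide at every internal position of a
# character vector of bases; positions whose centre is a purine are
# reverse-complemented
.collapsed_trinucleotides <- function(seq_chars) {
  n <- length(seq_chars)
  if (n < 3L) return(character(0))
  f5 <- seq_chars[1:(n - 2L)]
  ct <- seq_chars[2:(n - 1L)]
  f3 <- seq_chars[3:n]
  purine <- ct %in% c("A", "G")
  tri <- paste0(
    ifelse(purine, .COMPLEMENT[f3], f5),
    ifelse(purine, .COMPLEMENT[ct], ct),
    ifelse(purine, .COMPLEMENT[f5], f3)
  )
  tri
}

#' Index reference positions by pyrimidine-collapsed trinucleotide context
#'
#' Precomputes, for each of the 32 collapsed contexts, the 1-based positions
#' whose reference trinucleotide matches. Used by the simulator to place
#' changes so that their annotated context equals the channel they were
#' sampled from.
#'
#' @param reference Reference sequence (character string).
#' @return Named list of integer position vectors, names = 32 contexts.
#' @export
context_position_index <- function(reference) {
  seq_chars <- strsplit(toupper(as.character(reference)), "")[[1]]
  tri <- .collapsed_trinucleotides(seq_chars)
  split(seq_along(tri) + 1L, tri)
}
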