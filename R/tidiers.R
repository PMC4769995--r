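#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mutation catalog into long format
#'
#' @param x A `mutation_catalog`.
#' @param ... Unused.
#' @return Tibble: channel, substitution class, column, count.
#' @method tidy mutation_catalog
#' @export
tidy.mutation_catalog <- function(x, ...) {
  mat <- unclass(x)
  out <- tibble::tibble(
    channel = rep(rownames(mat), ncol(mat)),
    class = rep(substr(rownames(mat), 3, 5), ncol(mat)),
    column = rep(colnames(mat), each = nrow(mat)),
    count = as.vector(mat)
  )
  out
}

#' Tidy the signature matrix of an NMF fit
#'
#' @param x A `fixsig_nmf` object.
#' @param matrix Which factor to return, `"W"` (signatures; channel
#'   weights) or `"H"` (exposures; counts per column).
#' @param ... Unused.
#' @return Long tibble of the requested factor.
#' @method tidy fixsig_nmf
#' @export
tidy.fixsig_nmf <- function(x, matrix = c("W", "H"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "W") {
    tibble::tibble(
      channel = rep(rownames(x$W), ncol(x$W)),
      class = rep(substr(rownames(x$W), 3, 5), ncol(x$W)),
      signature = rep(colnames(x$W), each = nrow(x$W)),
      weight = as.vector(x$W)
    )
  } else {
    tibble::tibble(
      signature = rep(rownames(x$H), ncol(x$H)),
      column = rep(colnames(x$H) %||% as.character(seq_len(ncol(x$H))),
                   each = nrow(x$H)),
      exposure = as.vector(x$H)
    )
  }
}

#' One-row summary of an NMF fit
#'
#' @param x A `fixsig_nmf` object.
#' @param ... Unused.
#' @return Tibble: k, divergence, n_iter, converged.
#' @method glance fixsig_nmf
#' @export
glance.fixsig_nmf <- function(x, ...) {
  tibble::tibble(k = x$K, divergence = x$divergence, n_iter = x$n_iter,
                 converged = x$converged)
}

#' Tidy refitted exposures
#'
#' @param x A `fixsig_exposures` object.
#' @param ... Unused.
#' @return Tibble: signature, column, exposure (counts), proportion.
#' @method tidy fixsig_exposures
#' @export
tidy.fixsig_exposures <- function(x, ...) {
  tibble::tibble(
    signature = rep(rownames(x$H), ncol(x$H)),
    column = rep(colnames(x$H) %||% as.character(seq_len(ncol(x$H))),
                 each = nrow(x$H)),
    exposure = as.vector(x$H),
    proportion = as.vector(x$proportions)
  )
}

#' One-row summary of a rank-selection report
#'
#' @param x A `fixsig_rank_report`.
#' @param ... Unused.
#' @return Tibble: selected_k, max_stability, low_confidence.
#' @method glance fixsig_rank_report
#' @export
glance.fixsig_rank_report <- function(x, ...) {
  tibble::tibble(
    selected_k = attr(x, "selected_k"),
    max_stability = max(x$stability),
    low_confidence = attr(x, "low_confidence")
  )
}
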