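#' Generalized Kullback-Leibler divergence D(V || WH)
#'
#' The Poisson-likelihood objective minimized by the signature
#' factorization: `sum(v*log(v/x) - v + x)` over all matrix entries, with
#' the convention `0*log(0) = 0`.
#'
#' @param V Non-negative data matrix.
#' @param WH Non-negative reconstruction of the same dimension.
#' @return A single non-negative number.
#' @export
kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(WH) - sum(V) + sum(V[pos] * log(V[pos] / pmax(WH[pos], 1e-300)))
}

.nmf_run <- function(V, K, max_iter, tol, eps = 1e-16) {
  n <- ncol(V)
  W <- matrix(stats::runif(96 * K, 0.1, 1), 96, K)
  H <- matrix(stats::runif(K * n, 0.1, 1), K, n)
  trace <- numeric(0)
  d_prev <- Inf
  it <- 0L
  converged <- FALSE
  zero <- V == 0
  while (it < max_iter) {
    it <- it + 1L
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    R[zero] <- 0
    H <- H * (crossprod(W, R)) / pmax(colSums(W), eps)
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    R[zero] <- 0
    W <- W * (R %*% t(H)) / rep(pmax(rowSums(H), eps), each = 96)
    d <- kl_divergence(V, W %*% H)
    trace <- c(trace, d)
    if (is.finite(d_prev) && abs(d_prev - d) <= tol * max(1, abs(d_prev))) {
      converged <- TRUE
      break
    }
    d_prev <- d
  }
  list(W = W, H = H, divergence = d, trace = trace, n_iter = it,
       converged = converged)
}

#' Factorize a mutation catalog into non-negative signatures and exposures
#'
#' Minimizes the generalized Kullback-Leibler divergence between the 96 x n
#' catalog and `W %*% H` by multiplicative updates, keeping the best of
#' `n_restarts` random initializations (distinct sub-seeds of `seed`).
#' Signature columns of `W` are normalized to sum to 1 with the scale
#' absorbed into `H`, so exposures are in units of expected change counts.
#' Components are ordered by descending total exposure.
#'
#' @param catalog 96 x n non-negative matrix (a `mutation_catalog` or plain
#'   matrix), at least one column.
#' @param K Number of signatures, `1 <= K <= min(96, ncol)`.
#' @param n_restarts Random restarts; the fit with the lowest final
#'   divergence wins.
#' @param max_iter Maximum multiplicative-update iterations per restart.
#' @param tol Relative divergence-change convergence tolerance.
#' @param seed Integer seed controlling all initializations.
#' @return Object of class `fixsig_nmf`: list with `W` (96 x K, columns sum
#'   to 1), `H` (K x n), `divergence`, `trace` (divergence per iteration of
#'   the winning restart), `n_iter`, `converged`, `K`.
#' @export
nmf_factorize <- function(catalog, K, n_restarts = 20, max_iter = 5000,
                          tol = 1e-8, seed = 1L) {
  V <- unclass(as.matrix(catalog))
  if (nrow(V) != 96) stop("catalog must have 96 rows", call. = FALSE)
  if (ncol(V) < 1L) stop("catalog must have at least one column", call. = FALSE)
  if (any(V < 0)) stop("catalog must be non-negative", call. = FALSE)
  if (sum(V) == 0) stop("catalog is all zero", call. = FALSE)
  if (K < 1 || K > min(96, ncol(V))) {
    stop("K must be between 1 and min(96, ncol(catalog)) = ",
         min(96, ncol(V)), call. = FALSE)
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_restarts))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- withr::with_seed(sub_seeds[r], .nmf_run(V, K, max_iter, tol))
    if (is.null(best) || fit$divergence < best$divergence) best <- fit
  }
  scale <- colSums(best$W)
  scale[scale == 0] <- 1
  W <- sweep(best$W, 2, scale, "/")
  H <- best$H * scale
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  sig_names <- paste0("S", seq_len(K))
  dimnames(W) <- list(rownames(V) %||% sbs_channels(), sig_names)
  dimnames(H) <- list(sig_names, colnames(V))
  structure(
    list(W = W, H = H, divergence = best$divergence, trace = best$trace,
         n_iter = best$n_iter, converged = best$converged, K = K),
    class = "fixsig_nmf"
  )
}

#' @export
print.fixsig_nmf <- function(x, ...) {
  cat("KL-NMF signature fit: K =", x$K, "| divergence =",
      format(x$divergence, digits = 6), "|", x$n_iter, "iterations",
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Refit exposures against a fixed signature matrix
#'
#' Per-column non-negative exposures minimizing the KL divergence with `W`
#' frozen (multiplicative updates on `H` only). All-zero catalog columns get
#' zero exposures and are flagged.
#'
#' @param catalog 96 x n non-negative matrix.
#' @param W 96 x K signature matrix with columns summing to 1.
#' @param max_iter,tol Convergence controls as in [nmf_factorize()].
#' @param seed Seed for the (uniform) initialization.
#' @return Object of class `fixsig_exposures`: list with `H` (counts),
#'   `proportions` (columns sum to 1; zero columns stay zero and are listed
#'   in `flagged`), `divergence`.
#' @export
estimate_exposures <- function(catalog, W, max_iter = 5000, tol = 1e-10,
                               seed = 1L) {
  V <- unclass(as.matrix(catalog))
  W <- as.matrix(W)
  if (nrow(V) != 96 || nrow(W) != 96) {
    stop("catalog and W must both have 96 rows", call. = FALSE)
  }
  K <- ncol(W)
  n <- ncol(V)
  eps <- 1e-16
  zero_col <- colSums(V) == 0
  H <- withr::with_seed(seed, matrix(stats::runif(K * n, 0.1, 1), K, n))
  zero <- V == 0
  d_prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H
    R <- V / pmax(WH, eps)
    R[zero] <- 0
    H <- H * (crossprod(W, R)) / pmax(colSums(W), eps)
    d <- kl_divergence(V, W %*% H)
    if (is.finite(d_prev) && abs(d_prev - d) <= tol * max(1, abs(d_prev))) break
    d_prev <- d
  }
  H[, zero_col] <- 0
  totals <- colSums(H)
  prop <- sweep(H, 2, ifelse(totals > 0, totals, 1), "/")
  dimnames(H) <- dimnames(prop) <- list(colnames(W), colnames(V))
  structure(
    list(H = H, proportions = prop, divergence = kl_divergence(V, W %*% H),
         flagged = colnames(V)[zero_col] %||% which(zero_col)),
    class = "fixsig_exposures"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
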