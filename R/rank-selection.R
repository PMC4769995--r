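cosine_similarity <- function(A, B = A) {
  An <- sweep(A, 2, pmax(sqrt(colSums(A^2)), 1e-300), "/")
  Bn <- sweep(B, 2, pmax(sqrt(colSums(B^2)), 1e-300), "/")
  crossprod(An, Bn)
}

# multinomial resample of each catalog column, preserving column totals
bootstrap_catalog <- function(V) {
  out <- V
  for (j in seq_len(ncol(V))) {
    tot <- sum(V[, j])
    if (tot > 0) out[, j] <- stats::rmultinom(1, tot, V[, j])
  }
  out
}

#' Select the number of signatures by bootstrap stability
#'
#' For each candidate rank K, resamples each catalog column's changes with
#' replacement (multinomial, preserving column totals), factorizes every
#' bootstrap replicate (one random start each, so that optimizer
#' variability contributes to the instability of unsupported components),
#' pools all bootstrap signatures and clusters them into K groups by cosine
#' distance (partitioning around medoids). The stability score of K is the
#' *minimum* over clusters of the cluster-average silhouette width: a rank
#' is only as stable as its least reproducible signature, and the pooled
#' mean can stay high while one redundant component lands somewhere
#' different in every replicate (the mean is also reported). K = 1 is
#' defined as perfectly stable (single component, silhouette undefined).
#' The selected rank is the largest K whose stability meets `threshold`;
#' if none does, the most stable K (smallest on ties) is chosen.
#' Reconstruction divergence on the full catalog is reported per K.
#'
#' @param catalog 96 x n non-negative matrix.
#' @param k_min,k_max Candidate rank range (`k_max <= min(96, ncol)`).
#' @param n_bootstrap Bootstrap replicates per K.
#' @param n_restarts,max_iter,tol Factorization controls passed to
#'   [nmf_factorize()].
#' @param threshold Minimum mean silhouette for a K to count as stable.
#' @param seed Integer seed.
#' @return A tibble of class `fixsig_rank_report` with columns `k`,
#'   `divergence`, `stability` (min cluster silhouette), `stability_mean`,
#'   `selected`; attributes `selected_k` and `low_confidence` (TRUE for
#'   single-column catalogs).
#' @export
select_rank <- function(catalog, k_min = 1, k_max = 5, n_bootstrap = 100,
                        n_restarts = 3, max_iter = 2000, tol = 1e-6,
                        threshold = 0.8, seed = 1L) {
  V <- unclass(as.matrix(catalog))
  if (k_max > min(96, ncol(V))) {
    stop("k_max must be <= min(96, ncol(catalog))", call. = FALSE)
  }
  low_confidence <- ncol(V) == 1L
  ks <- seq.int(k_min, k_max)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, length(ks) * (n_bootstrap + 1)))
  seeds <- matrix(seeds, nrow = length(ks))
  rows <- lapply(seq_along(ks), function(i) {
    K <- ks[i]
    full_fit <- nmf_factorize(V, K, n_restarts = n_restarts,
                              max_iter = max_iter, tol = tol,
                              seed = seeds[i, 1])
    if (K == 1L) {
      stab <- 1
      stab_mean <- 1
    } else {
      sigs <- lapply(seq_len(n_bootstrap), function(b) {
        Vb <- withr::with_seed(seeds[i, b + 1], bootstrap_catalog(V))
        nmf_factorize(Vb, K, n_restarts = 1, max_iter = max_iter, tol = tol,
                      seed = seeds[i, b + 1])$W
      })
      pool <- do.call(cbind, sigs)
      dmat <- 1 - cosine_similarity(pool)
      dmat[dmat < 0] <- 0
      pam_fit <- cluster::pam(stats::as.dist(dmat), k = K, pamonce = 5)
      stab <- min(pam_fit$silinfo$clus.avg.widths)
      stab_mean <- pam_fit$silinfo$avg.width
    }
    tibble::tibble(k = K, divergence = full_fit$divergence, stability = stab,
                   stability_mean = stab_mean)
  })
  report <- dplyr::bind_rows(rows)
  stable <- report$k[report$stability >= threshold]
  selected_k <- if (length(stable) > 0) max(stable) else
    report$k[which.max(report$stability)]
  report$selected <- report$k == selected_k
  structure(report, class = c("fixsig_rank_report", class(report)),
            selected_k = selected_k, low_confidence = low_confidence)
}

#' Match fitted signatures to reference profiles
#'
#' Computes the full pairwise cosine-similarity matrix between fitted and
#' reference signature columns and the one-to-one assignment maximizing the
#' total similarity (Hungarian algorithm). When the two sets differ in
#' size, the unmatched columns are reported.
#'
#' @param W 96 x K fitted signature matrix.
#' @param reference 96 x R reference signature matrix.
#' @return List with `assignment` (tibble: signature, reference, cosine),
#'   `cosine` (K x R matrix), `unmatched` (names of unpaired columns).
#' @export
match_signatures <- function(W, reference) {
  W <- as.matrix(W); reference <- as.matrix(reference)
  if (nrow(W) != nrow(reference)) {
    stop("signature matrices must have the same number of rows", call. = FALSE)
  }
  C <- cosine_similarity(W, reference)
  K <- ncol(W); R <- ncol(reference)
  n <- max(K, R)
  cost <- matrix(0, n, n)  # padded square; maximize cosine == minimize -cosine
  cost[seq_len(K), seq_len(R)] <- -C
  assign_col <- hungarian_assignment(cost)
  rows <- seq_len(K)
  cols <- assign_col[rows]
  keep <- cols <= R
  assignment <- tibble::tibble(
    signature = (colnames(W) %||% paste0("S", seq_len(K)))[rows[keep]],
    reference = (colnames(reference) %||% paste0("R", seq_len(R)))[cols[keep]],
    cosine = C[cbind(rows[keep], cols[keep])]
  )
  unmatched <- c(
    (colnames(W) %||% paste0("S", seq_len(K)))[rows[!keep]],
    setdiff(colnames(reference) %||% paste0("R", seq_len(R)),
            assignment$reference)
  )
  list(assignment = assignment, cosine = C, unmatched = unmatched)
}

#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Potential-based O(n^3) shortest-augmenting-path formulation for a square
#' cost matrix. Used by [match_signatures()]; exported because optimal
#' assignment is handy on its own.
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector `a` with `a[i]` = column assigned to row `i`.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  # column index n+1 is the virtual root column of the augmenting path
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j] = row matched to column j (0 = free)
  way <- integer(n + 1)  # predecessor column on the shortest path
  for (i in seq_len(n)) {
    p[n + 1] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- logical(n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= n) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j] > 0L) assignment[p[j]] <- j
  assignment
}
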