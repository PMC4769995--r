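# cohort cache so expensive simulations are shared across test files
.cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function(seed) {
  key <- paste0("d", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  }
  .cohort_cache[[key]]
}

small_config <- function(seed = 42, ...) {
  sim_config(n_patients = 2, reference_length = 20000,
             burden_common = 60, burden_unique = 60,
             cn_n_bins = 40, cn_n_segments = 3, seed = seed, ...)
}

small_cohort <- function(seed = 42) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(small_config(seed))
  }
  .cohort_cache[[key]]
}

# brute-force rank-sum p-value by enumerating every assignment of ranks to
# the x-group (tie-free data only); independent of the package's DP branch
enumerate_ranksum_p <- function(x, y, alternative = "two.sided") {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  all_w <- apply(utils::combn(n, nx), 2, sum)
  p_le <- mean(all_w <= W)
  p_ge <- mean(all_w >= W)
  switch(alternative,
         two.sided = min(1, 2 * min(p_le, p_ge)),
         less = p_le,
         greater = p_ge)
}

# brute-force optimal assignment by permutation enumeration
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL
  best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_cost) {
      best_cost <- cc
      best <- p
    }
  }
  list(assignment = best, cost = best_cost)
}
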