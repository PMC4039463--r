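# Shared helpers: independent brute-force oracles and a small, fast
# generator configuration.

# small genome for cheap cohort generation in unit tests
small_genome <- function(marker_spacing = 1e4, n_genes = 200)
  default_genome(n_genes = n_genes, marker_spacing = marker_spacing)

small_config <- function(n_genes = 200, marker_spacing = 1e4, ...)
  cohort_config(genome = small_genome(marker_spacing, n_genes), ...)

# exhaustive HMM oracle: enumerate the scores of ALL K^n state paths by
# incremental expansion (no max-pruning until the very end)
exhaustive_path_max <- function(x, params) {
  K <- length(params$state_means)
  emis <- sapply(seq_len(K), function(k)
    dnorm(x, params$state_means[k], params$emission_sd, log = TRUE))
  if (length(x) == 1) emis <- matrix(emis, nrow = 1)
  lt <- params$log_trans
  scores <- params$log_init + emis[1, ]
  last <- seq_len(K)
  if (length(x) > 1) for (t in 2:length(x)) {
    ns <- length(scores)
    new_scores <- numeric(ns * K)
    new_last <- integer(ns * K)
    for (k in seq_len(K)) {
      idx <- (k - 1) * ns + seq_len(ns)
      new_scores[idx] <- scores + lt[cbind(last, k)] + emis[t, k]
      new_last[idx] <- k
    }
    scores <- new_scores
    last <- new_last
  }
  max(scores)
}

# single-arm marker track with a planted CN block
planted_track <- function(n = 2000, spacing = 2000, block = 801:1200,
                          cn = 3L, noise_sd = 0.25, arm = "a") {
  pos <- seq(spacing / 2, n * spacing, by = spacing)
  mu <- rep(0, n)
  mu[block] <- if (cn == 0) -2 else log2(cn / 2)
  data.frame(arm = arm, position = pos,
             log2ratio = mu + rnorm(n, 0, noise_sd))
}

# independent d-statistic recomputation for the SAM permutation oracle
oracle_sam_d <- function(x, idx1, s0) {
  idx2 <- setdiff(seq_len(ncol(x)), idx1)
  n1 <- length(idx1); n2 <- length(idx2)
  d <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    a <- x[i, idx1]; b <- x[i, idx2]
    si <- sqrt((1 / n1 + 1 / n2) *
                 (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
                 (n1 + n2 - 2))
    d[i] <- if (si + s0 == 0) 0 else (mean(a) - mean(b)) / (si + s0)
  }
  d
}

# segments helper for filter/burden tests
seg_df <- function(sample = "s1", arm = "a", start, end, state,
                   n_markers = 100) {
  data.frame(sample = sample, arm = arm, start = start, end = end,
             state = state, n_markers = n_markers, length = end - start)
}
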