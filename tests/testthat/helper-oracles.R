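# Independent brute-force oracles used to check the package's algorithms.
# Each is written from the problem definition, not from the implementation.

# Smith-Waterman local alignment score with affine gaps
# (gap of length L costs gap_open + L * gap_extend), plain DP
sw_score_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(-Inf, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (vertical)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (horizontal)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend, Y[i, j - 1] - gap_extend)
      M[i, j] <- max(0, max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                       mat[a[i - 1], b[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# best bidirectional hits by exhaustive double loop
bbh_oracle <- function(hits, evalue_threshold = 1e-10) {
  h <- hits[hits$evalue <= evalue_threshold, , drop = FALSE]
  best_of <- function(q) {
    hq <- h[h$query_id == q, , drop = FALSE]
    if (!nrow(hq)) return(NA_character_)
    hq <- hq[order(-hq$score, hq$subject_id), , drop = FALSE]
    hq$subject_id[1]
  }
  pairs <- character()
  for (q in unique(h$query_id)) {
    s <- best_of(q)
    if (!is.na(s) && !is.na(best_of(s)) && best_of(s) == q) {
      pairs <- c(pairs, paste(min(q, s), max(q, s)))
    }
  }
  sort(unique(pairs))
}

# best split of a diagnostic-site list by exhaustive evaluation
split_oracle <- function(sites) {
  inf <- sites[order(sites$pos), , drop = FALSE]
  inf <- inf[inf$support != "matches_neither", , drop = FALSE]
  n <- nrow(inf)
  sc <- vapply(0:n, function(k) {
    before <- if (k > 0) sum(inf$support[1:k] == "matches_donor") else 0L
    after <- if (k < n) sum(inf$support[(k + 1):n] == "matches_background") else 0L
    before + after
  }, 0L)
  list(max_score = max(sc), k = which.max(sc) - 1L)
}

# longest strictly increasing subsequence length by subset enumeration
lis_oracle <- function(x) {
  n <- length(x)
  best <- 0L
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) <= best) next
    v <- x[idx]
    if (all(diff(v) > 0)) best <- length(idx)
  }
  best
}

# small, fast simulation configuration for property loops
small_sim_config <- function(seed, ...) {
  sim_config(seed = seed, n_chromosomes = 1L, chromosome_length = 36000L,
             n_genes_per_chromosome = 10L,
             n_species_specific_donor = 0L, n_species_specific_background = 0L,
             n_duplicated = 0L, introgression_gene_span = c(4L, 7L), ...)
}

suppressPackageStartupMessages(loadNamespace("vcfR"))
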