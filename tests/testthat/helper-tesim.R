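# Shared fixtures and brute-force oracles for the unit tests.

# small, fast configuration for unit-scale runs
tiny_cfg <- function(N = 30, u = 0, s = 0, r = 0, n0 = 0,
                     chrom_length = 1e6, max_generations = 20, seed = 1,
                     ...) {
  te_config(N = N, u = u, s = s, r = r, n0 = n0,
            chrom_length = chrom_length, max_generations = max_generations,
            seed = seed, ...)
}

# brute-force heterozygous-copy count: O(n^2) double loop over insertions
bf_count_het <- function(m) {
  if (nrow(m) == 0L) return(0L)
  het <- 0L
  for (i in seq_len(nrow(m))) {
    paired <- FALSE
    for (j in seq_len(nrow(m))) {
      if (i == j) next
      if (m[i, 1] == m[j, 1] && m[i, 2] == m[j, 2] && m[i, 3] != m[j, 3])
        paired <- TRUE
    }
    if (!paired) het <- het + 1L
  }
  het
}

# brute-force eligible ectopic pair count by explicit pair enumeration
bf_eligible_pairs <- function(m, M = NULL, T = Inf, suppress = FALSE) {
  if (nrow(m) < 2L) return(0L)
  ok <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    others <- setdiff(seq_len(nrow(m)), i)
    het <- !any(m[others, 1] == m[i, 1] & m[others, 2] == m[i, 2] &
                  m[others, 3] != m[i, 3])
    ok[i] <- het && (!suppress || M[i] <= T)
  }
  n_pairs <- 0L
  for (i in seq_len(nrow(m) - 1L))
    for (j in seq(i + 1L, nrow(m)))
      if (ok[i] && ok[j]) n_pairs <- n_pairs + 1L
  n_pairs
}

# random insertion matrix with optional homozygous sites
random_genome <- function(n_het, n_hom, n_chroms = 2, L = 1e4) {
  stopifnot(n_het + 2 * n_hom >= 0)
  pos <- sample.int(L, n_het + n_hom)  # distinct (chrom implicitly 0) sites
  rows <- list()
  if (n_het > 0)
    rows$het <- cbind(sample.int(n_chroms, n_het, TRUE) - 1L,
                      pos[seq_len(n_het)],
                      sample(0:1, n_het, TRUE))
  if (n_hom > 0) {
    p <- pos[n_het + seq_len(n_hom)]
    rows$hom <- rbind(cbind(0L, p, 0L), cbind(0L, p, 1L))
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

expect_within_sigma <- function(est, target, se, n_sigma = 4) {
  expect_lt(abs(est - target), n_sigma * se)
}
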