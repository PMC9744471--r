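# Independent brute-force affine-gap DP oracle (score only).
# Deliberately written as a plain triple-matrix recurrence over characters,
# sharing no code with the package's C++ aligner. Gap of length L costs
# open + L * ext (same convention as scoring_scheme()).

oracle_local_score <- function(a, b, match = 2, mismatch = -1,
                               open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, E[i, j + 1] - ext)
      F[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, F[i + 1, j] - ext)
      s <- if (av[i] == bv[j]) match else mismatch
      h <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) best <- h
    }
  }
  best
}

oracle_global_score <- function(a, b, match = 2, mismatch = -1,
                                open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e30
  H <- matrix(NEG, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  F <- matrix(NEG, n + 1, m + 1)
  H[1, 1] <- 0
  for (i in 1:n) H[i + 1, 1] <- -(open + ext * i)
  for (j in 1:m) H[1, j + 1] <- -(open + ext * j)
  for (i in 1:n) {
    for (j in 1:m) {
      E[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, E[i, j + 1] - ext)
      F[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, F[i + 1, j] - ext)
      s <- if (av[i] == bv[j]) match else mismatch
      H[i + 1, j + 1] <- max(H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
    }
  }
  H[n + 1, m + 1]
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Mutate a sequence with per-site substitution probability p (substitutions
# only) -- used to build descendant sets for consensus-recovery properties.
mutate_seq <- function(x, p) {
  v <- strsplit(x, "")[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}
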