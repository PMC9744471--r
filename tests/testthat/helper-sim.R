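# Shared small simulation fixtures, built once per test session.
# Kept deliberately small so the default suite stays fast; the acceptance
# tests build their own, larger worlds.

small_family <- function() family_model(seed = 1L)

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fam <- small_family()
      cfg <- simulation_config(
        chrom_lengths = c(chr1A = 8e5, chr1B = 8e5, chr1D = 4e5),
        decoy_count = 5L, seed = 7L)
      cache <<- simulate_te_genome(fam, default_subfamilies(copy_count = 15L),
                                   cfg)
    }
    cache
  }
})

# match a set of calls against truth rows by chrom + boundary tolerance
match_truth <- function(calls, truth, tol = 2L) {
  vapply(seq_len(nrow(truth)), function(i) {
    any(calls$chrom == truth$chrom[i] &
          abs(calls$start - truth$start[i]) <= tol &
          abs(calls$end - truth$end[i]) <= tol)
  }, logical(1))
}
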