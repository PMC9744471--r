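test_that("scan_hits finds exact and mutated planted LTRs and rejects junk", {
  set.seed(4)
  bg <- make_background(c(chrA = 6e4), gc = 0.5, seed = 4)
  ltr <- small_family()$ltr
  L <- nchar(ltr)
  # plant: exact copy, 5% mutated copy, 25% mutated copy, 90%-truncated copy
  mut5 <- mutate_seq(ltr, 0.05)
  mut25 <- mutate_seq(ltr, 0.25)
  trunc90 <- substring(ltr, 1, floor(0.9 * L))
  g <- paste0(substring(bg[[1]], 1, 5000), ltr,
              substring(bg[[1]], 5001, 20000), mut5,
              substring(bg[[1]], 20001, 35000), mut25,
              substring(bg[[1]], 35001, 50000), trunc90,
              substring(bg[[1]], 50001, 60000))
  genome <- c(chrA = g)
  hits <- scan_hits(genome, c(cons1 = ltr))
  # exact copy: identity 1, coverage 1, exact span
  exact <- dplyr::filter(hits, abs(start - 5000) < 3)
  expect_equal(nrow(exact), 1L)
  expect_equal(exact$identity_fraction, 1)
  expect_equal(exact$consensus_coverage, 1)
  expect_equal(exact$start, 5000)
  expect_equal(exact$end, 5000 + L)
  # 5% mutated copy found
  expect_equal(sum(abs(hits$start - (20000 + L)) < 20), 1L)
  # 25% mutated copy below the 80% identity threshold: absent
  expect_equal(sum(abs(hits$start - (35000 + 2 * L)) < 20), 0L)
  # truncated copy below 95% coverage: absent
  expect_false(any(hits$start > 40000))

  # minus-strand detection with consensus-frame missing bp
  g2 <- paste0(substring(bg[[1]], 1, 5000), revcomp(ltr),
               substring(bg[[1]], 5001, 20000))
  h2 <- scan_hits(c(chrA = g2), c(cons1 = ltr))
  expect_equal(h2$strand, "-")
  expect_equal(h2$start, 5000)
})

test_that("completeness filter applies the 5 bp rule on both sides", {
  hits <- tibble::tibble(chrom = "c", start = 1:4, end = 2:5, strand = "+",
                         consensus_id = "x", identity_fraction = 1,
                         consensus_coverage = 0.99,
                         missing_5prime_bp = c(0L, 6L, 5L, 2L),
                         missing_3prime_bp = c(0L, 0L, 5L, 6L), score = 1)
  kept <- completeness_filter(hits)
  expect_equal(kept$start, c(1L, 3L))  # 0/0 and boundary 5/5 retained
})

test_that("pair_ltrs pairs by distance window with the greedy rule", {
  mk_hit <- function(start, end, strand = "+") {
    tibble::tibble(chrom = "c", start = start, end = end, strand = strand,
                   consensus_id = "x", identity_fraction = 0.95,
                   consensus_coverage = 1, missing_5prime_bp = 0L,
                   missing_3prime_bp = 0L, score = 100)
  }
  w <- c(7700, 9700)
  # outer span 8000: paired
  pr <- pair_ltrs(dplyr::bind_rows(mk_hit(0, 500), mk_hit(7500, 8000)), w)
  expect_equal(nrow(pr$candidates), 1L)
  expect_equal(pr$candidates$end - pr$candidates$start, 8000)
  # outer span 5000: not paired
  pr2 <- pair_ltrs(dplyr::bind_rows(mk_hit(0, 500), mk_hit(4500, 5000)), w)
  expect_equal(nrow(pr2$candidates), 0L)
  expect_equal(nrow(pr2$leftover), 2L)
  # triplet A,B,C with A-B and B-C admissible: A-B paired, C leftover
  pr3 <- pair_ltrs(dplyr::bind_rows(mk_hit(0, 500), mk_hit(7500, 8000),
                                    mk_hit(15000, 15500)), w)
  expect_equal(nrow(pr3$candidates), 1L)
  expect_equal(pr3$candidates$start, 0)
  expect_equal(pr3$leftover$start, 15000)
  # strand mismatch never pairs
  pr4 <- pair_ltrs(dplyr::bind_rows(mk_hit(0, 500), mk_hit(7500, 8000, "-")), w)
  expect_equal(nrow(pr4$candidates), 0L)
})

test_that("size trimming flags ceil(3%) per tail deterministically", {
  mk <- function(n, lens) {
    tibble::tibble(chrom = "c", start = seq_len(n) * 10000,
                   end = seq_len(n) * 10000 + lens, strand = "+")
  }
  cand <- mk(100, c(seq(5000, 5990, by = 10)))
  out <- trim_size_distribution(cand)
  expect_equal(sum(out$size_trimmed), 6L)  # 3 shortest + 3 longest
  expect_true(all(out$size_trimmed[c(1:3, 98:100)]))
  # ceiling rule at n = 10
  out10 <- trim_size_distribution(mk(10, seq(5000, 5900, by = 100)))
  expect_equal(sum(out10$size_trimmed), 2L)
  # all same length: deterministic across calls
  same <- mk(50, rep(6000, 50))
  expect_identical(trim_size_distribution(same)$size_trimmed,
                   trim_size_distribution(same)$size_trimmed)
})

test_that("TSD detection applies the 2-mismatch rule with jitter", {
  set.seed(31)
  core <- random_dna(300)
  pad_l <- random_dna(50)
  pad_r <- random_dna(50)
  mk_genome <- function(left, right) {
    g <- paste0(pad_l, left, core, right, pad_r)
    list(genome = c(chr = g), start = 50 + 5, end = 50 + 5 + 300)
  }
  g1 <- mk_genome("AACGT", "AACGT")
  t1 <- detect_tsd(g1$genome, "chr", g1$start, g1$end)
  expect_true(t1$tsd_ok)
  expect_equal(t1$tsd_mismatches, 0L)

  g2 <- mk_genome("AACGT", "AAGGT")
  t2 <- detect_tsd(g2$genome, "chr", g2$start, g2$end)
  expect_true(t2$tsd_ok)
  expect_equal(t2$tsd_mismatches, 1L)

  g3 <- mk_genome("AACGT", "GGGGT")
  t3 <- detect_tsd(g3$genome, "chr", g3$start, g3$end)
  expect_false(t3$tsd_ok)
  expect_gte(t3$tsd_mismatches, 3L)

  # boundary jitter: same TSD but boundaries reported 2 bp shifted
  t4 <- detect_tsd(g1$genome, "chr", g1$start + 2, g1$end + 2)
  expect_true(t4$tsd_ok)
  expect_equal(t4$tsd_mismatches, 0L)

  # contig edge: not assessable
  t5 <- detect_tsd(c(chr = "ACGTACGTACGT"), "chr", 2, 10)
  expect_true(is.na(t5$tsd_ok))
})

test_that("consensus building recovers planted variant groups", {
  set.seed(8)
  fam <- small_family()
  anc1 <- fam$ltr
  anc2 <- mutate_seq(anc1, 0.15)  # ~85% identity between groups
  ex <- c(setNames(vapply(1:6, function(i) mutate_seq(anc1, 0.02),
                          character(1)), paste0("g1_", 1:6)),
          setNames(vapply(1:6, function(i) mutate_seq(anc2, 0.02),
                          character(1)), paste0("g2_", 1:6)))
  cons <- build_ltr_consensuses(ex, identity_threshold = 0.90)
  expect_equal(length(cons), 2L)
  ids <- vapply(cons, function(cs) {
    max(local_align(cs, anc1)$identity_fraction,
        local_align(cs, anc2)$identity_fraction)
  }, numeric(1))
  expect_true(all(ids >= 0.99))

  # identical examples: one consensus equal to them
  same <- setNames(rep(anc1, 12), paste0("s", 1:12))
  cs <- build_ltr_consensuses(same)
  expect_equal(length(cs), 1L)
  expect_equal(unname(cs[[1]]), anc1)

  # < 10 examples warns and yields a single consensus
  expect_warning(build_ltr_consensuses(same[1:4]), "fewer than 10")
})

test_that("discovery recovers the planted population on the small world", {
  sim <- small_sim()
  fam <- sim$family
  cons <- vapply(sim$lineages, `[[`, character(1), "ltr")
  ann <- discover_elements(sim$genome, cons, fam$polyprotein,
                           fam$distance_window, family = fam$family_name)
  tr_fl <- dplyr::filter(sim$truth, feature_type == "full_length")
  calls <- dplyr::filter(ann$elements, retained)
  recall <- mean(match_truth(calls, tr_fl))
  precision <- mean(vapply(seq_len(nrow(calls)), function(i) {
    any(tr_fl$chrom == calls$chrom[i] &
          abs(tr_fl$start - calls$start[i]) <= 2 &
          abs(tr_fl$end - calls$end[i]) <= 2)
  }, logical(1)))
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)

  # solo-LTRs: planted ones recovered, decoys end up unclassified
  tr_solo <- dplyr::filter(sim$truth, feature_type == "solo_ltr")
  solo_recall <- mean(match_truth(ann$solo_ltrs, tr_solo))
  expect_gte(solo_recall, 0.9)
  tr_decoy <- dplyr::filter(sim$truth, feature_type == "decoy_fragment")
  expect_false(any(match_truth(ann$solo_ltrs, tr_decoy)))

  # retained elements never overlap on the same strand
  el <- dplyr::arrange(calls, chrom, start)
  if (nrow(el) > 1) {
    same <- el$chrom[-1] == el$chrom[-nrow(el)] &
      el$strand[-1] == el$strand[-nrow(el)]
    expect_true(all(el$start[-1][same] >= el$end[-nrow(el)][same]))
  }
})

test_that("annotation GFF3 round-trips losslessly", {
  sim <- small_sim()
  cons <- vapply(sim$lineages, `[[`, character(1), "ltr")
  ann <- discover_elements(sim$genome, cons, sim$family$polyprotein,
                           sim$family$distance_window)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation_gff3(ann, path)
  back <- read_annotation_gff3(path)
  el <- dplyr::filter(back, type == "LTR_retrotransposon")
  expect_setequal(paste(el$chrom, el$start, el$end, el$strand),
                  paste(ann$elements$chrom, ann$elements$start,
                        ann$elements$end, ann$elements$strand))
  sl <- dplyr::filter(back, type == "solo_LTR")
  expect_setequal(paste(sl$chrom, sl$start, sl$end),
                  paste(ann$solo_ltrs$chrom, ann$solo_ltrs$start,
                        ann$solo_ltrs$end))
})
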