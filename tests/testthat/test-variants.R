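# A constructed toy population: 20 copies of a 60-bp consensus with planted
# substitutions, one deletion copy, to exercise the MAF and missingness rules
# integer-exactly.
make_toy <- function() {
  set.seed(6)
  cons <- random_dna(150)
  v <- strsplit(cons, "")[[1]]
  swap <- function(b) c(A = "G", G = "A", C = "T", T = "C")[[b]]
  copies <- list()
  for (i in 1:20) copies[[i]] <- v
  # site 10: 8/20 copies carry an alternate (MAF 0.40)
  for (i in 1:8) copies[[i]][10] <- swap(v[10])
  # site 20: 4/20 copies (MAF 0.20)
  for (i in 5:8) copies[[i]][20] <- swap(v[20])
  # site 30: 1/20 copies (MAF 0.05, below threshold)
  copies[[3]][30] <- swap(v[30])
  # site 40: triallelic, 6 + 4 alternates (MAF 1 - 10/20 = 0.5)
  for (i in 1:6) copies[[i]][40] <- swap(v[40])
  for (i in 7:10) copies[[i]][40] <- setdiff(c("A", "C", "G", "T"),
                                             c(v[40], swap(v[40])))[1]
  # site 50: 5/20 copies (MAF 0.25)
  for (i in 11:15) copies[[i]][50] <- swap(v[50])
  seqs <- vapply(copies, paste, character(1), collapse = "")
  # copy 20 has a 9-bp deletion spanning site 50 (45..53 removed)
  seqs[20] <- paste0(substring(seqs[20], 1, 44), substring(seqs[20], 54, 150))
  names(seqs) <- sprintf("copy%02d", 1:20)
  list(cons = cons, seqs = seqs, v = v, swap = swap)
}

test_that("copy-to-consensus alignment handles deletions and coverage", {
  toy <- make_toy()
  alns <- align_copies_to_consensus(toy$seqs, toy$cons,
                                    scheme = scoring_scheme(2, -1, 50, 0.1),
                                    band = 0)
  expect_equal(length(alns), 20L)
  expect_equal(attr(alns, "excluded"), character(0))
  # identical copy: full coverage, zero mismatches
  al16 <- alns[["copy16"]]
  expect_equal(al16$subject_coverage, 1)
  expect_equal(al16$identity_fraction, 1)
  # deletion copy: subject span still covers the whole consensus
  al20 <- alns[["copy20"]]
  expect_true(grepl("-", al20$aligned_query))

  # a copy covering <50% of the consensus is excluded with a log entry
  short <- c(toy$seqs, frag = substring(toy$cons, 1, 50))
  alns2 <- suppressWarnings(align_copies_to_consensus(
    short, toy$cons, scheme = scoring_scheme(2, -1, 50, 0.1), band = 0))
  expect_true("frag" %in% attr(alns2, "excluded"))
})

test_that("MAF and missingness filters retain exactly the qualifying sites", {
  toy <- make_toy()
  alns <- align_copies_to_consensus(toy$seqs, toy$cons,
                                    scheme = scoring_scheme(2, -1, 50, 0.1),
                                    band = 0)
  vm <- build_matrix(alns)
  # sites 10, 20, 40, 50 qualify (MAF .40/.20/.50/.25); site 30 (5%) does not
  expect_setequal(vm$positions, c(10L, 20L, 40L, 50L))
  expect_equal(vm$ref, toy$v[vm$positions])
  # genotype codes match the planting
  g10 <- vm$geno[, "10"]
  expect_equal(unname(g10[sprintf("copy%02d", 1:8)]), rep(1L, 8))
  expect_equal(unname(g10[sprintf("copy%02d", 9:19)]), rep(0L, 11))
  # triallelic site 40: codes 1 (6 copies) and 2 (4 copies)
  g40 <- vm$geno[, "40"]
  expect_equal(sum(g40 == 1L, na.rm = TRUE), 6L)
  expect_equal(sum(g40 == 2L, na.rm = TRUE), 4L)
  # deletion: copy20 missing at site 50
  expect_true(is.na(vm$geno["copy20", "50"]))
  # MAF at site 50 uses the non-missing denominator: 5/19
  expect_equal(vm$maf[vm$positions == 50], 5 / 19)

  # missingness rule: drop a site with > 90% missing
  # (constructed directly: 19 of 20 copies missing -> 95%)
  al_sub <- alns
  for (id in names(al_sub)[1:19]) {
    a <- al_sub[[id]]
    # truncate the alignment to consensus positions 1..40
    qv <- strsplit(a$aligned_query, "")[[1]]
    sv <- strsplit(a$aligned_subject, "")[[1]]
    keep <- cumsum(sv != "-") <= 40
    a$aligned_query <- paste(qv[keep], collapse = "")
    a$aligned_subject <- paste(sv[keep], collapse = "")
    a$subject_span <- c(0, 40)
    al_sub[[id]] <- a
  }
  vm2 <- build_matrix(al_sub)
  expect_false(50 %in% vm2$positions)   # 95% missing > 90%
  expect_true(all(vm2$positions <= 40))

  # site count invariant to copy input order
  vm3 <- build_matrix(alns[rev(names(alns))])
  expect_setequal(vm3$positions, vm$positions)
})

test_that("MAF threshold boundary: exactly 10% passes, below fails", {
  set.seed(9)
  cons <- random_dna(40)
  v <- strsplit(cons, "")[[1]]
  seqs <- vapply(1:20, function(i) {
    w <- v
    if (i <= 2) w[5] <- c(A = "G", G = "A", C = "T", T = "C")[[w[5]]]  # 2/20
    if (i <= 1) w[15] <- c(A = "C", G = "C", C = "A", T = "A")[[w[15]]] # 1/20
    paste(w, collapse = "")
  }, character(1))
  names(seqs) <- paste0("c", 1:20)
  alns <- align_copies_to_consensus(seqs, cons, band = 0)
  vm <- build_matrix(alns)
  expect_true(5 %in% vm$positions)    # MAF 0.10 >= 0.10
  expect_false(15 %in% vm$positions)  # MAF 0.05 < 0.10
})

test_that("VCF round-trip is lossless and haploid", {
  toy <- make_toy()
  alns <- align_copies_to_consensus(toy$seqs, toy$cons, band = 0)
  ages <- setNames(seq(1e5, 2e6, length.out = 20), names(toy$seqs))
  vm <- build_matrix(alns, ages = ages)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(vm, path, family_name = "RLC_toy")

  txt <- readLines(path)
  gt_fields <- vapply(strsplit(txt[!startsWith(txt, "#")], "\t"),
                      function(f) paste(f[-(1:9)], collapse = ""),
                      character(1))
  expect_false(any(grepl("[/|]", gt_fields)))  # haploid GT only

  back <- read_vcf(path)
  expect_identical(back$copy_ids, vm$copy_ids)
  expect_identical(back$positions, vm$positions)
  expect_identical(back$ref, vm$ref)
  expect_identical(back$alt, vm$alt)
  expect_identical(unname(back$geno), unname(vm$geno))
  expect_equal(unname(back$ages), unname(vm$ages))
  expect_equal(back$maf, vm$maf, tolerance = 1e-6)

  # independent parser agrees on the basics
  skip_if_not_installed("VariantAnnotation")
  v2 <- VariantAnnotation::readVcf(path)
  expect_equal(as.integer(GenomicRanges::start(v2)), vm$positions)
  expect_equal(as.character(VariantAnnotation::ref(v2)), vm$ref)

  # empty matrix (monomorphic copy subset): header-only VCF
  empty <- suppressWarnings(build_matrix(alns[sprintf("copy%02d", 16:19)]))
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(empty, p2)
  expect_true(all(startsWith(readLines(p2), "#")))
})

test_that("copy identity falls with age on simulated populations", {
  sim <- small_sim()
  fam <- sim$family
  cons <- vapply(sim$lineages, `[[`, character(1), "ltr")
  ann <- discover_elements(sim$genome, cons, fam$polyprotein,
                           fam$distance_window)
  el <- element_sequences(sim$genome, dplyr::filter(ann$elements, retained))
  tr <- dplyr::filter(sim$truth, feature_type == "full_length")
  key <- paste(el$chrom, el$start)
  tkey <- paste(tr$chrom, tr$start)
  ages <- tr$true_age_years[match(key, tkey)]
  keep <- !is.na(ages)
  alns <- align_copies_to_consensus(
    setNames(el$element_seq, el$element_id)[keep],
    paste0(fam$ltr, fam$internal, fam$ltr))
  idf <- vapply(alns, `[[`, numeric(1), "identity_fraction")
  rho <- stats::cor(ages[keep][match(names(alns), el$element_id[keep])], idf,
                    method = "spearman")
  expect_lt(rho, -0.8)
})
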