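test_that("K2P insertion dating matches the closed form", {
  # identical LTRs: age exactly 0
  set.seed(1)
  ltr <- random_dna(1000)
  d0 <- date_insertion(ltr, ltr)
  expect_equal(d0$age_years, 0)
  expect_true(d0$identical_ltrs)

  # constructed 1000-site alignment with 10 transitions and 5 transversions:
  # K = -0.5*ln((1-2P-Q)*sqrt(1-2Q)) = 0.01517149, age = K/(2*1.3e-8)
  v <- strsplit(ltr, "")[[1]]
  w <- v
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "C", C = "A", T = "A")
  ts_sites <- sample(1000, 10)
  tv_sites <- sample(setdiff(1:1000, ts_sites), 5)
  for (s in ts_sites) w[s] <- ts_map[[w[s]]]
  for (s in tv_sites) w[s] <- tv_map[[w[s]]]
  d <- date_insertion(ltr, paste(w, collapse = ""))
  expect_equal(d$transitions, 10L)
  expect_equal(d$transversions, 5L)
  expect_equal(d$K, 0.01517149, tolerance = 1e-6)
  expect_equal(d$age_years, 583518.8, tolerance = 1e-6)

  # K2P monotone in P and Q in the valid domain
  expect_true(k2p_distance(0.02, 0.01) > k2p_distance(0.01, 0.01))
  expect_true(k2p_distance(0.01, 0.02) > k2p_distance(0.01, 0.01))

  # saturated correction domain: no finite distance
  expect_true(is.na(k2p_distance(0.4, 0.25)))  # 1 - 2P - Q <= 0
  expect_true(is.na(k2p_distance(0.1, 0.5)))   # 1 - 2Q <= 0

  # alignment covering <50% of the shorter LTR: undatable
  set.seed(2)
  shared <- random_dna(100)
  ltr5 <- paste0(shared, paste(rep("A", 300), collapse = ""))
  ltr3 <- paste0(shared, paste(rep("C", 300), collapse = ""))
  dud <- date_insertion(ltr5, ltr3)
  expect_equal(dud$status, "undatable")
})

test_that("simulated LTR pairs recover their true ages across strata", {
  fam <- small_family()
  r <- 1.3e-8
  set.seed(17)
  strata <- c(0.25e6, 0.5e6, 1e6, 2e6)
  for (t in strata) {
    est <- replicate(60, {
      l5 <- mutate_k2p(fam$ltr, r * t, 2)
      l3 <- mutate_k2p(fam$ltr, r * t, 2)
      date_insertion(l5, l3)$age_years
    })
    expect_lt(abs(mean(est) - t) / t, 0.10)
  }
})

test_that("K2P and Jukes-Cantor agree for kappa = 1 simulations", {
  set.seed(23)
  anc <- random_dna(5000)
  d_k2p <- c(); d_jc <- c()
  for (i in 1:20) {
    a <- mutate_k2p(anc, 0.02, kappa = 1)
    b <- mutate_k2p(anc, 0.02, kappa = 1)
    est <- date_insertion(a, b)
    d_k2p <- c(d_k2p, est$K)
    p <- (est$transitions + est$transversions) / est$aligned_sites
    d_jc <- c(d_jc, -3 / 4 * log(1 - 4 / 3 * p))
  }
  expect_lt(abs(mean(d_k2p) - mean(d_jc)) / mean(d_jc), 0.02)
})

test_that("CDS extraction counts in-frame stops and flags frameshifts", {
  fam <- small_family()
  cds <- substring(fam$internal, fam$cds_start + 1,
                   fam$cds_start + fam$cds_length)

  r0 <- extract_cds(fam$internal, cds)
  expect_equal(r0$stop_count, 0L)
  expect_false(r0$frameshift)
  expect_equal(r0$consensus_span, c(0, nchar(cds)))

  # one planted in-frame TAA
  v <- strsplit(fam$internal, "")[[1]]
  v[fam$cds_start + 30 * 3 + 1:3] <- c("T", "A", "A")
  r1 <- extract_cds(paste(v, collapse = ""), cds)
  expect_equal(r1$stop_count, 1L)

  # 1-bp deletion -> frameshift flag
  fs <- paste0(substring(fam$internal, 1, fam$cds_start + 100),
               substring(fam$internal, fam$cds_start + 102,
                         nchar(fam$internal)))
  r2 <- extract_cds(fs, cds)
  expect_true(r2$frameshift)

  # 3-bp deletion: no frameshift
  del3 <- paste0(substring(fam$internal, 1, fam$cds_start + 99),
                 substring(fam$internal, fam$cds_start + 103,
                           nchar(fam$internal)))
  expect_false(extract_cds(del3, cds)$frameshift)

  # random sequence: no CDS
  set.seed(3)
  expect_null(extract_cds(random_dna(500), cds))
})

test_that("planted Poisson stop counts are recovered by extraction", {
  fam <- small_family()
  cds <- substring(fam$internal, fam$cds_start + 1,
                   fam$cds_start + fam$cds_length)
  cfg <- simulation_config(chrom_lengths = c(chr1A = 3e6), seed = 31)
  specs <- list(subfamily_spec("s", 1e6, 5e5, 2e5, c(A = 1),
                               copy_count = 120L, doa_lambda = 0.5))
  sim <- simulate_te_genome(fam, specs, cfg)
  tr <- dplyr::filter(sim$truth, feature_type == "full_length")
  # measure stops from the genome sequence via extract_cds
  est <- vapply(seq_len(nrow(tr)), function(i) {
    el <- substring(sim$genome[[tr$chrom[i]]], tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") el <- revcomp(el)
    extract_cds(el, cds, band = 2000L)$stop_count
  }, numeric(1))
  # extraction agrees with the simulator's own records
  expect_gte(mean(est == tr$stop_count), 0.95)
  # and the mean is within 2 s.e. of the planted truth
  expect_lt(abs(mean(est) - mean(tr$stop_count)),
            2 * sd(tr$stop_count) / sqrt(nrow(tr)) + 1e-9)
})

test_that("four-fold site rules follow the codon eligibility table", {
  fam <- small_family()
  cds <- substring(fam$internal, fam$cds_start + 1,
                   fam$cds_start + fam$cds_length)
  # identical pair: zero divergence
  copies <- c(a = fam$internal, b = fam$internal)
  de <- fourfold_divergence_pairs(copies, copies, cds, n_pairs = 1, seed = 1)
  expect_equal(de$pairs$distance, 0)
  expect_equal(de$pairs$years, 0)

  # GCA|GCG (Ala) eligible and counted; TTA|TTG (Leu, non-CT) ineligible
  base <- paste(rep("GAAGAT", 60), collapse = "")  # E/D filler, ineligible
  mk <- function(codon) paste0("ATG", codon, base)
  d1 <- fourfold_divergence_pairs(c(x = mk("GCA"), x2 = mk("GCA")),
                                  c(y = mk("GCG"), y2 = mk("GCG")),
                                  mk("GCA"), n_pairs = 1, seed = 1)
  expect_equal(d1$pairs$sites_used, 1L)
  expect_equal(d1$pairs$distance, 1)
  expect_error(
    fourfold_divergence_pairs(c(x = mk("TTA"), x2 = mk("TTA")),
                              c(y = mk("TTG"), y2 = mk("TTG")),
                              mk("TTA"), n_pairs = 1, seed = 1),
    "eligible")

  # estimator is symmetric under group swap (same seed and pairing)
  set.seed(41)
  ca <- setNames(vapply(1:4, function(i) mutate_k2p(fam$internal, 0.01),
                        character(1)), paste0("a", 1:4))
  cb <- setNames(vapply(1:4, function(i) mutate_k2p(fam$internal, 0.01),
                        character(1)), paste0("b", 1:4))
  dab <- fourfold_divergence_pairs(ca, cb, cds, n_pairs = 16, seed = 2)
  dba <- fourfold_divergence_pairs(cb, ca, cds, n_pairs = 16, seed = 2)
  expect_setequal(round(dab$pairs$distance, 10), round(dba$pairs$distance, 10))
  expect_equal(dab$mode_years, dba$mode_years)
})

test_that("near-intact selection excludes frameshifted and stop-rich copies", {
  fam <- small_family()
  cds <- substring(fam$internal, fam$cds_start + 1,
                   fam$cds_start + fam$cds_length)
  good <- fam$internal
  v <- strsplit(fam$internal, "")[[1]]
  for (k in 1:5) v[fam$cds_start + (10 * k) * 3 + 1:3] <- c("T", "A", "A")
  stopy <- paste(v, collapse = "")  # 5 stops > max 3
  fs <- paste0(substring(good, 1, fam$cds_start + 100),
               substring(good, fam$cds_start + 102, nchar(good)))
  de <- fourfold_divergence_pairs(
    c(g1 = good, g2 = good, s = stopy, f = fs),
    c(h1 = good, h2 = good), cds, n_pairs = 10, seed = 1)
  expect_equal(de$eligible_a, 2L)  # stop-rich and frameshifted excluded
})

test_that("dead-on-arrival regression recovers intercept and slope", {
  # exactly collinear points: closed form to machine precision
  x <- seq(0, 2e6, length.out = 50)
  y <- 0.3 + 1e-6 * x
  fit <- doa_regression(x, y)
  expect_equal(fit$intercept, 0.3, tolerance = 1e-10)
  expect_equal(fit$slope, 1e-6, tolerance = 1e-12)

  # noisy Poisson counts, true intercept 0.3 (n chosen so the OLS standard
  # error of the intercept is ~0.04, well inside the 0.1 band)
  set.seed(77)
  age <- runif(1500, 0, 2e6)
  stops <- rpois(1500, 0.3 + 4e-7 * age)
  fit2 <- doa_regression(age, stops)
  expect_lt(abs(fit2$intercept - 0.3), 0.1)
  expect_equal(fit2$doa_fraction, 1 - exp(-fit2$intercept))

  expect_error(doa_regression(rep(1e5, 20), rpois(20, 1)), "degenerate")
  expect_error(doa_regression(1:5, 1:5), "at least 10")
})
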