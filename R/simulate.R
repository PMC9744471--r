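#' Define a retrotransposon family model for simulation
#'
#' Generates a random ancestral element: an LTR starting with `TG` and ending
#' in `CA`, and an internal region carrying a primer-binding-site motif just
#' downstream of the 5' LTR and a stop-free open reading frame encoding a
#' random polyprotein. The expected outer distance between the two LTR starts
#' of a full-length copy is bracketed by `distance_window`.
#'
#' @param family_name Family label.
#' @param ltr_length LTR length in bp (>= 100).
#' @param internal_length Internal-region length in bp.
#' @param polyprotein_length Polyprotein length in amino acids; its CDS
#'   (3x this) must fit in the internal region.
#' @param pbs_motif Primer-binding-site motif placed right after the 5' LTR.
#' @param distance_window Numeric length-2 vector bracketing the expected
#'   element outer length; defaults to total length +/- 1000 bp.
#' @param seed Integer seed for the random ancestor.
#' @return A `family_model` list with the ancestral `ltr`, `internal`,
#'   `polyprotein` and CDS coordinates (`cds_start`, 0-based offset within
#'   the internal region).
#' @export
family_model <- function(family_name = "RLC_sim", ltr_length = 800,
                         internal_length = 4000, polyprotein_length = 1100,
                         pbs_motif = "TGGTATCAGAGC",
                         distance_window = NULL, seed = 1L) {
  stopifnot(ltr_length >= 100)
  cds_len <- 3L * polyprotein_length
  lead <- nchar(pbs_motif) + 20L
  if (lead + cds_len > internal_length) {
    abort("internal_length too small for the polyprotein CDS")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    code
  }
  out <- withr_seed({
    aa_pool <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], character(0))
    polyprotein <- paste(c("M", sample(aa_pool, polyprotein_length - 1L,
                                       replace = TRUE)), collapse = "")
    cds <- back_translate(polyprotein)
    filler_len <- internal_length - lead - cds_len
    internal <- paste0(pbs_motif, rand_dna(20L), cds, rand_dna(filler_len))
    ltr <- paste0("TG", rand_dna(ltr_length - 4L), "CA")
    list(ltr = ltr, internal = internal, polyprotein = polyprotein)
  })
  total <- 2L * ltr_length + internal_length
  if (is.null(distance_window)) distance_window <- c(total - 1000, total + 1000)
  structure(list(
    family_name = family_name, ltr = out$ltr, internal = out$internal,
    polyprotein = out$polyprotein, ltr_length = ltr_length,
    internal_length = internal_length, cds_start = lead,
    cds_length = cds_len, pbs_motif = pbs_motif,
    distance_window = distance_window, seed = seed
  ), class = "family_model")
}

#' @keywords internal
#' @noRd
rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @keywords internal
#' @noRd
back_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  aa_v <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(aa_v, function(x) {
    opts <- names(gc)[gc == x]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Sub-family specification for the simulator
#'
#' @param name Sub-family label.
#' @param lineage_divergence_years Age of the split of this sub-family's
#'   consensus from the family ancestor.
#' @param activity_mean_years,activity_sd_years Normal insertion-age
#'   distribution (truncated at 0).
#' @param subgenome_weights Named numeric vector of sub-genome proportions
#'   (must sum to 1).
#' @param copy_count Number of planted insertions (full-length plus
#'   solo-LTR conversions).
#' @param doa_lambda Expected in-frame stop codons injected at insertion
#'   (Poisson), modelling dead-on-arrival copies.
#' @param solo_fraction Fraction of copies reduced to a solo-LTR; applied as
#'   an exact count `round(solo_fraction * copy_count)` so planted totals are
#'   reproducible.
#' @return A `subfamily_spec` list.
#' @export
subfamily_spec <- function(name, lineage_divergence_years = 2e6,
                           activity_mean_years = 1e6,
                           activity_sd_years = 3e5,
                           subgenome_weights = c(A = 1 / 3, B = 1 / 3, D = 1 / 3),
                           copy_count = 50L, doa_lambda = 0.3,
                           solo_fraction = 0) {
  stopifnot(abs(sum(subgenome_weights) - 1) < 1e-6,
            lineage_divergence_years >= 0, activity_mean_years >= 0,
            copy_count >= 0, solo_fraction >= 0, solo_fraction <= 1)
  structure(list(name = name,
                 lineage_divergence_years = lineage_divergence_years,
                 activity_mean_years = activity_mean_years,
                 activity_sd_years = activity_sd_years,
                 subgenome_weights = subgenome_weights,
                 copy_count = as.integer(copy_count),
                 doa_lambda = doa_lambda, solo_fraction = solo_fraction),
            class = "subfamily_spec")
}

#' Simulation configuration
#'
#' @param chrom_lengths Named integer vector of chromosome lengths; names
#'   like `chr1A` carry the sub-genome in their last character unless
#'   `subgenomes` is given.
#' @param subgenomes Optional named character vector chromosome -> sub-genome.
#' @param rate Substitution rate per site per year (default 1.3e-8, the
#'   grass intergenic clock used throughout).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param tsd_length Target-site-duplication length in bp (default 5).
#' @param tsd_mismatch_prob Per-base corruption probability of the 3' TSD
#'   copy.
#' @param gc GC content of the random background.
#' @param indel_rate Expected small (1-3 bp) indels per copy's internal
#'   region.
#' @param decoy_count Number of partial-LTR decoy fragments planted without
#'   TSDs to exercise false-positive filtering.
#' @param introgressions Tibble with columns `chrom`, `start`, `end`,
#'   `subfamily`, `copies`: intervals whose planted copies are forced to the
#'   given sub-family mix.
#' @param seed Mandatory integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(chrom_lengths = c(chr1A = 2e6, chr1B = 2e6,
                                                chr1D = 1e6),
                              subgenomes = NULL, rate = 1.3e-8, kappa = 2,
                              tsd_length = 5L, tsd_mismatch_prob = 0.05,
                              gc = 0.46, indel_rate = 0.3, decoy_count = 0L,
                              introgressions = NULL, seed = 1L) {
  stopifnot(rate > 0, kappa > 0, all(chrom_lengths > 0))
  if (is.null(subgenomes)) {
    subgenomes <- setNames(substr(names(chrom_lengths),
                                  nchar(names(chrom_lengths)),
                                  nchar(names(chrom_lengths))),
                           names(chrom_lengths))
  }
  if (!is.null(introgressions)) {
    stopifnot(all(c("chrom", "start", "end", "subfamily", "copies") %in%
                    names(introgressions)))
    stopifnot(all(introgressions$chrom %in% names(chrom_lengths)))
    stopifnot(all(introgressions$end <=
                    chrom_lengths[introgressions$chrom]))
  }
  structure(list(chrom_lengths = chrom_lengths, subgenomes = subgenomes,
                 rate = rate, kappa = kappa, tsd_length = as.integer(tsd_length),
                 tsd_mismatch_prob = tsd_mismatch_prob, gc = gc,
                 indel_rate = indel_rate, decoy_count = as.integer(decoy_count),
                 introgressions = introgressions, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Kimura two-parameter substitution process on a sequence
#'
#' Applies `Poisson(mu * length)` substitution events; each event is a
#' transition with probability `kappa / (kappa + 2)` and otherwise one of the
#' two possible transversions, which is exactly the embedded chain of the
#' K2P model with expected substitutions per site `mu`.
#'
#' @param x Nucleotide string.
#' @param mu Expected substitutions per site.
#' @param kappa Transition/transversion rate ratio.
#' @return Mutated string.
#' @export
mutate_k2p <- function(x, mu, kappa = 2) {
  v <- strsplit(x, "", fixed = TRUE)[[1]]
  L <- length(v)
  n_ev <- rpois(1L, mu * L)
  if (n_ev == 0L) return(x)
  sites <- sample.int(L, n_ev, replace = TRUE)
  transition <- runif(n_ev) < kappa / (kappa + 2)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  for (e in seq_len(n_ev)) {
    b <- v[sites[e]]
    if (!b %in% c("A", "C", "G", "T")) next
    v[sites[e]] <- if (transition[e]) ts_map[[b]] else
      tv_map[[b]][sample.int(2L, 1L)]
  }
  paste(v, collapse = "")
}

#' @keywords internal
#' @noRd
count_inframe_stops <- function(internal, cds_start, cds_length) {
  cds <- substring(internal, cds_start + 1L, cds_start + cds_length)
  aa <- translate_dna(cds)
  sum(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
}

# mutate internal region but keep the CDS stop-free (lineage consensuses stay
# coding-competent; stops arise only per copy)
#' @keywords internal
#' @noRd
mutate_internal_nostop <- function(internal, mu, kappa, cds_start, cds_length) {
  anc <- strsplit(internal, "", fixed = TRUE)[[1]]
  for (tries in 1:20) {
    mut <- mutate_k2p(internal, mu, kappa)
    if (count_inframe_stops(mut, cds_start, cds_length) == 0L) return(mut)
    # revert the codons that became stops
    v <- strsplit(mut, "", fixed = TRUE)[[1]]
    aa <- translate_dna(substring(mut, cds_start + 1L, cds_start + cds_length))
    stops <- which(strsplit(aa, "", fixed = TRUE)[[1]] == "*")
    for (s in stops) {
      idx <- cds_start + (s - 1L) * 3L + 1:3
      v[idx] <- anc[idx]
    }
    internal2 <- paste(v, collapse = "")
    if (count_inframe_stops(internal2, cds_start, cds_length) == 0L) {
      return(internal2)
    }
  }
  internal
}

#' Evolve sub-family lineage consensuses from the family ancestor
#'
#' Each sub-family's consensus LTR and internal region derive from the family
#' ancestor by K2P substitutions with expected per-site count
#' `rate * lineage_divergence_years`; the polyprotein frame is preserved and
#' mutations creating in-frame stops in the consensus are reverted, so
#' synonymous divergence between two lineages is ~ `2 * rate * dt` in
#' expectation.
#'
#' @param family A [family_model()].
#' @param specs List of [subfamily_spec()] objects.
#' @param config A [simulation_config()] (provides `rate` and `kappa`).
#' @return Named list (per sub-family) with `ltr`, `internal` and `element`
#'   (= ltr + internal + ltr) consensus sequences.
#' @export
evolve_lineages <- function(family, specs, config) {
  out <- lapply(specs, function(sp) {
    mu <- config$rate * sp$lineage_divergence_years
    ltr <- mutate_k2p(family$ltr, mu, config$kappa)
    internal <- mutate_internal_nostop(family$internal, mu, config$kappa,
                                       family$cds_start, family$cds_length)
    list(ltr = ltr, internal = internal,
         element = paste0(ltr, internal, ltr))
  })
  names(out) <- vapply(specs, `[[`, character(1), "name")
  out
}

#' Random genome background
#'
#' @param lengths Named chromosome lengths.
#' @param gc GC content.
#' @param seed Integer seed.
#' @return Named character vector of chromosome sequences.
#' @export
make_background <- function(lengths, gc = 0.46, seed = 1L) {
  set.seed(seed)
  setNames(vapply(lengths, function(L) rand_dna(as.integer(L), gc),
                  character(1)), names(lengths))
}

#' @keywords internal
#' @noRd
apply_small_indels <- function(x, n_indels) {
  if (n_indels == 0L) return(x)
  for (k in seq_len(n_indels)) {
    L <- nchar(x)
    pos <- sample.int(L - 10L, 1L) + 5L
    size <- sample.int(3L, 1L)
    if (runif(1) < 0.5) {
      x <- paste0(substring(x, 1L, pos), substring(x, pos + size + 1L, L))
    } else {
      x <- paste0(substring(x, 1L, pos), rand_dna(size), substring(x, pos + 1L, L))
    }
  }
  x
}

#' @keywords internal
#' @noRd
corrupt_tsd <- function(tsd, p) {
  v <- strsplit(tsd, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < p)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  list(seq = paste(v, collapse = ""), mismatches = length(hit))
}

#' Plant a retrotransposon population into a background genome
#'
#' For every copy: sample its insertion age from the sub-family activity
#' distribution (normal truncated at 0); start from the lineage consensus
#' with both LTRs identical; apply post-insertion K2P substitutions at
#' expected rate `rate * age` per site with the two LTRs mutated
#' independently; inject `Poisson(doa_lambda)` premature stop codons into the
#' CDS; optionally add small (1-3 bp) indels to the internal region; insert
#' at a uniform non-overlapping position flanked by a duplicated target site
#' (`tsd_length` bp, 3' copy corrupted at `tsd_mismatch_prob` per base). An
#' exact count `round(solo_fraction * copy_count)` of copies is reduced to
#' solo-LTRs. Copies inside configured introgression intervals are planted
#' from the interval's own sub-family mix.
#'
#' @param background Named character vector of chromosome sequences (see
#'   [make_background()]).
#' @param family A [family_model()].
#' @param specs List of [subfamily_spec()].
#' @param config A [simulation_config()]; `config$seed` drives all
#'   randomness, so a rerun is byte-identical.
#' @return List with `genome` (named character vector, insertions applied),
#'   `truth` (tibble, 0-based half-open coordinates), `lineages` (from
#'   [evolve_lineages()]) and `config`.
#' @export
plant_population <- function(background, family, specs, config) {
  set.seed(config$seed)
  lineages <- evolve_lineages(family, specs, config)
  tsd_len <- config$tsd_length
  r <- config$rate

  # ---- per-copy draws -------------------------------------------------------
  spec_names <- vapply(specs, `[[`, character(1), "name")
  draws <- list()
  for (sp in specs) {
    nc <- sp$copy_count
    if (nc == 0L) next
    n_solo <- round(sp$solo_fraction * nc)
    is_solo <- rep(FALSE, nc)
    if (n_solo > 0) is_solo[sample.int(nc, n_solo)] <- TRUE
    sg <- sample(names(sp$subgenome_weights), nc, replace = TRUE,
                 prob = sp$subgenome_weights)
    age <- pmax(0, rnorm(nc, sp$activity_mean_years, sp$activity_sd_years))
    draws[[length(draws) + 1L]] <- tibble(
      subfamily = sp$name, subgenome = sg, age = age, solo = is_solo,
      doa_lambda = sp$doa_lambda, intro = NA_integer_)
  }
  copies <- bind_rows(draws)

  # introgression copies (forced sub-family, placed inside the interval)
  if (!is.null(config$introgressions)) {
    intro <- config$introgressions
    for (i in seq_len(nrow(intro))) {
      sp <- specs[[match(intro$subfamily[i], spec_names)]]
      if (is.na(match(intro$subfamily[i], spec_names))) {
        abort(paste("introgression sub-family not in specs:",
                    intro$subfamily[i]))
      }
      nc <- intro$copies[i]
      age <- pmax(0, rnorm(nc, sp$activity_mean_years, sp$activity_sd_years))
      copies <- bind_rows(copies, tibble(
        subfamily = sp$name,
        subgenome = unname(config$subgenomes[intro$chrom[i]]),
        age = age, solo = FALSE, doa_lambda = sp$doa_lambda,
        intro = i))
    }
  }

  # ---- choose insertion points ---------------------------------------------
  chroms <- names(background)
  chrom_sg <- config$subgenomes[chroms]
  min_sep <- tsd_len + 60L
  margin <- 2000L
  points_by_chrom <- lapply(setNames(chroms, chroms), function(ch) numeric(0))

  pick_point <- function(ch, lo, hi) {
    taken <- points_by_chrom[[ch]]
    for (try in 1:200) {
      p <- floor(runif(1, lo, hi))
      if (!length(taken) || min(abs(taken - p)) > min_sep) return(p)
    }
    NA_real_
  }

  intro_iv <- config$introgressions
  copies$chrom <- NA_character_
  copies$point <- NA_real_
  ord <- sample.int(nrow(copies))  # place in random order
  for (i in ord) {
    if (!is.na(copies$intro[i])) {
      ch <- intro_iv$chrom[copies$intro[i]]
      lo <- intro_iv$start[copies$intro[i]] + tsd_len
      hi <- intro_iv$end[copies$intro[i]] - tsd_len
    } else {
      cand <- chroms[chrom_sg == copies$subgenome[i]]
      if (!length(cand)) abort(paste("no chromosome for sub-genome",
                                     copies$subgenome[i]))
      w <- config$chrom_lengths[cand]
      ch <- sample(cand, 1L, prob = w / sum(w))
      lo <- margin
      hi <- config$chrom_lengths[[ch]] - margin
    }
    p <- pick_point(ch, lo, hi)
    # keep ordinary copies out of introgression intervals
    if (!is.na(p) && is.na(copies$intro[i]) && !is.null(intro_iv)) {
      for (try in 1:50) {
        iv <- intro_iv[intro_iv$chrom == ch, , drop = FALSE]
        if (!nrow(iv) || !any(p >= iv$start - margin & p < iv$end + margin)) break
        p <- pick_point(ch, lo, hi)
        if (is.na(p)) break
      }
    }
    if (is.na(p)) {
      abort(paste("could not place a copy of sub-family", copies$subfamily[i]))
    }
    copies$chrom[i] <- ch
    copies$point[i] <- p
    points_by_chrom[[ch]] <- c(points_by_chrom[[ch]], p)
  }

  # decoy fragments: partial LTR pieces without TSD
  decoys <- NULL
  if (config$decoy_count > 0L) {
    dn <- config$decoy_count
    dec <- tibble(chrom = NA_character_, point = NA_real_,
                  frag = character(dn))
    for (i in seq_len(dn)) {
      ch <- sample(chroms, 1L, prob = config$chrom_lengths / sum(config$chrom_lengths))
      p <- pick_point(ch, margin, config$chrom_lengths[[ch]] - margin)
      if (is.na(p)) abort("could not place a decoy fragment")
      L <- nchar(family$ltr)
      flen <- floor(runif(1, 0.3, 0.6) * L)
      fstart <- sample.int(L - flen, 1L)
      frag <- mutate_k2p(substring(family$ltr, fstart, fstart + flen - 1L),
                         runif(1, 0, 0.05), config$kappa)
      if (runif(1) < 0.5) frag <- revcomp(frag)
      dec$chrom[i] <- ch; dec$point[i] <- p; dec$frag[i] <- frag
      points_by_chrom[[ch]] <- c(points_by_chrom[[ch]], p)
    }
    decoys <- dec
  }

  # ---- build inserted fragments --------------------------------------------
  lens <- list(ltr = nchar(family$ltr))
  frag_rows <- list()
  for (i in seq_len(nrow(copies))) {
    lin <- lineages[[copies$subfamily[i]]]
    mu <- r * copies$age[i]
    strand <- sample(c("+", "-"), 1L)
    if (copies$solo[i]) {
      ltr <- mutate_k2p(lin$ltr, mu, config$kappa)
      seq <- if (strand == "-") revcomp(ltr) else ltr
      frag_rows[[i]] <- list(type = "solo_ltr", seq = seq, strand = strand,
                             stops = NA_integer_, ltr_len = nchar(ltr))
    } else {
      ltr5 <- mutate_k2p(lin$ltr, mu, config$kappa)
      ltr3 <- mutate_k2p(lin$ltr, mu, config$kappa)
      internal <- mutate_k2p(lin$internal, mu, config$kappa)
      # dead-on-arrival stops injected at insertion
      n_doa <- rpois(1L, copies$doa_lambda[i])
      if (n_doa > 0L) {
        v <- strsplit(internal, "", fixed = TRUE)[[1]]
        cod <- sample.int(family$cds_length %/% 3L, min(n_doa,
                                                        family$cds_length %/% 3L))
        for (cidx in cod) {
          idx <- family$cds_start + (cidx - 1L) * 3L + 1:3
          v[idx] <- strsplit(sample(c("TAA", "TAG", "TGA"), 1L), "")[[1]]
        }
        internal <- paste(v, collapse = "")
      }
      stops <- count_inframe_stops(internal, family$cds_start,
                                   family$cds_length)
      internal <- apply_small_indels(internal, rpois(1L, config$indel_rate))
      el <- paste0(ltr5, internal, ltr3)
      seq <- if (strand == "-") revcomp(el) else el
      frag_rows[[i]] <- list(type = "full_length", seq = seq, strand = strand,
                             stops = stops, ltr_len = nchar(ltr5))
    }
  }

  # ---- assemble chromosomes and final coordinates --------------------------
  events <- copies
  events$idx <- seq_len(nrow(events))
  events$kind <- "copy"
  if (!is.null(decoys)) {
    events <- bind_rows(events,
                        tibble(subfamily = NA, subgenome = NA, age = NA,
                               solo = NA, doa_lambda = NA, intro = NA,
                               chrom = decoys$chrom, point = decoys$point,
                               idx = seq_len(nrow(decoys)), kind = "decoy"))
  }

  truth <- list()
  genome <- background
  for (ch in chroms) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$point), , drop = FALSE]
    if (!nrow(ev)) next
    bg <- background[[ch]]
    pieces <- character(0)
    cursor <- 0L  # 0-based, consumed background prefix
    offset <- 0L  # accumulated inserted length
    for (k in seq_len(nrow(ev))) {
      p <- as.integer(ev$point[k])
      if (ev$kind[k] == "decoy") {
        frag <- decoys$frag[ev$idx[k]]
        pieces <- c(pieces, substring(bg, cursor + 1L, p))
        start_final <- p + offset
        pieces <- c(pieces, frag)
        offset <- offset + nchar(frag)
        cursor <- p
        truth[[length(truth) + 1L]] <- tibble(
          feature_type = "decoy_fragment", chrom = ch,
          start = start_final, end = start_final + nchar(frag),
          ltr5_start = NA_integer_, ltr5_end = NA_integer_,
          ltr3_start = NA_integer_, ltr3_end = NA_integer_,
          strand = "+", subfamily = NA_character_,
          true_age_years = NA_real_, tsd_mismatches = NA_integer_,
          stop_count = NA_integer_, in_introgression = FALSE)
        next
      }
      fr <- frag_rows[[ev$idx[k]]]
      tsd_src <- substring(bg, p + 1L, p + tsd_len)
      tsd3 <- corrupt_tsd(tsd_src, config$tsd_mismatch_prob)
      pieces <- c(pieces, substring(bg, cursor + 1L, p + tsd_len))
      start_final <- p + tsd_len + offset
      pieces <- c(pieces, fr$seq, tsd3$seq)
      cursor <- p + tsd_len
      offset <- offset + nchar(fr$seq) + tsd_len - tsd_len  # element only
      offset <- offset + tsd_len                            # plus the 3' TSD
      end_final <- start_final + nchar(fr$seq)
      Ltr <- fr$ltr_len
      if (fr$type == "solo_ltr") {
        l5 <- c(start_final, end_final)
        l3 <- c(NA_integer_, NA_integer_)
      } else if (fr$strand == "+") {
        l5 <- c(start_final, start_final + Ltr)
        l3 <- c(end_final - Ltr, end_final)
      } else {
        l5 <- c(end_final - Ltr, end_final)
        l3 <- c(start_final, start_final + Ltr)
      }
      truth[[length(truth) + 1L]] <- tibble(
        feature_type = fr$type, chrom = ch,
        start = start_final, end = end_final,
        ltr5_start = l5[1], ltr5_end = l5[2],
        ltr3_start = l3[1], ltr3_end = l3[2],
        strand = fr$strand, subfamily = ev$subfamily[k],
        true_age_years = ev$age[k], tsd_mismatches = tsd3$mismatches,
        stop_count = fr$stops,
        in_introgression = !is.na(ev$intro[k]))
    }
    pieces <- c(pieces, substring(bg, cursor + 1L, nchar(bg)))
    genome[[ch]] <- paste(pieces, collapse = "")
  }

  truth <- if (length(truth)) bind_rows(truth) else tibble()
  list(genome = genome, truth = truth, lineages = lineages, config = config)
}

#' Simulate a genome with a planted retrotransposon population
#'
#' Convenience wrapper: random background + lineage evolution + population
#' planting. Returns an object carrying everything downstream modules need,
#' including per-sub-family LTR consensuses for discovery.
#'
#' @inheritParams plant_population
#' @return A `te_simulation` list: `genome`, `truth`, `lineages`, `family`,
#'   `specs`, `config`, `subgenomes`.
#' @export
simulate_te_genome <- function(family = family_model(),
                               specs = default_subfamilies(),
                               config = simulation_config()) {
  bg <- make_background(config$chrom_lengths, config$gc, config$seed)
  res <- plant_population(bg, family, specs, config)
  structure(list(genome = res$genome, truth = res$truth,
                 lineages = res$lineages, family = family, specs = specs,
                 config = config, subgenomes = config$subgenomes),
            class = "te_simulation")
}

#' @export
print.te_simulation <- function(x, ...) {
  cat("<te_simulation>", length(x$genome), "chromosomes,",
      sum(nchar(x$genome)), "bp,", nrow(x$truth), "planted features\n")
  invisible(x)
}

#' Default sub-family set
#'
#' Three sub-families with distinct activity waves (0.3, 0.9 and 1.8 Myr
#' means), lineage divergences 1.5-3 Myr, sub-genome-biased abundances and a
#' shared solo-LTR fraction chosen so the default world plants 150
#' full-length copies and 30 solo-LTRs.
#'
#' @param copy_count Copies per sub-family (default 60).
#' @param solo_fraction Fraction reduced to solo-LTRs (default 1/6).
#' @return List of three [subfamily_spec()].
#' @export
default_subfamilies <- function(copy_count = 60L, solo_fraction = 1 / 6) {
  list(
    subfamily_spec("sfA", lineage_divergence_years = 1.5e6,
                   activity_mean_years = 3e5, activity_sd_years = 1e5,
                   subgenome_weights = c(A = 0.6, B = 0.2, D = 0.2),
                   copy_count = copy_count, doa_lambda = 0.3,
                   solo_fraction = solo_fraction),
    subfamily_spec("sfB", lineage_divergence_years = 2.2e6,
                   activity_mean_years = 9e5, activity_sd_years = 2e5,
                   subgenome_weights = c(A = 0.2, B = 0.6, D = 0.2),
                   copy_count = copy_count, doa_lambda = 0.3,
                   solo_fraction = solo_fraction),
    subfamily_spec("sfC", lineage_divergence_years = 3e6,
                   activity_mean_years = 1.8e6, activity_sd_years = 3e5,
                   subgenome_weights = c(A = 0.25, B = 0.25, D = 0.5),
                   copy_count = copy_count, doa_lambda = 0.3,
                   solo_fraction = solo_fraction)
  )
}

#' Write simulation outputs to disk
#'
#' Chromosomes as FASTA, ground truth as GFF3 (LTR_retrotransposon,
#' long_terminal_repeat, solo_LTR features) and as TSV, and the
#' configuration (seed included) as key=value text.
#'
#' @param sim A `te_simulation`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  write_fasta(sim$genome, fa)
  tsv <- file.path(dir, "truth.tsv")
  write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gff <- file.path(dir, "truth.gff3")
  write_truth_gff3(sim$truth, gff)
  cfgf <- file.path(dir, "config.txt")
  cfg <- sim$config
  writeLines(c(
    paste0("seed=", cfg$seed), paste0("rate=", cfg$rate),
    paste0("kappa=", cfg$kappa), paste0("tsd_length=", cfg$tsd_length),
    paste0("gc=", cfg$gc),
    paste0("chrom_lengths=", paste(names(cfg$chrom_lengths),
                                   cfg$chrom_lengths, sep = ":",
                                   collapse = ","))), cfgf)
  invisible(c(fa, tsv, gff, cfgf))
}

#' @keywords internal
#' @noRd
write_truth_gff3 <- function(truth, path) {
  type_map <- c(full_length = "LTR_retrotransposon", solo_ltr = "solo_LTR",
                decoy_fragment = "repeat_fragment")
  gr <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end),
    strand = truth$strand)
  S4Vectors::mcols(gr)$type <- unname(type_map[truth$feature_type])
  S4Vectors::mcols(gr)$ID <- paste0("feat", seq_len(nrow(truth)))
  S4Vectors::mcols(gr)$subfamily <- truth$subfamily
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
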