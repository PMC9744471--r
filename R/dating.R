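#' Molecular clock model
#'
#' @param rate Substitutions per site per year (default 1.3e-8, the grass
#'   intergenic rate).
#' @return A `clock_model` list (`rate`, `model = "K2P"`).
#' @export
clock_model <- function(rate = 1.3e-8) {
  stopifnot(rate > 0)
  structure(list(rate = rate, model = "K2P"), class = "clock_model")
}

#' @keywords internal
#' @noRd
is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Kimura two-parameter distance from transition/transversion fractions
#'
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with P the transition and Q
#' the transversion fraction of aligned (gap-free) sites. Returns `NA` when
#' the correction is saturated (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`).
#'
#' @param P Transition fraction.
#' @param Q Transversion fraction.
#' @return The corrected distance (substitutions per site), or NA.
#' @export
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1 * sqrt(w2))
}

#' Date a retrotransposon insertion from its two LTRs
#'
#' The LTRs (identical at insertion) are locally aligned with the 10/0.5
#' dating penalties; transitions and transversions are counted over gap-free
#' columns; the K2P-corrected distance K gives the age as `K / (2 * rate)`
#' since both LTRs accumulate mutations independently.
#'
#' @param ltr5,ltr3 The two LTR sequences (>= 50 bp).
#' @param clock A [clock_model()].
#' @param scheme Alignment scoring scheme (default match 2, mismatch -1, gap
#'   open 10, extend 0.5).
#' @param element_id Identifier carried into the result.
#' @return One-row tibble: `element_id`, `aligned_sites`, `transitions`,
#'   `transversions`, `P`, `Q`, `K`, `age_years`, `identical_ltrs`,
#'   `status` ("ok", "undatable" when the alignment covers <50% of the
#'   shorter LTR, "saturated" when the K2P correction fails).
#' @export
date_insertion <- function(ltr5, ltr3, clock = clock_model(),
                           scheme = scoring_scheme(2, -1, 10, 0.5),
                           element_id = "element") {
  if (nchar(ltr5) < 50 || nchar(ltr3) < 50) abort("LTRs must be >= 50 bp")
  empty_row <- function(status) {
    tibble(element_id = element_id, aligned_sites = NA_integer_,
           transitions = NA_integer_, transversions = NA_integer_,
           P = NA_real_, Q = NA_real_, K = NA_real_, age_years = NA_real_,
           identical_ltrs = FALSE, status = status)
  }
  al <- local_align(ltr5, ltr3, scheme)
  if (isTRUE(al$empty)) return(empty_row("undatable"))
  qv <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
  sv <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
  keep <- qv != "-" & sv != "-"
  n_sites <- sum(keep)
  if (n_sites < 0.5 * min(nchar(ltr5), nchar(ltr3))) {
    return(empty_row("undatable"))
  }
  a <- qv[keep]; b <- sv[keep]
  ts <- sum(is_transition(a, b))
  diffs <- sum(a != b)
  tv <- diffs - ts
  P <- ts / n_sites
  Q <- tv / n_sites
  if (ts + tv == 0L) {
    return(tibble(element_id = element_id, aligned_sites = n_sites,
                  transitions = 0L, transversions = 0L, P = 0, Q = 0, K = 0,
                  age_years = 0, identical_ltrs = TRUE, status = "ok"))
  }
  K <- k2p_distance(P, Q)
  if (is.na(K)) {
    out <- empty_row("saturated")
    out$aligned_sites <- n_sites; out$transitions <- ts
    out$transversions <- tv; out$P <- P; out$Q <- Q
    return(out)
  }
  tibble(element_id = element_id, aligned_sites = n_sites, transitions = ts,
         transversions = tv, P = P, Q = Q, K = K,
         age_years = K / (2 * clock$rate), identical_ltrs = FALSE,
         status = "ok")
}

#' Date every element in an annotation
#'
#' @param elements Elements tibble with `ltr5_seq`/`ltr3_seq` columns (see
#'   [element_sequences()]).
#' @param clock A [clock_model()].
#' @return The tibble with age columns joined (one row per element).
#' @export
date_elements <- function(elements, clock = clock_model()) {
  ages <- purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    date_insertion(elements$ltr5_seq[i], elements$ltr3_seq[i], clock,
                   element_id = elements$element_id[i])
  })
  left_join(elements, ages, by = "element_id")
}

#' Extract a copy's CDS in the consensus reading frame
#'
#' The copy is locally aligned to the family CDS consensus (nucleotide
#' level); the copy's bases are read off in the consensus frame (consensus
#' position 1 = codon position 1). Copy insertions are dropped, consensus
#' positions deleted in the copy become `-`. In-frame stop codons are counted
#' over complete, gap-free codons, and a frameshift is flagged when the
#' alignment contains a gap whose length is not a multiple of 3.
#'
#' @param copy Copy nucleotide sequence (the internal region or whole
#'   element, element orientation).
#' @param cds_consensus CDS consensus (starts at a codon boundary).
#' @param scheme Scoring scheme (default 10/0.5).
#' @param band Optional alignment band half-width (0 = unbanded).
#' @param min_identity,min_columns Guard against spurious low-complexity
#'   chaining: alignments with identity below `min_identity` (default 0.6)
#'   or fewer than `min_columns` gap-free columns count as "no CDS".
#' @return List: `cds` (consensus-framed copy CDS with `-` for deletions),
#'   `protein`, `stop_count`, `frameshift`, `consensus_span` (0-based
#'   half-open), `codons` (character vector of complete codons),
#'   `codon_positions` (0-based consensus codon index per entry), or NULL
#'   when there is no alignment ("no CDS").
#' @export
extract_cds <- function(copy, cds_consensus,
                        scheme = scoring_scheme(2, -1, 10, 0.5), band = 0L,
                        min_identity = 0.6, min_columns = 60L) {
  al <- local_align(copy, cds_consensus, scheme, band = band)
  if (isTRUE(al$empty) || al$identity_fraction < min_identity ||
      al$aligned_columns < min_columns) {
    return(NULL)
  }
  qv <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
  sv <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
  # frameshift: any gap run with length %% 3 != 0
  gap_runs <- function(v) {
    r <- rle(v == "-")
    r$lengths[r$values]
  }
  fs <- any(c(gap_runs(qv), gap_runs(sv)) %% 3L != 0L)
  # copy base per consensus position within the aligned span
  cons_idx <- cumsum(sv != "-") + al$subject_span[1]  # 1-based consensus pos
  keep <- sv != "-"
  pos <- cons_idx[keep]
  base <- qv[keep]
  cds_vec <- rep(NA_character_, nchar(cds_consensus))
  cds_vec[pos] <- base
  span <- c(al$subject_span[1], al$subject_span[2])
  # complete codons fully inside the aligned span with no gaps
  n_codon <- nchar(cds_consensus) %/% 3L
  codons <- character(0); codon_pos <- integer(0); stops <- 0L
  for (cidx in seq_len(n_codon)) {
    idx <- (cidx - 1L) * 3L + 1:3
    cod <- cds_vec[idx]
    if (anyNA(cod) || any(cod == "-")) next
    codon <- paste(cod, collapse = "")
    codons <- c(codons, codon)
    codon_pos <- c(codon_pos, cidx - 1L)
    if (codon %in% c("TAA", "TAG", "TGA")) stops <- stops + 1L
  }
  cds_vec[is.na(cds_vec)] <- "-"
  list(cds = paste(cds_vec, collapse = ""),
       protein = translate_dna(paste(codons, collapse = "")),
       stop_count = stops, frameshift = fs, consensus_span = span,
       codons = codons, codon_positions = codon_pos)
}

# four-fold degenerate codon families: third position free given these
# first-two-base prefixes; Leu/Arg/Ser restricted to one prefix each
FOURFOLD_PREFIXES <- c("GC",  # Ala
                       "GG",  # Gly
                       "CT",  # Leu (CTN only)
                       "CC",  # Pro
                       "CG",  # Arg (CGN only)
                       "TC",  # Ser (TCN only)
                       "AC",  # Thr
                       "GT")  # Val

#' Sub-group divergence time from four-fold degenerate sites
#'
#' Near-intact copies (at most `max_stops` in-frame stops, no frameshift)
#' are selected from each group; random cross-group pairs are drawn; per
#' pair the predicted proteins are aligned and back-mapped to a
#' codon-by-codon DNA alignment. A site is eligible when both codons belong
#' to a four-fold degenerate family (third positions of Ala, Gly, Leu, Pro,
#' Arg, Ser, Thr, Val; for the six-codon Leu/Arg/Ser only the CT/TC/CG
#' prefixes) and the two codons agree at their first two positions. The
#' per-pair synonymous distance is the fraction of eligible third positions
#' that differ, converted to years as `d / (2 * rate)`; the divergence
#' estimate is the midpoint of the peak bin of the per-pair histogram.
#'
#' @param copies_a,copies_b Named character vectors of copy sequences
#'   (element orientation) for the two groups.
#' @param cds_consensus Family CDS consensus.
#' @param clock A [clock_model()].
#' @param max_stops Near-intact rule: maximum in-frame stops.
#' @param n_pairs Number of random cross pairs (default `min(200, all)`).
#' @param mode_bin_years Histogram bin width for the mode (default 1e5).
#' @param band Alignment band for [extract_cds()].
#' @param seed Seed for pair sampling.
#' @return List of class `divergence_estimate`: `pairs` tibble (`id_a`,
#'   `id_b`, `sites_used`, `distance`, `years`), `mode_years`, `pair_count`,
#'   `skipped` (pairs with zero eligible sites), `eligible_a`/`eligible_b`
#'   counts.
#' @export
fourfold_divergence_pairs <- function(copies_a, copies_b, cds_consensus,
                                      clock = clock_model(), max_stops = 3L,
                                      n_pairs = NULL, mode_bin_years = 1e5,
                                      band = 0L, seed = 1L) {
  prep <- function(copies) {
    res <- lapply(copies, extract_cds, cds_consensus = cds_consensus,
                  band = band)
    ok <- vapply(res, function(r) !is.null(r) && r$stop_count <= max_stops &&
                   !r$frameshift, logical(1))
    res[ok]
  }
  ca <- prep(copies_a)
  cb <- prep(copies_b)
  if (length(ca) < 2 || length(cb) < 2) {
    abort("each group needs >= 2 near-intact copies")
  }
  all_pairs <- expand.grid(a = seq_along(ca), b = seq_along(cb))
  if (is.null(n_pairs)) n_pairs <- min(200L, nrow(all_pairs))
  set.seed(seed)
  sel <- all_pairs[sample.int(nrow(all_pairs), min(n_pairs, nrow(all_pairs))), ]

  pscheme <- protein_scheme()
  rows <- list()
  skipped <- 0L
  for (r in seq_len(nrow(sel))) {
    ea <- ca[[sel$a[r]]]
    eb <- cb[[sel$b[r]]]
    pal <- local_align(ea$protein, eb$protein, pscheme)
    if (isTRUE(pal$empty)) { skipped <- skipped + 1L; next }
    av <- strsplit(pal$aligned_query, "", fixed = TRUE)[[1]]
    bv <- strsplit(pal$aligned_subject, "", fixed = TRUE)[[1]]
    ai <- cumsum(av != "-") + pal$query_span[1]    # 1-based aa index in a
    bi <- cumsum(bv != "-") + pal$subject_span[1]
    both <- av != "-" & bv != "-"
    cod_a <- ea$codons[ai[both]]
    cod_b <- eb$codons[bi[both]]
    pre_a <- substr(cod_a, 1, 2)
    pre_b <- substr(cod_b, 1, 2)
    eligible <- pre_a == pre_b & pre_a %in% FOURFOLD_PREFIXES
    n_el <- sum(eligible)
    if (n_el == 0L) { skipped <- skipped + 1L; next }
    mism <- sum(substr(cod_a[eligible], 3, 3) != substr(cod_b[eligible], 3, 3))
    d <- mism / n_el
    rows[[length(rows) + 1L]] <- tibble(
      id_a = names(ca)[sel$a[r]] %||% as.character(sel$a[r]),
      id_b = names(cb)[sel$b[r]] %||% as.character(sel$b[r]),
      sites_used = n_el, distance = d, years = d / (2 * clock$rate))
  }
  if (!length(rows)) abort("no pair had eligible four-fold sites")
  pairs <- bind_rows(rows)
  mode_years <- histogram_mode(pairs$years, mode_bin_years)
  structure(list(pairs = pairs, mode_years = mode_years,
                 pair_count = nrow(pairs), skipped = skipped,
                 eligible_a = length(ca), eligible_b = length(cb),
                 bin_years = mode_bin_years),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("<divergence_estimate> %d pairs (%d skipped), mode %.3g years\n",
              x$pair_count, x$skipped, x$mode_years))
  invisible(x)
}

#' @keywords internal
#' @noRd
histogram_mode <- function(x, bin) {
  b <- floor(x / bin)
  tab <- table(b)
  peak <- as.numeric(names(tab)[which.max(tab)])
  (peak + 0.5) * bin
}

#' Dead-on-arrival regression of stop codons on insertion age
#'
#' Ordinary least squares of in-frame stop counts on estimated insertion
#' ages. The intercept estimates the expected number of stops in newly
#' inserted elements; assuming a Poisson count, the fraction of copies dead
#' on arrival (>= 1 stop at insertion) is `1 - exp(-intercept)`.
#'
#' @param age_years Numeric vector of insertion ages.
#' @param stop_counts Integer vector of in-frame stop counts.
#' @return List of class `doa_fit`: `intercept`, `slope`,
#'   `doa_fraction`, `r_squared`, `n`, and the underlying `lm` fit.
#' @export
doa_regression <- function(age_years, stop_counts) {
  keep <- complete.cases(age_years, stop_counts)
  age_years <- age_years[keep]; stop_counts <- stop_counts[keep]
  if (length(age_years) < 10) abort("need at least 10 points")
  if (sd(age_years) == 0) abort("degenerate ages: all equal")
  fit <- lm(stop_counts ~ age_years)
  ic <- unname(coef(fit)[1]); sl <- unname(coef(fit)[2])
  structure(list(intercept = ic, slope = sl,
                 doa_fraction = 1 - exp(-max(0, ic)),
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n = length(age_years), fit = fit),
            class = "doa_fit")
}

#' @export
print.doa_fit <- function(x, ...) {
  cat(sprintf(
    "<doa_fit> intercept %.3f stops at insertion (DOA fraction %.2f), slope %.3g/yr, n=%d\n",
    x$intercept, x$doa_fraction, x$slope, x$n))
  invisible(x)
}

#' @export
tidy.doa_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.doa_fit <- function(x, ...) {
  tibble(intercept = x$intercept, slope = x$slope,
         doa_fraction = x$doa_fraction, r_squared = x$r_squared, n = x$n)
}
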