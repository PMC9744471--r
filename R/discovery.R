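#' Build one or more LTR consensus sequences from example LTRs
#'
#' Examples are clustered by pairwise identity (single linkage at
#' `identity_threshold`, default 90%) and one majority-rule consensus is
#' built per cluster, mirroring the practice of using several consensus LTRs
#' per family to cover intra-family diversity.
#'
#' @param ltr_examples Named character vector of LTR sequences from one
#'   family (>= 10 recommended; fewer triggers a warning and a single
#'   consensus).
#' @param identity_threshold Single-linkage identity threshold.
#' @param scheme Scoring scheme for the multiple alignments (default the
#'   10/0.2 consensus-building penalties).
#' @return Named character vector of consensus sequences (`cons1`, ...).
#' @export
build_ltr_consensuses <- function(ltr_examples, identity_threshold = 0.90,
                                  scheme = scoring_scheme(gap_open = 10,
                                                          gap_extend = 0.2)) {
  n <- length(ltr_examples)
  if (is.null(names(ltr_examples))) {
    names(ltr_examples) <- paste0("ltr", seq_len(n))
  }
  if (n < 2) return(setNames(unname(ltr_examples), "cons1"))
  single <- FALSE
  if (n < 10) {
    warn("fewer than 10 LTR examples; building a single consensus")
    single <- TRUE
  }
  if (single) {
    cl <- rep(1L, n)
  } else {
    idm <- matrix(1, n, n)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        al <- local_align(ltr_examples[[i]], ltr_examples[[j]], scheme)
        idf <- if (isTRUE(al$empty)) 0 else
          al$identity_fraction * al$aligned_columns /
            max(nchar(ltr_examples[[i]]), nchar(ltr_examples[[j]]))
        idm[i, j] <- idm[j, i] <- idf
      }
    }
    # single linkage: union-find over pairs above threshold
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (idm[i, j] >= identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    cl <- vapply(seq_len(n), find, integer(1))
    cl <- match(cl, unique(cl))
  }
  out <- character(0)
  for (g in sort(unique(cl))) {
    members <- ltr_examples[cl == g]
    cons <- if (length(members) == 1) unname(members[[1]]) else
      as.character(majority_consensus(progressive_msa(members, scheme)))
    out <- c(out, cons)
  }
  setNames(out, paste0("cons", seq_along(out)))
}

#' Scan a genome for LTR consensus hits
#'
#' Seed-and-extend search: exact k-mer seeds (default k = 12) of each
#' consensus (both strands) are located with Biostrings, clustered into
#' candidate windows, and each window is aligned to the consensus with the
#' affine-gap local aligner. Hits below the identity or coverage thresholds
#' are discarded; overlapping hits from different consensuses are merged
#' keeping the best identity. Coordinates are 0-based half-open on the
#' forward strand.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param consensuses Named character vector of LTR consensus sequences.
#' @param min_identity Minimum alignment identity (default 0.80).
#' @param min_coverage Minimum fraction of the consensus covered (default
#'   0.95).
#' @param k Seed length.
#' @param min_seeds Minimum seeds per candidate window.
#' @param scheme Scoring scheme for extension. The default uses a stricter
#'   mismatch penalty (-2) than the general-purpose aligner so that, as in
#'   blastn-style extension, alignments do not creep through flanking
#'   non-homologous sequence and inflate consensus coverage.
#' @return Tibble of hits: `chrom`, `start`, `end`, `strand`,
#'   `consensus_id`, `identity_fraction`, `consensus_coverage`,
#'   `missing_5prime_bp`, `missing_3prime_bp` (5'/3' in consensus
#'   orientation).
#' @export
scan_hits <- function(genome, consensuses, min_identity = 0.80,
                      min_coverage = 0.95, k = 12L, min_seeds = 2L,
                      scheme = scoring_scheme(2, -2, 10, 0.5)) {
  stopifnot(length(genome) > 0, length(consensuses) > 0)
  if (is.null(names(consensuses))) {
    names(consensuses) <- paste0("cons", seq_along(consensuses))
  }
  pad <- 150L
  rows <- list()
  for (ch in names(genome)) {
    subj <- Biostrings::DNAString(genome[[ch]])
    chrom_len <- nchar(genome[[ch]])
    for (cid in names(consensuses)) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") consensuses[[cid]] else
          revcomp(consensuses[[cid]])
        L <- nchar(q)
        if (L < k) next
        starts <- seq_len(L - k + 1L)
        kmers <- substring(q, starts, starts + k - 1L)
        ok <- !grepl("[^ACGT]", kmers)
        if (!any(ok)) next
        pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmers[ok]))
        mt <- Biostrings::matchPDict(pd, subj)
        qpos <- starts[ok]
        gstart <- unlist(Biostrings::startIndex(mt), use.names = FALSE)
        if (is.null(gstart) || !length(gstart)) next
        reps <- lengths(Biostrings::startIndex(mt))
        qrep <- rep(qpos, reps)
        implied <- gstart - qrep  # 0-based implied query start in genome
        o <- order(implied)
        implied <- implied[o]
        brk <- c(0L, which(diff(implied) > 100L), length(implied))
        for (b in seq_len(length(brk) - 1L)) {
          idx <- (brk[b] + 1L):brk[b + 1L]
          if (length(idx) < min_seeds) next
          est <- as.integer(round(median(implied[idx])))
          w0 <- max(0L, est - pad)
          w1 <- min(chrom_len, est + L + pad)
          window <- substring(genome[[ch]], w0 + 1L, w1)
          al <- local_align(q, window, scheme)
          if (isTRUE(al$empty)) next
          cov <- (al$query_span[2] - al$query_span[1]) / L
          if (al$identity_fraction < min_identity || cov < min_coverage) next
          m5 <- al$query_span[1]
          m3 <- L - al$query_span[2]
          if (strand == "-") { tmp <- m5; m5 <- m3; m3 <- tmp }
          rows[[length(rows) + 1L]] <- tibble(
            chrom = ch, start = w0 + al$subject_span[1],
            end = w0 + al$subject_span[2], strand = strand,
            consensus_id = cid, identity_fraction = al$identity_fraction,
            consensus_coverage = cov, missing_5prime_bp = m5,
            missing_3prime_bp = m3, score = al$score)
        }
      }
    }
  }
  if (!length(rows)) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character(), consensus_id = character(),
                  identity_fraction = double(), consensus_coverage = double(),
                  missing_5prime_bp = integer(), missing_3prime_bp = integer(),
                  score = double()))
  }
  hits <- bind_rows(rows) |> arrange(.data$chrom, .data$start, desc(.data$identity_fraction))
  # merge overlapping hits (same or different consensuses): keep best identity
  keep <- logical(nrow(hits))
  last_by_key <- list()
  out <- list()
  for (i in seq_len(nrow(hits))) {
    key <- paste(hits$chrom[i], hits$strand[i])
    merged <- FALSE
    if (!is.null(last_by_key[[key]])) {
      for (j in last_by_key[[key]]) {
        ov <- min(hits$end[i], out[[j]]$end) - max(hits$start[i], out[[j]]$start)
        shorter <- min(hits$end[i] - hits$start[i],
                       out[[j]]$end - out[[j]]$start)
        if (ov > 0.5 * shorter) {
          if (hits$identity_fraction[i] > out[[j]]$identity_fraction) {
            out[[j]] <- hits[i, ]
          }
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) {
      out[[length(out) + 1L]] <- hits[i, ]
      last_by_key[[key]] <- c(last_by_key[[key]], length(out))
      # only recent windows can overlap; prune
      lb <- last_by_key[[key]]
      if (length(lb) > 6) last_by_key[[key]] <- tail(lb, 6)
    }
  }
  bind_rows(out) |> arrange(.data$chrom, .data$start)
}

#' Completeness filter for LTR hits
#'
#' Retains hits missing at most `max_missing` bp (default 5) on either side
#' of the consensus.
#'
#' @param hits Tibble from [scan_hits()].
#' @param max_missing Maximum missing bp per side.
#' @return Filtered tibble.
#' @export
completeness_filter <- function(hits, max_missing = 5L) {
  filter(hits, .data$missing_5prime_bp <= max_missing,
         .data$missing_3prime_bp <= max_missing)
}

#' Pair LTR hits into candidate full-length elements
#'
#' Same-chromosome, same-strand hits whose outer distance (left start to
#' right end) falls inside the family distance window are paired greedily
#' left-to-right, each hit taking its nearest admissible partner and
#' participating in at most one element. Unpaired hits are returned as
#' leftover solo-LTR candidates.
#'
#' @param hits Completeness-passing hits, any order.
#' @param distance_window Numeric length-2: admissible outer distances in bp.
#' @return List with `candidates` (tibble: element spans plus both LTR
#'   spans) and `leftover` (unpaired hits tibble).
#' @export
pair_ltrs <- function(hits, distance_window) {
  stopifnot(length(distance_window) == 2)
  hits <- arrange(hits, .data$chrom, .data$start)
  used <- logical(nrow(hits))
  cand <- list()
  grp <- paste(hits$chrom, hits$strand)
  for (i in seq_len(nrow(hits))) {
    if (used[i]) next
    js <- which(!used & grp == grp[i] & seq_len(nrow(hits)) > i)
    if (!length(js)) next
    outer <- hits$end[js] - hits$start[i]
    adm <- js[outer >= distance_window[1] & outer <= distance_window[2]]
    if (!length(adm)) next
    j <- adm[which.min(hits$end[adm] - hits$start[i])]
    used[i] <- used[j] <- TRUE
    cand[[length(cand) + 1L]] <- tibble(
      chrom = hits$chrom[i], strand = hits$strand[i],
      start = hits$start[i], end = hits$end[j],
      ltr_left_start = hits$start[i], ltr_left_end = hits$end[i],
      ltr_right_start = hits$start[j], ltr_right_end = hits$end[j],
      consensus_id = hits$consensus_id[i],
      ltr_identity = (hits$identity_fraction[i] +
                        hits$identity_fraction[j]) / 2)
  }
  candidates <- if (length(cand)) bind_rows(cand) else
    tibble(chrom = character(), strand = character(), start = integer(),
           end = integer(), ltr_left_start = integer(),
           ltr_left_end = integer(), ltr_right_start = integer(),
           ltr_right_end = integer(), consensus_id = character(),
           ltr_identity = double())
  list(candidates = candidates, leftover = hits[!used, , drop = FALSE])
}

#' Screen candidate elements for the expected polyprotein
#'
#' The internal region (between the LTRs) is aligned in translation against
#' the family polyprotein consensus; a candidate passes when the alignment
#' covers at least `min_cov` of the consensus at `min_aa_identity` identity.
#'
#' @param candidates Candidates tibble from [pair_ltrs()].
#' @param genome Named character vector of chromosomes.
#' @param polyprotein_consensus Amino-acid string.
#' @param min_cov Minimum consensus coverage.
#' @param min_aa_identity Minimum amino-acid identity.
#' @return Candidates with `cds_pass`, `cds_identity`, `cds_coverage` and
#'   `cds_frame` columns added.
#' @export
screen_cds <- function(candidates, genome, polyprotein_consensus,
                       min_cov = 0.3, min_aa_identity = 0.4) {
  n <- nrow(candidates)
  pass <- logical(n); idf <- rep(NA_real_, n); cov <- rep(NA_real_, n)
  frame <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    int_start <- candidates$ltr_left_end[i]
    int_end <- candidates$ltr_right_start[i]
    if (int_end - int_start < 300) next
    region <- substring(genome[[candidates$chrom[i]]], int_start + 1L, int_end)
    al <- translated_align(region, polyprotein_consensus,
                           strand = candidates$strand[i])
    if (isTRUE(al$empty)) next
    idf[i] <- al$identity_fraction
    cov[i] <- al$subject_coverage
    frame[i] <- al$frame
    pass[i] <- al$subject_coverage >= min_cov &&
      al$identity_fraction >= min_aa_identity
  }
  mutate(candidates, cds_pass = pass, cds_identity = idf,
         cds_coverage = cov, cds_frame = frame)
}

#' Flag candidates at the extremes of the size distribution
#'
#' The shortest and longest `tail_fraction` (default 3%, `ceiling` per tail)
#' of candidates by element length are flagged `size_trimmed` rather than
#' deleted, keeping the filter auditable. Ties are resolved by row order
#' after sorting on (length, chrom, start).
#'
#' @param candidates Candidates tibble.
#' @param tail_fraction Fraction flagged per tail.
#' @return Candidates with logical `size_trimmed` column.
#' @export
trim_size_distribution <- function(candidates, tail_fraction = 0.03) {
  n <- nrow(candidates)
  out <- mutate(candidates, length_bp = .data$end - .data$start,
                size_trimmed = FALSE)
  if (n < 2) return(out)
  k <- ceiling(tail_fraction * n)
  ord <- order(out$length_bp, out$chrom, out$start)
  flag <- c(head(ord, k), tail(ord, k))
  out$size_trimmed[flag] <- TRUE
  out
}

#' Detect a target-site duplication around an element
#'
#' Compares the `tsd_length` bp immediately flanking the element on each
#' side. Because alignment-derived boundaries can be a couple of bases off,
#' offsets of +/- `jitter` bp (applied to both boundaries together) are also
#' tested and the offset with the fewest mismatches is kept.
#'
#' @param genome Named character vector.
#' @param chrom,start,end Element coordinates (0-based half-open).
#' @param tsd_length TSD length (default 5).
#' @param max_mismatches Maximum mismatches for `tsd_ok` (default 2).
#' @param jitter Boundary jitter tolerance in bp.
#' @return List: `tsd_left`, `tsd_right`, `tsd_mismatches`, `tsd_ok`
#'   (NA when a flank runs off the contig: "not assessable").
#' @export
detect_tsd <- function(genome, chrom, start, end, tsd_length = 5L,
                       max_mismatches = 2L, jitter = 2L) {
  seqlen <- nchar(genome[[chrom]])
  if (start - tsd_length - jitter < 0 || end + tsd_length + jitter > seqlen) {
    return(list(tsd_left = NA_character_, tsd_right = NA_character_,
                tsd_mismatches = NA_integer_, tsd_ok = NA))
  }
  best <- NULL
  for (d in -jitter:jitter) {
    lf <- substring(genome[[chrom]], start + d - tsd_length + 1L, start + d)
    rf <- substring(genome[[chrom]], end + d + 1L, end + d + tsd_length)
    mm <- sum(strsplit(lf, "")[[1]] != strsplit(rf, "")[[1]])
    if (is.null(best) || mm < best$mm) best <- list(lf = lf, rf = rf, mm = mm)
  }
  list(tsd_left = best$lf, tsd_right = best$rf, tsd_mismatches = best$mm,
       tsd_ok = best$mm <= max_mismatches)
}

#' Call solo-LTRs among leftover hits
#'
#' An unpaired, completeness-passing hit flanked by a target-site
#' duplication (same rule as for elements) is called a solo-LTR; the rest
#' are reported as unclassified fragments.
#'
#' @param leftover Leftover hits from [pair_ltrs()].
#' @param genome Named character vector.
#' @param tsd_length,max_mismatches,jitter See [detect_tsd()].
#' @return List of tibbles `solo` and `unclassified`, each with TSD columns.
#' @export
call_solo_ltrs <- function(leftover, genome, tsd_length = 5L,
                           max_mismatches = 2L, jitter = 2L) {
  n <- nrow(leftover)
  tl <- character(n); tr <- character(n); mm <- integer(n); ok <- logical(n)
  for (i in seq_len(n)) {
    t <- detect_tsd(genome, leftover$chrom[i], leftover$start[i],
                    leftover$end[i], tsd_length, max_mismatches, jitter)
    tl[i] <- t$tsd_left %||% NA_character_
    tr[i] <- t$tsd_right %||% NA_character_
    mm[i] <- t$tsd_mismatches %||% NA_integer_
    ok[i] <- isTRUE(t$tsd_ok)
  }
  out <- mutate(leftover, tsd_left = tl, tsd_right = tr,
                tsd_mismatches = mm, tsd_ok = ok)
  list(solo = filter(out, .data$tsd_ok),
       unclassified = filter(out, !.data$tsd_ok))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Full-length element and solo-LTR discovery pipeline
#'
#' Runs the identification pipeline: consensus scan, completeness filter,
#' LTR pairing at the family distance window, coding-sequence screen,
#' size-distribution trimming, TSD detection and solo-LTR calling.
#' TSDs are recorded but not required for retention.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param ltr_consensuses Named character vector of LTR consensuses.
#' @param polyprotein Family polyprotein consensus (amino acids), or NULL to
#'   skip the CDS screen.
#' @param distance_window Admissible outer element span (bp).
#' @param family Family label for the output.
#' @param min_identity,min_coverage Scan thresholds.
#' @param tsd_length,max_tsd_mismatches TSD rule.
#' @param tail_fraction Size-trim tail fraction.
#' @return List of class `te_annotation`: `elements` (one row per candidate;
#'   `retained` marks full-length calls passing the CDS screen, while
#'   `size_trimmed` flags the size-distribution tails for exclusion from
#'   population analyses without deleting the call), `solo_ltrs`,
#'   `unclassified`, `hits`.
#' @export
discover_elements <- function(genome, ltr_consensuses, polyprotein = NULL,
                              distance_window, family = "family",
                              min_identity = 0.80, min_coverage = 0.95,
                              tsd_length = 5L, max_tsd_mismatches = 2L,
                              tail_fraction = 0.03) {
  hits <- scan_hits(genome, ltr_consensuses, min_identity, min_coverage)
  hits_ok <- completeness_filter(hits)
  pr <- pair_ltrs(hits_ok, distance_window)
  cand <- pr$candidates
  if (nrow(cand)) {
    if (!is.null(polyprotein)) {
      cand <- screen_cds(cand, genome, polyprotein)
    } else {
      cand <- mutate(cand, cds_pass = NA, cds_identity = NA_real_,
                     cds_coverage = NA_real_, cds_frame = NA_integer_)
    }
    cand <- trim_size_distribution(cand, tail_fraction)
    tsds <- lapply(seq_len(nrow(cand)), function(i) {
      detect_tsd(genome, cand$chrom[i], cand$start[i], cand$end[i],
                 tsd_length, max_tsd_mismatches)
    })
    cand <- mutate(cand,
      tsd_left = vapply(tsds, function(t) t$tsd_left %||% NA_character_, character(1)),
      tsd_right = vapply(tsds, function(t) t$tsd_right %||% NA_character_, character(1)),
      tsd_mismatches = vapply(tsds, function(t) t$tsd_mismatches %||% NA_integer_, integer(1)),
      tsd_ok = vapply(tsds, function(t) t$tsd_ok %||% NA, logical(1)),
      family = family,
      element_id = paste0(family, "_", .data$chrom, "_", .data$start),
      # 5'/3' LTR and internal spans in element orientation
      ltr5_start = ifelse(.data$strand == "+", .data$ltr_left_start, .data$ltr_right_start),
      ltr5_end = ifelse(.data$strand == "+", .data$ltr_left_end, .data$ltr_right_end),
      ltr3_start = ifelse(.data$strand == "+", .data$ltr_right_start, .data$ltr_left_start),
      ltr3_end = ifelse(.data$strand == "+", .data$ltr_right_end, .data$ltr_left_end),
      internal_start = .data$ltr_left_end,
      internal_end = .data$ltr_right_start,
      retained = if (!is.null(polyprotein)) .data$cds_pass else TRUE)
  }
  sl <- call_solo_ltrs(pr$leftover, genome, tsd_length, max_tsd_mismatches)
  structure(list(elements = cand, solo_ltrs = sl$solo,
                 unclassified = sl$unclassified, hits = hits,
                 family = family),
            class = "te_annotation")
}

#' @export
print.te_annotation <- function(x, ...) {
  nret <- if (nrow(x$elements)) sum(x$elements$retained, na.rm = TRUE) else 0L
  cat("<te_annotation>", x$family, "-", nrow(x$elements),
      "candidate elements (", nret, "retained ),",
      nrow(x$solo_ltrs), "solo-LTRs,", nrow(x$unclassified),
      "unclassified fragments\n")
  invisible(x)
}

#' Extract element sequences in element orientation
#'
#' @param genome Named character vector.
#' @param elements Elements tibble from [discover_elements()].
#' @return The tibble with `element_seq`, `ltr5_seq`, `ltr3_seq` and
#'   `internal_seq` columns added (reverse-complemented for minus-strand
#'   elements so all sequences read 5' to 3' of the element).
#' @export
element_sequences <- function(genome, elements) {
  getseq <- function(chrom, s, e, strand) {
    x <- substring(genome[[chrom]], s + 1L, e)
    if (strand == "-") revcomp(x) else x
  }
  n <- nrow(elements)
  el <- character(n); l5 <- character(n); l3 <- character(n); int <- character(n)
  for (i in seq_len(n)) {
    ch <- elements$chrom[i]; st <- elements$strand[i]
    el[i] <- getseq(ch, elements$start[i], elements$end[i], st)
    l5[i] <- getseq(ch, elements$ltr5_start[i], elements$ltr5_end[i], st)
    l3[i] <- getseq(ch, elements$ltr3_start[i], elements$ltr3_end[i], st)
    int[i] <- getseq(ch, elements$internal_start[i], elements$internal_end[i], st)
  }
  mutate(elements, element_seq = el, ltr5_seq = l5, ltr3_seq = l3,
         internal_seq = int)
}

#' Write and read discovery annotation as GFF3
#'
#' Elements (with LTR and TSD subfeatures) and solo-LTRs, 1-based inclusive
#' coordinates as GFF3 requires; [read_annotation_gff3()] restores the
#' 0-based half-open tibble representation.
#'
#' @param annotation A `te_annotation` from [discover_elements()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  el <- annotation$elements
  rows <- list()
  if (nrow(el)) {
    rows[[1]] <- tibble(chrom = el$chrom, start = el$start, end = el$end,
                        strand = el$strand, type = "LTR_retrotransposon",
                        id = el$element_id, parent = NA_character_)
    rows[[2]] <- tibble(chrom = el$chrom, start = el$ltr5_start,
                        end = el$ltr5_end, strand = el$strand,
                        type = "long_terminal_repeat",
                        id = paste0(el$element_id, "_ltr5"),
                        parent = el$element_id)
    rows[[3]] <- tibble(chrom = el$chrom, start = el$ltr3_start,
                        end = el$ltr3_end, strand = el$strand,
                        type = "long_terminal_repeat",
                        id = paste0(el$element_id, "_ltr3"),
                        parent = el$element_id)
  }
  sl <- annotation$solo_ltrs
  if (nrow(sl)) {
    rows[[length(rows) + 1L]] <- tibble(
      chrom = sl$chrom, start = sl$start, end = sl$end, strand = sl$strand,
      type = "solo_LTR", id = paste0("solo_", sl$chrom, "_", sl$start),
      parent = NA_character_)
  }
  df <- bind_rows(rows)
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Parent <- df$parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         strand = as.character(GenomicRanges::strand(gr)),
         type = as.character(gr$type),
         id = as.character(gr$ID))
}
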