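#' @keywords internal
#' @noRd
encode_seq <- function(x, alphabet) {
  v <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  idx <- match(v, alphabet)
  if (anyNA(idx)) {
    # map unknown residues to N/X when available, else error
    fallback <- if ("N" %in% alphabet) "N" else if ("X" %in% alphabet) "X" else NA
    if (is.na(fallback)) {
      abort(paste0("residues outside alphabet: ",
                   paste(unique(v[is.na(idx)]), collapse = ",")))
    }
    idx[is.na(idx)] <- match(fallback, alphabet)
  }
  idx - 1L
}

#' @keywords internal
#' @noRd
decode_aln <- function(codes, alphabet) {
  out <- character(length(codes))
  out[codes < 0] <- "-"
  out[codes >= 0] <- alphabet[codes[codes >= 0] + 1L]
  paste(out, collapse = "")
}

#' @keywords internal
#' @noRd
new_pairwise_alignment <- function(query_id, subject_id, q_aln, s_aln,
                                   q_span, s_span, score, subject_len,
                                   frame = NA_integer_) {
  qv <- strsplit(q_aln, "", fixed = TRUE)[[1]]
  sv <- strsplit(s_aln, "", fixed = TRUE)[[1]]
  both <- qv != "-" & sv != "-"
  ident <- if (any(both)) mean(qv[both] == sv[both]) else 0
  structure(list(
    query_id = query_id, subject_id = subject_id,
    aligned_query = q_aln, aligned_subject = s_aln,
    query_span = q_span, subject_span = s_span,
    score = score,
    identity_fraction = ident,
    aligned_columns = sum(both),
    subject_coverage = sum(sv != "-") / subject_len,
    frame = frame,
    empty = FALSE
  ), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<pairwise_alignment> no alignment (no positive-scoring cell)\n")
    return(invisible(x))
  }
  cat(sprintf("<pairwise_alignment> %s vs %s  score %.1f  identity %.3f  cols %d\n",
              x$query_id, x$subject_id, x$score, x$identity_fraction,
              x$aligned_columns))
  cat(sprintf("  query [%d,%d)  subject [%d,%d)\n", x$query_span[1],
              x$query_span[2], x$subject_span[1], x$subject_span[2]))
  invisible(x)
}

#' Tidy a pairwise alignment into a one-row tibble
#' @param x A `pairwise_alignment`.
#' @param ... Unused.
#' @export
tidy.pairwise_alignment <- function(x, ...) {
  if (isTRUE(x$empty)) {
    return(tibble(query_id = x$query_id, subject_id = x$subject_id,
                  score = 0, identity_fraction = NA_real_,
                  subject_coverage = NA_real_, query_start = NA_integer_,
                  query_end = NA_integer_, subject_start = NA_integer_,
                  subject_end = NA_integer_))
  }
  tibble(query_id = x$query_id, subject_id = x$subject_id, score = x$score,
         identity_fraction = x$identity_fraction,
         subject_coverage = x$subject_coverage,
         query_start = x$query_span[1], query_end = x$query_span[2],
         subject_start = x$subject_span[1], subject_end = x$subject_span[2])
}

#' Optimal affine-gap local alignment
#'
#' Smith-Waterman alignment with affine gap costs (a gap of length L costs
#' `gap_open + L * gap_extend`). Traceback ties are broken deterministically:
#' diagonal over up (gap in subject) over left (gap in query); the traceback
#' starts at the maximum-scoring cell with the smallest query, then subject,
#' coordinate. When no cell scores above zero the result is an empty
#' alignment with `empty = TRUE` and score 0.
#'
#' @param a Query sequence (single string).
#' @param b Subject sequence (single string).
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @param band Optional band half-width around the (shifted) main diagonal;
#'   0 disables banding. Use only when the optimal path is known to stay near
#'   the diagonal (e.g. copy versus same-family consensus).
#' @param band_shift Diagonal offset of the band centre.
#' @return A `pairwise_alignment` with 0-based half-open spans.
#' @examples
#' local_align("ACGTACGT", "ACGT", scoring_scheme())$identity_fraction
#' @export
local_align <- function(a, b, scheme = scoring_scheme(), query_id = "query",
                        subject_id = "subject", band = 0L, band_shift = 0L) {
  if (!nzchar(a) || !nzchar(b)) abort("empty sequence")
  ab <- scheme$alphabet
  res <- .cpp_align(encode_seq(a, ab), encode_seq(b, ab), scheme$matrix,
                    scheme$gap_open, scheme$gap_extend, FALSE,
                    as.integer(band), as.integer(band_shift))
  if (isTRUE(res$empty)) {
    return(structure(list(query_id = query_id, subject_id = subject_id,
                          score = 0, empty = TRUE),
                     class = "pairwise_alignment"))
  }
  new_pairwise_alignment(query_id, subject_id,
                         decode_aln(res$q_aln, ab), decode_aln(res$s_aln, ab),
                         c(res$q_start, res$q_end), c(res$s_start, res$s_end),
                         res$score, nchar(b))
}

#' @keywords internal
#' @noRd
global_align <- function(a, b, scheme = scoring_scheme(), band = 0L,
                         band_shift = 0L) {
  ab <- scheme$alphabet
  res <- .cpp_align(encode_seq(a, ab), encode_seq(b, ab), scheme$matrix,
                    scheme$gap_open, scheme$gap_extend, TRUE,
                    as.integer(band), as.integer(band_shift))
  list(q_aln = decode_aln(res$q_aln, ab), s_aln = decode_aln(res$s_aln, ab),
       score = res$score)
}

#' Reverse complement of a nucleotide string
#' @param x Single nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  chartr("ACGTNacgtn", "TGCANtgcan",
         vapply(x, function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                                     collapse = ""), character(1),
                USE.NAMES = FALSE))
}

#' Translate a nucleotide sequence (standard code, stops as `*`)
#' @param x Nucleotide string; trailing partial codon is dropped.
#' @return Amino-acid string with `*` for stop codons and `X` for ambiguous
#'   codons.
#' @export
translate_dna <- function(x) {
  x <- toupper(x)
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Best translated local alignment over three reading frames
#'
#' Translates the nucleotide region in the three reading frames of the given
#' strand (standard genetic code; stop codons become `*`, which the default
#' protein scheme scores -4 against everything), locally aligns each frame's
#' protein to the consensus, and returns the best-scoring frame's alignment
#' with `frame` (0, 1 or 2) recorded.
#'
#' @param nucleotide_region Nucleotide string, length >= 3.
#' @param protein_consensus Amino-acid string.
#' @param strand `"+"` or `"-"`; for `"-"` the region is reverse-complemented
#'   before translation.
#' @param scheme Protein [scoring_scheme()]; defaults to [protein_scheme()].
#' @return A `pairwise_alignment` (query = translated region, subject =
#'   protein consensus) with `frame` set, or an empty alignment if no frame
#'   aligns.
#' @export
translated_align <- function(nucleotide_region, protein_consensus,
                             strand = "+", scheme = protein_scheme()) {
  if (nchar(nucleotide_region) < 3) abort("region shorter than one codon")
  stopifnot(strand %in% c("+", "-"))
  region <- if (strand == "-") revcomp(nucleotide_region) else nucleotide_region
  best <- NULL
  for (f in 0:2) {
    aa <- translate_dna(substring(region, f + 1L, nchar(region)))
    if (nchar(aa) == 0) next
    aln <- local_align(aa, protein_consensus, scheme,
                       query_id = paste0("frame", f), subject_id = "consensus")
    if (isTRUE(aln$empty)) next
    aln$frame <- f
    if (is.null(best) || aln$score > best$score) best <- aln
  }
  if (is.null(best)) {
    return(structure(list(query_id = "region", subject_id = "consensus",
                          score = 0, empty = TRUE, frame = NA_integer_),
                     class = "pairwise_alignment"))
  }
  best
}

#' Centre-star progressive multiple alignment
#'
#' Intended for sets of highly similar sequences (the use-case is consensus
#' building from copies of one family). The sequence with the highest summed
#' pairwise identity is picked as the centre; every other sequence is
#' globally aligned to it and gaps are merged under "once a gap, always a
#' gap".
#'
#' @param sequences Named character vector of >= 2 sequences.
#' @param scheme A [scoring_scheme()].
#' @return A `multiple_alignment`: list with `sequence_ids` and equal-length
#'   gapped `rows` (named character vector).
#' @export
progressive_msa <- function(sequences, scheme = scoring_scheme(gap_open = 10,
                                                              gap_extend = 0.2)) {
  n <- length(sequences)
  if (n < 2) abort("need at least two sequences")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_len(n))
  ids <- names(sequences)

  # centre = max summed pairwise identity (local identities, cheap proxy)
  idsum <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      aln <- local_align(sequences[[i]], sequences[[j]], scheme)
      idf <- if (isTRUE(aln$empty)) 0 else aln$identity_fraction *
        aln$aligned_columns / max(nchar(sequences[[i]]), nchar(sequences[[j]]))
      idsum[i] <- idsum[i] + idf
      idsum[j] <- idsum[j] + idf
    }
  }
  centre <- which.max(idsum)
  cs <- sequences[[centre]]
  L <- nchar(cs)
  others <- setdiff(seq_len(n), centre)

  # pairwise global alignments centre-vs-other
  alns <- lapply(others, function(k) global_align(cs, sequences[[k]], scheme))

  # ins[p+1] = max insertions before centre position p (p in 0..L)
  ins <- integer(L + 1)
  parsed <- lapply(alns, function(al) {
    cq <- strsplit(al$q_aln, "", fixed = TRUE)[[1]]
    so <- strsplit(al$s_aln, "", fixed = TRUE)[[1]]
    cpos <- 0L
    run <- 0L
    # per column: centre position it precedes (for insertions) or occupies
    col_cpos <- integer(length(cq))   # centre position of column (1..L, 0 = ins)
    ins_before <- integer(length(cq)) # for ins columns: centre pos they precede
    for (t in seq_along(cq)) {
      if (cq[t] == "-") {
        run <- run + 1L
        col_cpos[t] <- 0L
        ins_before[t] <- cpos + 1L
      } else {
        cpos <- cpos + 1L
        if (run > ins[cpos]) ins[cpos] <<- run
        run <- 0L
        col_cpos[t] <- cpos
      }
    }
    if (run > ins[L + 1L]) ins[L + 1L] <<- run
    list(cq = cq, so = so, col_cpos = col_cpos, ins_before = ins_before)
  })

  # master layout: for centre position p, columns = ins[p] gap slots then p
  width <- sum(ins) + L
  slot_start <- cumsum(c(0L, ins[seq_len(L)] + 1L))  # start offset per position

  build_row <- function(p) {
    row <- rep("-", width)
    # walk the pairwise alignment, placing subject chars
    run_count <- 0L
    for (t in seq_along(p$cq)) {
      if (p$col_cpos[t] == 0L) {
        run_count <- run_count + 1L
        cpos <- p$ins_before[t]
        # left-aligned in the insertion block before centre position cpos
        off <- slot_start[cpos] + run_count
        row[off] <- p$so[t]
      } else {
        run_count <- 0L
        cpos <- p$col_cpos[t]
        off <- slot_start[cpos] + ins[cpos] + 1L
        row[off] <- p$so[t]
      }
    }
    paste(row, collapse = "")
  }

  centre_row <- rep("-", width)
  cv <- strsplit(cs, "", fixed = TRUE)[[1]]
  for (p in seq_len(L)) centre_row[slot_start[p] + ins[p] + 1L] <- cv[p]

  rows <- character(n)
  rows[centre] <- paste(centre_row, collapse = "")
  for (k in seq_along(others)) rows[others[k]] <- build_row(parsed[[k]])
  names(rows) <- ids
  structure(list(sequence_ids = ids, rows = rows),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> ", length(x$rows), " sequences, width ",
      nchar(x$rows[[1]]), "\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus of a multiple alignment
#'
#' Per column the most frequent non-gap residue is emitted; columns whose gap
#' fraction exceeds `gap_column_threshold` are dropped. Ties are broken
#' alphabetically (documented convention) and reported in the `ties`
#' attribute (a tibble of column, winning residue and tied alternatives).
#'
#' @param msa A `multiple_alignment` from [progressive_msa()].
#' @param gap_column_threshold Columns with a gap fraction strictly above
#'   this are dropped (default 0.5).
#' @return Consensus sequence string with attribute `ties`.
#' @export
majority_consensus <- function(msa, gap_column_threshold = 0.5) {
  rows <- msa$rows
  M <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  if (all(M == "-")) abort("all-gap alignment")
  nr <- nrow(M)
  out <- character(0)
  ties <- list()
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    gaps <- sum(col == "-")
    if (gaps / nr > gap_column_threshold) next
    res <- col[col != "-"]
    tab <- sort(table(res), decreasing = TRUE)
    winners <- names(tab)[tab == tab[1]]
    pick <- sort(winners)[1]
    if (length(winners) > 1) {
      ties[[length(ties) + 1L]] <- tibble(column = j, residue = pick,
                                          tied_with = paste(sort(winners)[-1],
                                                            collapse = ","))
    }
    out <- c(out, pick)
  }
  if (length(out) == 0) abort("no columns survive the gap threshold")
  structure(paste(out, collapse = ""),
            ties = if (length(ties)) bind_rows(ties) else
              tibble(column = integer(), residue = character(),
                     tied_with = character()))
}

#' Read/write FASTA
#'
#' Thin wrappers around Biostrings returning and accepting plain named
#' character vectors; sequences are written wrapped at 60 columns.
#'
#' @param path File path.
#' @return `read_fasta()` returns a named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences Named character vector.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
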