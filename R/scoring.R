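#' Scoring schemes for pairwise alignment
#'
#' A scoring scheme bundles match/mismatch scores (or a residue substitution
#' table) with affine gap penalties. A gap of length `L` costs
#' `gap_open + L * gap_extend`, so `gap_open` is the cost of opening a gap on
#' top of the per-residue extension cost. This is the convention under which
#' the classic EMBOSS-style penalty pairs used throughout the package
#' (10/0.2 for consensus building, 10/0.5 for LTR dating, 50/0.1 for
#' copy-versus-consensus alignment) are interpreted.
#'
#' @param match Score for identical residues (ignored when
#'   `substitution_table` is supplied).
#' @param mismatch Score for differing residues (ignored when
#'   `substitution_table` is supplied).
#' @param gap_open Non-negative gap opening penalty.
#' @param gap_extend Non-negative per-residue gap extension penalty; must not
#'   exceed `gap_open`.
#' @param substitution_table Optional square numeric matrix with matching
#'   row/column names giving residue-pair scores (protein alignment).
#' @param alphabet Residue alphabet; derived from the substitution table when
#'   one is given.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme(gap_open = 10, gap_extend = 0.5)
#' @export
scoring_scheme <- function(match = 2, mismatch = -1, gap_open = 10,
                           gap_extend = 0.5, substitution_table = NULL,
                           alphabet = c("A", "C", "G", "T", "N")) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  if (gap_extend > gap_open) {
    abort("gap_extend must not exceed gap_open")
  }
  if (is.null(substitution_table)) {
    ab <- toupper(alphabet)
    S <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
    diag(S) <- match
    if ("N" %in% ab) {
      # N never rewards a match
      S["N", ] <- mismatch
      S[, "N"] <- mismatch
    }
  } else {
    stopifnot(is.matrix(substitution_table),
              nrow(substitution_table) == ncol(substitution_table))
    S <- substitution_table
    ab <- rownames(S)
  }
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, matrix = S, alphabet = ab),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> alphabet:", paste(head(x$alphabet, 8), collapse = ""),
      if (length(x$alphabet) > 8) "...", "\n  gap_open:", x$gap_open,
      " gap_extend:", x$gap_extend, "\n")
  invisible(x)
}

#' Protein scoring scheme based on BLOSUM62
#'
#' BLOSUM62 with the stop symbol `*` rescored to -4 against every residue
#' (including itself), so in-frame stops act as strong mismatches in
#' translated alignments rather than being rewarded.
#'
#' @inheritParams scoring_scheme
#' @return A `scoring_scheme` over the amino-acid alphabet plus `*` and `X`.
#' @export
protein_scheme <- function(gap_open = 10, gap_extend = 0.5) {
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  B <- data_env$BLOSUM62
  keep <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
            "F", "P", "S", "T", "W", "Y", "V", "X", "*")
  B <- B[keep, keep]
  B["*", ] <- -4
  B[, "*"] <- -4
  scoring_scheme(gap_open = gap_open, gap_extend = gap_extend,
                 substitution_table = B)
}
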