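#' Align family copies to the family consensus
#'
#' One local alignment per copy against the family consensus with the 50/0.1
#' copy-versus-consensus penalties. Copies whose alignment covers less than
#' `min_cov` of the consensus are excluded (logged in the `excluded`
#' attribute).
#'
#' @param copies Named character vector of copy sequences (element
#'   orientation).
#' @param consensus Family consensus sequence.
#' @param scheme Scoring scheme (default gap open 50, extend 0.1).
#' @param min_cov Minimum consensus coverage to keep a copy.
#' @param band Band half-width for the banded aligner (copies are
#'   near-collinear with the consensus; default 250, 0 = unbanded).
#' @return Named list of `pairwise_alignment`s (query = copy, subject =
#'   consensus), with attribute `excluded` (character vector of dropped copy
#'   ids).
#' @export
align_copies_to_consensus <- function(copies, consensus,
                                      scheme = scoring_scheme(2, -1, 50, 0.1),
                                      min_cov = 0.5, band = 250L) {
  if (!length(copies)) abort("empty copy set")
  if (is.null(names(copies))) names(copies) <- paste0("copy", seq_along(copies))
  out <- list()
  excluded <- character(0)
  for (id in names(copies)) {
    al <- local_align(copies[[id]], consensus, scheme, query_id = id,
                      subject_id = "consensus", band = band)
    if (isTRUE(al$empty) || al$subject_coverage < min_cov) {
      excluded <- c(excluded, id)
      next
    }
    out[[id]] <- al
  }
  if (!length(out)) abort("no copy aligned to the consensus")
  attr(out, "excluded") <- excluded
  out
}

#' Variant-matrix site filters
#'
#' @param maf_min Minimum minor-allele frequency (default 0.10). The
#'   denominator is the non-missing calls at the site by default; set
#'   `maf_all_copies = TRUE` for the all-copies denominator.
#' @param missing_max Sites with a missing fraction strictly above this are
#'   dropped (default 0.90).
#' @param maf_all_copies Use all copies as the MAF denominator.
#' @return A `matrix_filters` list.
#' @export
matrix_filters <- function(maf_min = 0.10, missing_max = 0.90,
                           maf_all_copies = FALSE) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, missing_max > 0, missing_max <= 1)
  structure(list(maf_min = maf_min, missing_max = missing_max,
                 maf_all_copies = maf_all_copies, substitutions_only = TRUE),
            class = "matrix_filters")
}

#' Build the copy-population variant matrix
#'
#' Combines per-copy alignments against one shared consensus into a single
#' haploid variant matrix over consensus positions. Only substitutions are
#' considered: copy insertions are ignored, deletions (and consensus
#' positions outside a copy's aligned span) become missing data. Sites are
#' retained when the minor-allele frequency is at least `filters$maf_min`
#' and the missing fraction is at most `filters$missing_max`. Multi-allelic
#' sites keep up to 3 alternate alleles (rarer alleles become missing).
#'
#' @param alignments List from [align_copies_to_consensus()].
#' @param filters A [matrix_filters()].
#' @param ages Optional named numeric vector of per-copy insertion ages,
#'   carried as sample metadata.
#' @return A `variant_matrix`: `copy_ids`, `positions` (1-based consensus),
#'   `ref` (consensus allele), `alt` (list of alternate alleles per site),
#'   `geno` (copies x sites integer matrix; 0 = ref, k = k-th alternate, NA
#'   = missing), `maf`, `missing_frac`, `ages`, `consensus_length`.
#' @export
build_matrix <- function(alignments, filters = matrix_filters(), ages = NULL) {
  ids <- names(alignments)
  Lc <- max(vapply(alignments, function(a) a$subject_span[2], numeric(1)))
  calls <- matrix(NA_character_, nrow = length(ids), ncol = Lc,
                  dimnames = list(ids, NULL))
  consb <- rep(NA_character_, Lc)           # consensus base per position
  for (i in seq_along(alignments)) {
    al <- alignments[[i]]
    qv <- strsplit(al$aligned_query, "", fixed = TRUE)[[1]]
    sv <- strsplit(al$aligned_subject, "", fixed = TRUE)[[1]]
    keep <- sv != "-"                       # drop copy insertions
    pos <- cumsum(sv != "-")[keep] + al$subject_span[1]
    base <- qv[keep]
    base[base == "-"] <- NA_character_      # deletions = missing
    calls[i, pos] <- base
    consb[pos] <- sv[keep]
  }
  n <- length(ids)
  keep_site <- logical(Lc)
  ref <- character(Lc); altl <- vector("list", Lc)
  maf <- rep(NA_real_, Lc); missf <- rep(NA_real_, Lc)
  geno_cols <- vector("list", Lc)
  for (p in seq_len(Lc)) {
    col <- calls[, p]
    nm <- !is.na(col)
    missf[p] <- 1 - sum(nm) / n
    if (missf[p] > filters$missing_max) next
    if (!any(nm)) next
    tab <- table(col[nm])
    if (length(tab) < 2) next               # monomorphic
    denom <- if (filters$maf_all_copies) n else sum(nm)
    m <- 1 - max(tab) / denom
    if (m < filters$maf_min - 1e-9) next  # tolerance: exact-boundary MAF passes
    # ref = consensus base; alternates by decreasing count then alphabetical;
    # alleles beyond 3 alternates become missing
    rb <- consb[p]
    alts <- setdiff(names(tab), rb)
    alts <- alts[order(-as.vector(tab[alts]), alts)]
    alleles <- c(rb, alts)
    if (length(alleles) > 4) alleles <- alleles[1:4]
    g <- match(col, alleles) - 1L
    keep_site[p] <- TRUE
    ref[p] <- alleles[1]
    altl[[p]] <- alleles[-1]
    maf[p] <- m
    geno_cols[[p]] <- g
  }
  pos <- which(keep_site)
  geno <- if (length(pos)) do.call(cbind, geno_cols[pos]) else
    matrix(NA_integer_, n, 0)
  dimnames(geno) <- list(ids, as.character(pos))
  if (!length(pos)) warn("all sites filtered: empty variant matrix")
  if (!is.null(ages)) ages <- ages[ids]
  structure(list(copy_ids = ids, positions = pos, ref = ref[pos],
                 alt = altl[pos], geno = geno, maf = maf[pos],
                 missing_frac = missf[pos], ages = ages,
                 consensus_length = Lc, filters = filters),
            class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("<variant_matrix>", length(x$copy_ids), "copies x", length(x$positions),
      "sites (consensus length", x$consensus_length, ")\n")
  invisible(x)
}

#' Tidy a variant matrix into long format
#' @param x A `variant_matrix`.
#' @param ... Unused.
#' @return Tibble: `copy_id`, `position`, `allele_code`, `allele`.
#' @export
tidy.variant_matrix <- function(x, ...) {
  if (!length(x$positions)) {
    return(tibble(copy_id = character(), position = integer(),
                  allele_code = integer(), allele = character()))
  }
  long <- as_tibble(as.table(x$geno), .name_repair = "minimal")
  names(long) <- c("copy_id", "position", "allele_code")
  long$position <- as.integer(as.character(long$position))
  long$allele_code <- as.integer(long$allele_code)
  site_idx <- match(long$position, x$positions)
  allele <- mapply(function(code, si) {
    if (is.na(code)) return(NA_character_)
    if (code == 0L) x$ref[si] else x$alt[[si]][code]
  }, long$allele_code, site_idx)
  mutate(long, allele = as.character(allele))
}

#' Write a variant matrix as haploid VCFv4.2
#'
#' CHROM is the family consensus id, POS the 1-based consensus position, one
#' sample column per copy with haploid GT codes (`.` for missing). INFO
#' carries the site MAF; per-copy insertion ages travel in `##SAMPLE` header
#' lines.
#'
#' @param matrix A `variant_matrix`.
#' @param path Output path.
#' @param family_name Value for the CHROM column.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(matrix, path, family_name = "consensus") {
  x <- matrix
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", family_name, x$consensus_length),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency over non-missing calls\">",
    "##INFO=<ID=MISS,Number=1,Type=Float,Description=\"Missing-call fraction\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">")
  if (!is.null(x$ages)) {
    hdr <- c(hdr, sprintf("##SAMPLE=<ID=%s,AgeYears=%s>", x$copy_ids,
                          format(unname(x$ages), scientific = FALSE,
                                 trim = TRUE)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", x$copy_ids), collapse = "\t"))
  lines <- hdr
  for (s in seq_along(x$positions)) {
    gt <- x$geno[, s]
    gt_str <- ifelse(is.na(gt), ".", as.character(gt))
    lines <- c(lines, paste(c(
      family_name, x$positions[s], ".", x$ref[s],
      paste(x$alt[[s]], collapse = ","), ".", "PASS",
      sprintf("MAF=%.6g;MISS=%.6g", x$maf[s], x$missing_frac[s]),
      "GT", gt_str), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a haploid VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return A `variant_matrix` (round-trip lossless for matrices written by
#'   [write_vcf()]).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "##")]
  body <- lines[!startsWith(lines, "##")]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  ids <- cols[-(1:9)]
  clen <- as.integer(sub(".*length=(\\d+).*", "\\1",
                         hdr[grepl("^##contig", hdr)][1]))
  sample_lines <- hdr[startsWith(hdr, "##SAMPLE=")]
  ages <- NULL
  if (length(sample_lines)) {
    sid <- sub("##SAMPLE=<ID=([^,]+),.*", "\\1", sample_lines)
    sage <- as.numeric(sub(".*AgeYears=([^>]+)>", "\\1", sample_lines))
    ages <- setNames(sage, sid)[ids]
  }
  recs <- body[-1]
  n_sites <- length(recs)
  positions <- integer(n_sites); ref <- character(n_sites)
  altl <- vector("list", n_sites)
  maf <- numeric(n_sites); missf <- numeric(n_sites)
  geno <- matrix(NA_integer_, length(ids), n_sites,
                 dimnames = list(ids, NULL))
  for (s in seq_len(n_sites)) {
    f <- strsplit(recs[s], "\t", fixed = TRUE)[[1]]
    positions[s] <- as.integer(f[2])
    ref[s] <- f[4]
    altl[[s]] <- strsplit(f[5], ",", fixed = TRUE)[[1]]
    maf[s] <- as.numeric(sub(".*MAF=([^;]+).*", "\\1", f[8]))
    missf[s] <- as.numeric(sub(".*MISS=([^;]+).*", "\\1", f[8]))
    gt <- f[-(1:9)]
    geno[, s] <- suppressWarnings(as.integer(gt))
  }
  colnames(geno) <- as.character(positions)
  structure(list(copy_ids = ids, positions = positions, ref = ref,
                 alt = altl, geno = geno, maf = maf, missing_frac = missf,
                 ages = ages, consensus_length = clen,
                 filters = matrix_filters()),
            class = "variant_matrix")
}
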