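#' Chromosomal distribution of elements in fixed-size bins
#'
#' Half-open bins `[i*B, (i+1)*B)`; the last partial bin is included.
#'
#' @param elements Tibble with `chrom`, `start` and a grouping column.
#' @param bin_size_bp Bin width (default 40 Mb).
#' @param group Column to count by (default `subfamily`).
#' @return Tibble: `chrom`, `bin` (0-based index), `bin_start`, plus the
#'   group column and `n`.
#' @export
bin_distribution <- function(elements, bin_size_bp = 40e6,
                             group = "subfamily") {
  stopifnot(group %in% names(elements))
  elements |>
    mutate(bin = floor(.data$start / bin_size_bp)) |>
    count(.data$chrom, .data$bin, .data[[group]]) |>
    mutate(bin_start = .data$bin * bin_size_bp, .after = "bin") |>
    arrange(.data$chrom, .data$bin)
}

#' Activity-through-time table per sub-family and sub-genome
#'
#' Counts dated copies per (sub-family, age bin, sub-genome) — the tabular
#' backbone of activity violin plots — plus per-sub-family age modes and
#' sub-genome proportions. Undated copies are excluded and their count
#' reported in the `undated` attribute.
#'
#' @param elements Tibble with `subfamily`, `age_years` and `subgenome`
#'   columns.
#' @param age_bin_years Age bin width (default 100,000 years).
#' @return List of class `activity_table`: `counts` (sub-family x age bin x
#'   sub-genome), `summary` (per sub-family: n, age mode, sub-genome
#'   proportions in wide columns), attribute-carried `undated` count.
#' @export
activity_table <- function(elements, age_bin_years = 1e5) {
  stopifnot(all(c("subfamily", "age_years", "subgenome") %in%
                  names(elements)))
  undated <- sum(is.na(elements$age_years))
  el <- filter(elements, !is.na(.data$age_years))
  counts <- el |>
    mutate(age_bin = floor(.data$age_years / age_bin_years)) |>
    count(.data$subfamily, .data$age_bin, .data$subgenome) |>
    mutate(age_bin_start = .data$age_bin * age_bin_years,
           .after = "age_bin")
  smry <- el |>
    group_by(.data$subfamily) |>
    summarise(n = n(),
              age_mode_years = histogram_mode(.data$age_years,
                                              age_bin_years),
              .groups = "drop")
  props <- el |>
    count(.data$subfamily, .data$subgenome) |>
    group_by(.data$subfamily) |>
    mutate(prop = .data$n / sum(.data$n)) |>
    ungroup() |>
    select("subfamily", "subgenome", "prop") |>
    tidyr::pivot_wider(names_from = "subgenome", values_from = "prop",
                       names_prefix = "prop_", values_fill = 0)
  smry <- left_join(smry, props, by = "subfamily")
  structure(list(counts = counts, summary = smry, undated = undated,
                 age_bin_years = age_bin_years),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("<activity_table>", nrow(x$summary), "sub-families,",
      sum(x$counts$n), "dated copies (", x$undated, "undated )\n")
  print(x$summary)
  invisible(x)
}

#' Label an introgression segment
#'
#' Naming convention: `"in"` + chromosome + zero-padded start position in
#' Mb, e.g. `in2B093` for a segment starting at 93 Mb on chromosome 2B.
#'
#' @param chrom Chromosome name (a leading `chr` prefix is stripped).
#' @param start_bp Segment start in bp.
#' @return Character label.
#' @export
segment_label <- function(chrom, start_bp) {
  paste0("in", sub("^chr", "", chrom),
         sprintf("%03d", round(start_bp / 1e6)))
}

#' PCA signature of introgression segments against sub-genome controls
#'
#' For each segment the copies inside it are projected together with the
#' per-sub-genome control copies into a PCA of the variant matrix; the
#' segment's PC1/PC2 centroid is compared with each control centroid. The
#' segment is flagged `distinct` when its centroid lies farther from the
#' nearest control centroid than `distinct_factor` times that control's
#' within-cluster dispersion (root-mean-square member-to-centroid
#' distance) — a formalisation of the visual "forms a distinct group"
#' judgement. Segments with fewer than `min_elements` copies are skipped.
#'
#' @param segments Tibble with `label`, `chrom`, `start`, `end` (bp; a
#'   `line` column is carried through if present).
#' @param elements Tibble with `copy_id`, `chrom`, `start` (element
#'   positions).
#' @param matrix A `variant_matrix` over the same copies.
#' @param controls Named list: sub-genome label -> character vector of
#'   control copy ids.
#' @param min_elements Minimum copies per analysed segment (default 40).
#' @param distinct_factor Distance multiple for the distinct flag
#'   (default 2).
#' @param normalization Passed to [run_pca()].
#' @return Tibble: one row per analysed segment with `n_elements`, distance
#'   to each control centroid (`dist_<label>`), `nearest_control`,
#'   `nearest_dispersion`, `distinct`; skipped segments appear with
#'   `skipped = TRUE`.
#' @export
segment_signature <- function(segments, elements, matrix, controls,
                              min_elements = 40L, distinct_factor = 2,
                              normalization = "center") {
  stopifnot(all(c("label", "chrom", "start", "end") %in% names(segments)))
  rows <- list()
  for (i in seq_len(nrow(segments))) {
    seg <- segments[i, ]
    ids <- elements$copy_id[elements$chrom == seg$chrom &
                              elements$start >= seg$start &
                              elements$start < seg$end]
    ids <- intersect(ids, matrix$copy_ids)
    base <- tibble(label = seg$label, n_elements = length(ids))
    if ("line" %in% names(segments)) base$line <- seg$line
    if (length(ids) < min_elements) {
      rows[[i]] <- mutate(base, skipped = TRUE, nearest_control = NA_character_,
                          nearest_dispersion = NA_real_, distinct = NA)
      next
    }
    ctrl_ids <- unlist(controls, use.names = FALSE)
    sub <- subset_matrix(matrix, unique(c(ids, ctrl_ids)))
    pca <- run_pca(sub, normalization = normalization, n_components = 2L)
    pts <- as.matrix(pca$scores[, c("PC1", "PC2")])
    rownames(pts) <- pca$scores$copy_id
    seg_centroid <- colMeans(pts[intersect(ids, rownames(pts)), , drop = FALSE])
    dists <- vapply(names(controls), function(cn) {
      cp <- pts[intersect(controls[[cn]], rownames(pts)), , drop = FALSE]
      sqrt(sum((seg_centroid - colMeans(cp))^2))
    }, numeric(1))
    nearest <- names(controls)[which.min(dists)]
    cp <- pts[intersect(controls[[nearest]], rownames(pts)), , drop = FALSE]
    disp <- sqrt(mean(rowSums(sweep(cp, 2, colMeans(cp))^2)))
    row <- base
    for (cn in names(controls)) row[[paste0("dist_", cn)]] <- dists[[cn]]
    rows[[i]] <- mutate(row, skipped = FALSE, nearest_control = nearest,
                        nearest_dispersion = disp,
                        distinct = min(dists) > distinct_factor * disp)
  }
  bind_rows(rows)
}

#' Subset a variant matrix to a set of copies
#'
#' Sites are kept as-is (filters are not re-applied), so projections of
#' copy subsets stay comparable.
#'
#' @param matrix A `variant_matrix`.
#' @param copy_ids Copies to keep.
#' @return A `variant_matrix` over the subset.
#' @export
subset_matrix <- function(matrix, copy_ids) {
  keep <- matrix$copy_ids %in% copy_ids
  if (!any(keep)) abort("no requested copy is in the matrix")
  out <- matrix
  out$copy_ids <- matrix$copy_ids[keep]
  out$geno <- matrix$geno[keep, , drop = FALSE]
  if (!is.null(matrix$ages)) out$ages <- matrix$ages[keep]
  out
}
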