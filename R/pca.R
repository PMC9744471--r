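#' Principal component analysis of a variant matrix
#'
#' Allele codes are taken as numeric (ref = 0, k-th alternate = k), missing
#' calls are filled with the site mean, sites are centred (and under
#' `"eigenstrat"` scaled by `1/sqrt(p(1-p))` with p the site mean divided by
#' the allele-code range), and principal components are computed by singular
#' value decomposition. A deterministic sign convention is applied: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param matrix A `variant_matrix` (>= 3 copies, >= 2 sites).
#' @param normalization `"center"` (default) or `"eigenstrat"`.
#' @param n_components Number of components to keep (default 10, capped at
#'   the matrix rank).
#' @return A `te_pca`: `scores` tibble (copy_id, PC1..), `variance_explained`
#'   (percent per component), `loadings`, `normalization`, `ages` (if the
#'   matrix carried them).
#' @export
run_pca <- function(matrix, normalization = c("center", "eigenstrat"),
                    n_components = 10L) {
  normalization <- match.arg(normalization)
  x <- matrix
  if (length(x$copy_ids) < 3) abort("need at least 3 copies")
  if (length(x$positions) < 2) abort("need at least 2 sites")
  G <- x$geno * 1.0
  # site-mean imputation of missing calls
  mu <- colMeans(G, na.rm = TRUE)
  for (j in seq_len(ncol(G))) {
    nas <- is.na(G[, j])
    if (any(nas)) G[nas, j] <- mu[j]
  }
  Gc <- sweep(G, 2, mu)
  if (normalization == "eigenstrat") {
    rng <- pmax(1, vapply(seq_along(x$positions), function(j)
      length(x$alt[[j]]), numeric(1)))
    p <- pmin(pmax(mu / rng, 1e-6), 1 - 1e-6)
    Gc <- sweep(Gc, 2, sqrt(p * (1 - p)), "/")
  }
  sv <- svd(Gc)
  pos <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[pos]
  k <- min(n_components, length(d))
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  # sign convention: largest-|loading| positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) { V[, j] <- -V[, j]; U[, j] <- -U[, j] }
  }
  scores <- U %*% diag(d[seq_len(k)], k)
  colnames(scores) <- paste0("PC", seq_len(k))
  ve <- 100 * d^2 / sum(sv$d^2)
  st <- as_tibble(scores)
  st <- mutate(st, copy_id = x$copy_ids, .before = 1)
  if (!is.null(x$ages)) st$age_years <- unname(x$ages[x$copy_ids])
  structure(list(scores = st, variance_explained = ve[seq_len(k)],
                 loadings = V, singular_values = d[seq_len(k)],
                 normalization = normalization, positions = x$positions),
            class = "te_pca")
}

#' @export
print.te_pca <- function(x, ...) {
  cat(sprintf("<te_pca> %d copies, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), length(x$variance_explained),
              x$variance_explained[1],
              if (length(x$variance_explained) > 1) x$variance_explained[2]
              else NA))
  invisible(x)
}

#' @export
tidy.te_pca <- function(x, ...) x$scores

#' @export
glance.te_pca <- function(x, ...) {
  tibble(n_copies = nrow(x$scores),
         n_components = length(x$variance_explained),
         pc1_var = x$variance_explained[1],
         pc2_var = if (length(x$variance_explained) > 1)
           x$variance_explained[2] else NA_real_,
         pc12_var = sum(x$variance_explained[1:min(2, length(x$variance_explained))]),
         normalization = x$normalization)
}

#' Scatter plot of PCA scores
#' @param object A `te_pca`.
#' @param colour_by Optional vector (named by copy_id or in score order) to
#'   colour points by, e.g. sub-family assignments or sub-genomes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.te_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) {
    df$group <- if (!is.null(names(colour_by)))
      colour_by[df$copy_id] else colour_by
  }
  ve <- object$variance_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", ve[1]),
      y = sprintf("PC2 (%.1f%%)", if (length(ve) > 1) ve[2] else NA)) +
    ggplot2::theme_minimal()
  if (!is.null(colour_by)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 1)
  } else {
    p + ggplot2::geom_point(size = 1)
  }
}

#' Define a sub-family region in PC1/PC2 space
#'
#' @param name Sub-family name.
#' @param polygon Two-column matrix or data frame of polygon vertices
#'   (PC1, PC2), not self-intersecting; or NULL with `center`/`radius` for a
#'   circular region.
#' @param center,radius Circle alternative to a polygon.
#' @param core_only Shrink the region toward its member centroid before
#'   assignment (see [assign_subfamilies()]).
#' @return A `subfamily_region`.
#' @export
subfamily_region <- function(name, polygon = NULL, center = NULL,
                             radius = NULL, core_only = FALSE) {
  if (is.null(polygon)) {
    stopifnot(!is.null(center), !is.null(radius))
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    polygon <- cbind(center[1] + radius * cos(th),
                     center[2] + radius * sin(th))
  }
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3) {
    abort("polygon must have >= 3 vertices in 2 columns")
  }
  structure(list(name = name, polygon = polygon, core_only = core_only),
            class = "subfamily_region")
}

#' @keywords internal
#' @noRd
shrink_polygon <- function(poly, factor) {
  ctr <- colMeans(poly)
  sweep(sweep(poly, 2, ctr) * factor, 2, ctr, "+")
}

#' Assign copies to sub-family regions on PC1/PC2
#'
#' Point-in-polygon assignment; copies falling in no region, or in more than
#' one, are `"unassigned"` (with a warning for overlaps). Regions with
#' `core_only` are shrunk toward their centroid by `core_factor` first,
#' mirroring the practice of keeping only the central parts of blurred
#' sub-family clouds.
#'
#' @param pca A `te_pca`.
#' @param regions List of [subfamily_region()] objects.
#' @param core_factor Shrink factor for `core_only` regions (default 0.8).
#' @return Tibble: `copy_id`, `subfamily` (name or "unassigned").
#' @export
assign_subfamilies <- function(pca, regions, core_factor = 0.8) {
  pts <- as.matrix(pca$scores[, c("PC1", "PC2")])
  inside <- vapply(regions, function(r) {
    poly <- if (isTRUE(r$core_only)) shrink_polygon(r$polygon, core_factor)
      else r$polygon
    mgcv::in.out(rbind(poly, poly[1, , drop = FALSE]), pts)
  }, logical(nrow(pts)))
  if (is.null(dim(inside))) inside <- matrix(inside, nrow = 1)
  n_hit <- rowSums(inside)
  if (any(n_hit > 1)) {
    warn(sprintf("%d copies fall in more than one region: unassigned",
                 sum(n_hit > 1)))
  }
  nm <- vapply(regions, `[[`, character(1), "name")
  sf <- rep("unassigned", nrow(pts))
  one <- n_hit == 1
  sf[one] <- nm[apply(inside[one, , drop = FALSE], 1, which)]
  tibble(copy_id = pca$scores$copy_id, subfamily = sf)
}

#' Propose sub-family regions by clustering PC1/PC2
#'
#' Advisory k-means clustering of the first two components; each cluster's
#' convex hull, shrunk slightly toward its centroid, is returned as a
#' proposed region. User-defined regions always override these proposals.
#'
#' @param pca A `te_pca` (>= 10 copies).
#' @param k Number of clusters.
#' @param shrink Hull shrink factor (default 1.05, slight expansion so
#'   boundary points stay inside; use < 1 for cores).
#' @param seed Seed for k-means initialisation.
#' @return List of [subfamily_region()] proposals named `auto1`..`autok`.
#' @export
auto_cluster <- function(pca, k, shrink = 1.05, seed = 1L) {
  pts <- as.matrix(pca$scores[, c("PC1", "PC2")])
  if (nrow(pts) < 10) abort("need at least 10 copies")
  if (k > nrow(pts)) abort("k exceeds the number of copies")
  set.seed(seed)
  km <- kmeans(pts, centers = k, nstart = 10)
  lapply(seq_len(k), function(g) {
    p <- pts[km$cluster == g, , drop = FALSE]
    if (nrow(p) < 3) {
      return(subfamily_region(paste0("auto", g), center = colMeans(p),
                              radius = max(1e-6, max(dist(p)) / 2)))
    }
    hull <- p[grDevices::chull(p), , drop = FALSE]
    subfamily_region(paste0("auto", g), shrink_polygon(hull, shrink))
  })
}

#' Build a consensus sequence per sub-family
#'
#' For each sub-family, `n_pick` members are drawn at random (all members,
#' with a warning, when fewer are available), aligned with the 10/0.2
#' consensus-building penalties and collapsed by majority rule.
#'
#' @param assignment Tibble from [assign_subfamilies()].
#' @param sequences Named character vector of copy sequences.
#' @param n_pick Number of copies to pick (default 10; the working range is
#'   8-13).
#' @param seed Seed for the random pick.
#' @return Named character vector of per-sub-family consensuses.
#' @export
subfamily_consensus <- function(assignment, sequences, n_pick = 10L,
                                seed = 1L) {
  set.seed(seed)
  sf <- setdiff(unique(assignment$subfamily), "unassigned")
  out <- character(0)
  for (s in sf) {
    ids <- assignment$copy_id[assignment$subfamily == s]
    ids <- ids[ids %in% names(sequences)]
    if (!length(ids)) {
      warn(paste("sub-family", s, "has no sequences: skipped"))
      next
    }
    if (length(ids) < n_pick) {
      warn(paste("sub-family", s, "has fewer than", n_pick,
                 "members: using all"))
      pick <- ids
    } else {
      pick <- sample(ids, n_pick)
    }
    cons <- if (length(pick) == 1) unname(sequences[[pick]]) else
      as.character(majority_consensus(progressive_msa(sequences[pick])))
    out[s] <- cons
  }
  out
}
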