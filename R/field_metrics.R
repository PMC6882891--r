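#' Mean of the top-k electric field magnitudes
#'
#' The STRENGTH predictor: the average field magnitude over the `k`
#' strongest voxels inside a compartment mask. `k` can be given either as
#' an absolute voxel count or as a volume fraction of the mask (so coarse
#' grids remain comparable to the high-resolution voxel counts used with
#' individual anatomy). Ties at the k-th value are broken by voxel index
#' order.
#'
#' @param efield A [tes_efield()] map, or a plain numeric vector of field
#'   magnitudes (e.g. from [tes_efield_points()]).
#' @param mask Logical vector over grid voxels (or a compartment label
#'   such as `"brain"`); ignored defaulting to all values when `efield`
#'   is a plain vector.
#' @param k Absolute number of voxels (overrides `frac` when given).
#' @param frac Volume fraction of the mask to average (default 0.7%,
#'   the proportion that 10,000 voxels represent in a ~1.5e6-voxel
#'   1-mm brain segmentation).
#' @return Mean field magnitude (V/m).
#' @export
topk_strength <- function(efield, mask = "brain", k = NULL, frac = 0.007) {
  if (is.numeric(efield)) {
    vals <- if (is.character(mask)) efield else efield[as.logical(mask)]
  } else {
    mask <- resolve_mask(efield$grid, mask)
    if (!any(mask)) stop("mask is empty")
    vals <- efield$magnitude[mask]
  }
  if (length(vals) == 0) stop("mask is empty")
  if (is.null(k)) k <- max(1L, round(frac * length(vals)))
  if (k > length(vals)) stop("k exceeds the number of masked voxels")
  idx <- order(vals, decreasing = TRUE)[seq_len(k)]   # stable: index order on ties
  mean(vals[idx])
}

resolve_mask <- function(grid, mask) {
  if (is.character(mask)) grid$labels %in% mask else as.logical(mask)
}

#' Peripheral (skin and eye) field strengths
#'
#' Control-model predictors: top-k mean field magnitude inside the skin
#' compartment and inside the eye-ball regions (the 10,000-skin-voxel /
#' 1,000-eye-voxel convention of high-resolution segmentations, expressed
#' as volume fractions by default).
#'
#' @inheritParams topk_strength
#' @param skin_mask,eye_mask Masks (labels or logical vectors).
#' @param frac_skin,frac_eye Volume fractions for the two compartments.
#' @param k_skin,k_eye Optional absolute counts.
#' @return Named list `strength_skin`, `strength_eye` (V/m).
#' @export
peripheral_strengths <- function(efield, skin_mask = "skin", eye_mask = "eye",
                                 frac_skin = 0.007, frac_eye = 0.03,
                                 k_skin = NULL, k_eye = NULL) {
  list(strength_skin = topk_strength(efield, skin_mask, k = k_skin, frac = frac_skin),
       strength_eye = topk_strength(efield, eye_mask, k = k_eye, frac = frac_eye))
}

#' Spatial precision of stimulation
#'
#' PRECISION_spat: the Pearson correlation, over masked voxels, between
#' the electric field magnitude and the source-projected alpha topography
#' (neural activity index), quantifying how well the field overlaps the
#' targeted brain activity.
#'
#' @param efield A [tes_efield()] map.
#' @param nai_map A [nai()] source map on the same grid.
#' @param mask Voxel mask (default: the map's brain voxels).
#' @return Pearson r in `[-1, 1]`.
#' @export
spatial_precision <- function(efield, nai_map, mask = NULL) {
  if (!identical(efield$grid$dims, nai_map$grid$dims))
    stop("efield and NAI maps must share a grid")
  idx <- nai_map$vox_idx
  keep <- rep(TRUE, length(idx))
  if (!is.null(mask)) {
    m <- resolve_mask(efield$grid, mask)
    keep <- m[idx]
  }
  x <- efield$magnitude[idx][keep]
  y <- nai_map$values[keep]
  if (sum(keep) < 3) stop("need at least 3 masked voxels")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in field or topography over the mask")
  stats::cor(x, y)
}

#' Pairwise inter-subject field similarity
#'
#' Symmetric matrix of Pearson correlations of the field magnitude over
#' brain voxels of a common grid, across subjects.
#'
#' @param efields List of [tes_efield()] maps on a common grid.
#' @param mask Voxel mask (default `"brain"` of the first map's grid).
#' @return n x n correlation matrix with unit diagonal.
#' @export
intersubject_field_similarity <- function(efields, mask = "brain") {
  if (length(efields) < 2) stop("need at least 2 subjects")
  dims <- efields[[1]]$grid$dims
  for (e in efields)
    if (!identical(e$grid$dims, dims)) stop("all fields must share a common grid")
  m <- resolve_mask(efields[[1]]$grid, mask)
  M <- vapply(efields, function(e) e$magnitude[m], numeric(sum(m)))
  R <- stats::cor(M)
  diag(R) <- 1
  dimnames(R) <- NULL
  R
}

#' Voxel-wise dose-response association
#'
#' For every brain voxel, the across-subject Pearson correlation between
#' the alpha-power change at that voxel and the field magnitude at the
#' same voxel.
#'
#' @param dpower_maps List of per-subject difference `source_map`s on a
#'   common grid (same voxel sets).
#' @param efields List of matching [tes_efield()] maps.
#' @return `source_map` of per-voxel correlations (`kind = "r"`).
#' @export
voxelwise_dose_association <- function(dpower_maps, efields) {
  n <- length(dpower_maps)
  if (n < 3) stop("need at least 3 subjects")
  if (length(efields) != n) stop("one field map per subject is required")
  idx <- dpower_maps[[1]]$vox_idx
  for (d in dpower_maps)
    if (!identical(d$vox_idx, idx)) stop("maps must share a common voxel set")
  D <- vapply(dpower_maps, function(d) d$values, numeric(length(idx)))
  E <- vapply(efields, function(e) e$magnitude[idx], numeric(length(idx)))
  r <- vapply(seq_along(idx), function(v) {
    if (stats::sd(D[v, ]) == 0 || stats::sd(E[v, ]) == 0) return(NA_real_)
    stats::cor(D[v, ], E[v, ])
  }, numeric(1))
  structure(list(values = r, vox_idx = idx, grid = dpower_maps[[1]]$grid,
                 kind = "r", band = dpower_maps[[1]]$band),
            class = "source_map")
}

#' Write a predictor table or similarity matrix as TSV
#'
#' @param x Data frame (predictor table) or matrix.
#' @param path Output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
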