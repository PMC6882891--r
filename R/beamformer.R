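#' Band-limited cross-spectral density matrix
#'
#' Averages the outer products of windowed, zero-padded epoch Fourier
#' coefficients over all epochs and all FFT bins inside the band,
#' producing the Hermitian sensor cross-spectral density (CSD) that drives
#' the DICS beamformer.
#'
#' @param epochs An [epoch()] set (or a list of them, pooled — used for the
#'   common filter across pre/post blocks).
#' @param band Closed frequency band in Hz, e.g. `iaf + c(-2, 2)`.
#' @param window,pad_to_s FFT parameters as in [epoch_spectrum()].
#' @return Object of class `csd_matrix`: `csd` (complex channels x
#'   channels), `band`, `n_epochs`, `n_bins`, `freqs` (band bin centers).
#' @export
band_csd <- function(epochs, band, window = "hanning", pad_to_s = 4) {
  sets <- if (inherits(epochs, "epoch_set")) list(epochs) else epochs
  fs <- sets[[1]]$fs
  if (band[2] <= band[1]) stop("band must have positive width")
  if (band[2] > fs / 2) stop("band exceeds the Nyquist frequency")
  csd_from_fourier(lapply(sets, epoch_fourier, window = window,
                          pad_to_s = pad_to_s), band)
}

# CSD from precomputed epoch Fourier coefficient sets (list of
# epoch_fourier() results, pooled).
csd_from_fourier <- function(ef_list, band) {
  acc <- NULL
  n_ep_tot <- 0L
  n_bins <- NULL
  bfreqs <- NULL
  for (ef in ef_list) {
    sel <- which(ef$freqs >= band[1] - 1e-9 & ef$freqs <= band[2] + 1e-9)
    if (length(sel) == 0) stop("no FFT bins fall inside the band")
    n_bins <- length(sel)
    bfreqs <- ef$freqs[sel]
    d <- dim(ef$coefs)
    nchan <- d[2]
    if (is.null(acc)) acc <- matrix(0 + 0i, nchan, nchan)
    # stack (bin, epoch) rows and accumulate sum_b x_b x_b^H in one product
    A <- matrix(aperm(ef$coefs[sel, , , drop = FALSE], c(1, 3, 2)),
                length(sel) * d[3], nchan)
    acc <- acc + crossprod(A, Conj(A))
    n_ep_tot <- n_ep_tot + d[3]
  }
  csd <- acc / (n_ep_tot * n_bins)
  csd <- (csd + Conj(t(csd))) / 2          # Hermitian by construction
  structure(list(csd = csd, band = band, n_epochs = n_ep_tot,
                 n_bins = n_bins, freqs = bfreqs),
            class = "csd_matrix")
}

#' DICS spatial filters from a common CSD
#'
#' Per-voxel frequency-domain minimum-variance (DICS) filters computed
#' from the regularized real part of the common CSD and the voxel
#' leadfield. The 3-orientation source CSD is collapsed onto its
#' largest-eigenvalue (dominant) orientation, yielding a scalar filter per
#' voxel with unit gain on the collapsed leadfield.
#'
#' @param csd_common A [band_csd()] across all blocks (the common filter).
#' @param leadfield A [meg_leadfield()].
#' @param lambda Regularization. In `"absolute"` mode (default) it is
#'   added to the diagonal in sensor-power units; in `"relative"` mode it
#'   is a fraction of the mean diagonal.
#' @param lambda_mode `"absolute"` or `"relative"`.
#' @return Object of class `dics_filters`: `weights` (n_vox x channels),
#'   `orientation` (n_vox x 3), `vox_idx`, `grid`, `lambda_applied`,
#'   `noise_level` (smallest eigenvalue of the common CSD, the NAI noise
#'   estimate), `band`.
#' @export
dics_filters <- function(csd_common, leadfield, lambda = 1e-12,
                         lambda_mode = c("absolute", "relative")) {
  lambda_mode <- match.arg(lambda_mode)
  C <- Re(csd_common$csd)
  nchan <- nrow(C)
  if (ncol(leadfield$matrix) %% 3L != 0L || nrow(leadfield$matrix) != nchan)
    stop("leadfield and CSD channel sets do not match")
  lam <- if (lambda_mode == "absolute") lambda else lambda * mean(diag(C))
  Creg <- C + diag(lam, nchan)
  rc <- rcond(Creg)
  if (rc < 1e-14) {
    # auto-escalation: relative loading restoring usable conditioning
    lam <- lam + 1e-7 * mean(diag(C))
    Creg <- C + diag(lam, nchan)
    rc <- rcond(Creg)
    if (rc < 1e-14)
      stop(sprintf("regularized CSD numerically singular (rcond = %.3g)", rc))
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  noise_level <- max(min(ev), 0)
  CiL <- solve(Creg, leadfield$matrix)       # channels x 3 n_vox
  CCiL <- C %*% CiL
  nv <- ncol(leadfield$matrix) / 3L
  W <- matrix(0, nv, nchan)
  ori <- matrix(0, nv, 3)
  for (v in seq_len(nv)) {
    cols <- (3L * (v - 1L) + 1L):(3L * v)
    Lv <- leadfield$matrix[, cols, drop = FALSE]
    CiLv <- CiL[, cols, drop = FALSE]
    G <- crossprod(Lv, CiLv)                 # L^T Creg^-1 L (3 x 3)
    Gs <- (G + t(G)) / 2
    # 3x3 source CSD of the vector filter W3 = G^+ L^T Creg^-1, collapsed
    # onto its largest-eigenvalue (dominant) orientation; the pseudo-inverse
    # discards the numerically silent radial direction
    M <- crossprod(CiLv, CCiL[, cols, drop = FALSE])
    gg <- eigen(Gs, symmetric = TRUE)
    keep <- gg$values > max(gg$values) * 1e-10
    Ginv <- gg$vectors[, keep, drop = FALSE] %*%
      (t(gg$vectors[, keep, drop = FALSE]) / gg$values[keep])
    S <- Ginv %*% ((M + t(M)) / 2) %*% Ginv
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    u <- eg$vectors[, which.max(eg$values)]
    ori[v, ] <- u
    lu <- as.vector(Lv %*% u)
    Cilu <- as.vector(CiLv %*% u)
    W[v, ] <- Cilu / sum(lu * Cilu)          # unit gain: w . l_u = 1
  }
  structure(list(weights = W, orientation = ori,
                 vox_idx = leadfield$vox_idx, grid = leadfield$grid,
                 lambda_applied = lam, noise_level = noise_level,
                 band = csd_common$band),
            class = "dics_filters")
}

#' Project band power into source space
#'
#' Applies the common DICS filters to a block CSD: per-voxel source power
#' is the filter quadratic form on the block CSD.
#'
#' @param filters [dics_filters()] from the common CSD.
#' @param csd_block [band_csd()] of one experimental block (same band).
#' @return Object of class `source_map` with `values` (power per brain
#'   voxel), `vox_idx`, `grid`, `band`, `kind = "power"`.
#' @export
project_power <- function(filters, csd_block) {
  C <- Re(csd_block$csd)
  p <- rowSums((filters$weights %*% C) * filters$weights)
  source_map(pmax(p, 0), filters, kind = "power", band = csd_block$band)
}

#' Neural activity index map
#'
#' Noise-normalized source power: `NAI = power / (noise_level * |w|^2)`,
#' countering the center-of-head (depth) bias of the beamformer. The
#' default noise level is the smallest eigenvalue of the common-filter CSD.
#'
#' @inheritParams project_power
#' @param noise_level Noise power estimate; defaults to the value stored
#'   in `filters`.
#' @return `source_map` with `kind = "nai"` (unitless, >= 0).
#' @export
nai <- function(filters, csd_block, noise_level = NULL) {
  if (is.null(noise_level)) noise_level <- filters$noise_level
  if (noise_level <= 0) stop("noise level must be positive")
  C <- Re(csd_block$csd)
  p <- rowSums((filters$weights %*% C) * filters$weights)
  wn <- rowSums(filters$weights^2)
  source_map(pmax(p, 0) / (noise_level * wn), filters, kind = "nai",
             band = csd_block$band)
}

# Internal constructor for brain-voxel maps.
source_map <- function(values, ref, kind, band = NULL) {
  structure(list(values = as.numeric(values), vox_idx = ref$vox_idx,
                 grid = ref$grid, kind = kind, band = band),
            class = "source_map")
}

#' Per-voxel power difference between blocks
#'
#' `post - pre` for two source maps sharing a grid and voxel set.
#'
#' @param pre_map,post_map [project_power()] or [nai()] maps from the same
#'   filters.
#' @return `source_map` with `kind = "difference"`.
#' @export
power_difference <- function(pre_map, post_map) {
  if (!identical(pre_map$vox_idx, post_map$vox_idx) ||
      !identical(pre_map$grid$dims, post_map$grid$dims))
    stop("pre and post maps must share the same grid and voxel set")
  structure(list(values = post_map$values - pre_map$values,
                 vox_idx = pre_map$vox_idx, grid = pre_map$grid,
                 kind = "difference", band = pre_map$band),
            class = "source_map")
}

#' Export a source map to NIfTI-1
#'
#' Writes the map into a full-grid NIfTI volume (non-brain voxels `NA`),
#' with the affine derived from the grid origin and spacing (mm).
#'
#' @param map A `source_map` (or [tes_efield()] magnitude via
#'   `write_efield_nifti`).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  vol <- rep(NA_real_, prod(map$grid$dims))
  vol[map$vox_idx] <- map$values
  write_grid_nifti(vol, map$grid, path)
}

#' @rdname write_map_nifti
#' @param efield A [tes_efield()] map (magnitude is written).
#' @export
write_efield_nifti <- function(efield, path) {
  write_grid_nifti(efield$magnitude, efield$grid, path)
}

write_grid_nifti <- function(values, grid, path) {
  arr <- array(values, grid$dims)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(grid$spacing * 1000, 3)
  aff <- diag(c(grid$spacing * 1000, grid$spacing * 1000,
                grid$spacing * 1000, 1))
  aff[1:3, 4] <- grid$origin * 1000
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a grid map back from NIfTI-1
#'
#' Inverse of [write_map_nifti()]: returns the full-grid value vector and
#' the reconstructed grid geometry (m).
#'
#' @param path NIfTI file path.
#' @return List with `values` (full grid, column-major), `origin`,
#'   `spacing`, `dims`.
#' @export
read_grid_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  list(values = as.vector(img),
       origin = aff[1:3, 4] / 1000,
       spacing = aff[1, 1] / 1000,
       dims = dim(img))
}
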