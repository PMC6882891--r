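# Shared tiny scene: one subject, coarse grid, short session.
bf_scene <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- cohort_config(n_subjects = 2)
    cohort <- sample_cohort(cfg, 7)
    s <- cohort[[1]]
    acq <- acquisition_config(duration_s = 48, iaf_block_s = 16)
    sens <- sensor_array(acq$n_sensors, acq$helmet_radius, head = s$head)
    grid <- voxel_grid(s$head, spacing = 0.016)
    lf <- meg_leadfield(s$head, grid, sens)
    rec_pre <- simulate_session(s, "pre", 1, s$session_seeds[2], acq, sens)
    rec_post <- simulate_session(s, "post", 1.5, s$session_seeds[3], acq, sens)
    ep_pre <- epoch(rec_pre, 2)
    ep_post <- epoch(rec_post, 2)
    band <- s$iaf_true + c(-2, 2)
    csd_all <- band_csd(list(ep_pre, ep_post), band)
    csd_pre <- band_csd(ep_pre, band)
    csd_post <- band_csd(ep_post, band)
    cache <<- list(s = s, sens = sens, grid = grid, lf = lf, band = band,
                   csd_all = csd_all, csd_pre = csd_pre, csd_post = csd_post,
                   ep_pre = ep_pre, acq = acq)
    cache
  }
})

test_that("band CSD is Hermitian, PSD, with the in-band power on its diagonal", {
  sc <- bf_scene()
  C <- sc$csd_all$csd
  expect_equal(C, Conj(t(C)))
  ev <- eigen(C, only.values = TRUE)$values
  expect_true(all(Re(ev) > -1e-8 * max(Re(ev))))
  expect_true(all(abs(Im(ev)) < 1e-8 * max(Re(ev))))
  # diagonal equals the band-average of the per-channel power spectrum
  sp <- epoch_spectrum(sc$ep_pre)
  sel <- sp$freqs >= sc$band[1] - 1e-9 & sp$freqs <= sc$band[2] + 1e-9
  expect_equal(Re(diag(sc$csd_pre$csd)), rowMeans(sp$power[, sel]),
               tolerance = 1e-10)
  expect_error(band_csd(sc$ep_pre, c(10, 500)), "Nyquist")
  expect_error(band_csd(sc$ep_pre, c(10, 9)), "positive width")
})

test_that("a single common sinusoid produces a rank-1 CSD", {
  fs <- 250
  tt <- (seq_len(fs * 20) - 1) / fs
  mix <- c(1, -0.5, 2)
  rec <- structure(list(data = outer(mix, sin(2 * pi * 10 * tt)), fs = fs),
                   class = "session_recording")
  C <- band_csd(epoch(rec, 2), c(8, 12))$csd
  ev <- sort(abs(eigen(C, only.values = TRUE)$values), decreasing = TRUE)
  expect_lt(ev[2] / ev[1], 1e-6)
})

test_that("independent white channels decorrelate as epochs grow", {
  set.seed(9)
  offdiag_level <- function(dur) {
    rec <- structure(list(data = matrix(rnorm(4 * dur * 250), 4), fs = 250),
                     class = "session_recording")
    C <- band_csd(epoch(rec, 2), c(8, 12))$csd
    mean(abs(C[upper.tri(C)])) / mean(Re(diag(C)))
  }
  expect_lt(offdiag_level(480), offdiag_level(16))
})

test_that("DICS filters satisfy unit gain and CSD-scale homogeneity", {
  sc <- bf_scene()
  flt <- dics_filters(sc$csd_all, sc$lf)
  nv <- nrow(flt$weights)
  gains <- vapply(seq_len(nv), function(v) {
    Lv <- sc$lf$matrix[, (3 * v - 2):(3 * v)]
    sum(flt$weights[v, ] * (Lv %*% flt$orientation[v, ]))
  }, numeric(1))
  expect_lt(max(abs(gains - 1)), 1e-6)
  # scaling the block CSD by c scales projected power by c
  p1 <- project_power(flt, sc$csd_pre)
  csd_scaled <- sc$csd_pre
  csd_scaled$csd <- csd_scaled$csd * 3
  p3 <- project_power(flt, csd_scaled)
  expect_equal(p3$values, 3 * p1$values, tolerance = 1e-12)
})

test_that("filters equal the brute-force constrained minimizer per voxel", {
  sc <- bf_scene()
  flt <- dics_filters(sc$csd_all, sc$lf)
  Creg <- Re(sc$csd_all$csd) + diag(flt$lambda_applied, ncol(flt$weights))
  set.seed(4)
  for (v in sample(nrow(flt$weights), 5)) {
    lu <- sc$lf$matrix[, (3 * v - 2):(3 * v)] %*% flt$orientation[v, ]
    # KKT system of min w' C w s.t. w'lu = 1 (independent route)
    nch <- length(lu)
    K <- rbind(cbind(2 * Creg, lu), c(lu, 0))
    sol <- solve(K, c(rep(0, nch), 1))
    expect_equal(flt$weights[v, ], sol[seq_len(nch)], tolerance = 1e-8)
  }
})

test_that("NAI localizes a noiseless dipole to within one grid spacing", {
  sc <- bf_scene()
  # analytic noiseless CSD: source + tiny isotropic floor
  lsrc <- as.vector(tacsdose:::point_leadfield(sc$s$head, sc$s$source_pos,
                                              sc$sens) %*% sc$s$source_ori)
  C <- tcrossprod(lsrc) + diag(1e-6 * mean(lsrc^2), length(lsrc))
  csd0 <- structure(list(csd = C, band = sc$band, n_epochs = 1, n_bins = 1,
                         freqs = NA), class = "csd_matrix")
  flt <- dics_filters(csd0, sc$lf)
  m <- nai(flt, csd0)
  peak <- m$grid$coords[m$vox_idx[which.max(m$values)], ]
  expect_lt(sqrt(sum((peak - sc$s$source_pos)^2)), sc$grid$spacing + 1e-12)
  expect_true(all(m$values >= 0))
})

test_that("NAI is invariant to a global data-scale change", {
  sc <- bf_scene()
  flt <- dics_filters(sc$csd_all, sc$lf)
  n1 <- nai(flt, sc$csd_pre)
  csd_all2 <- sc$csd_all; csd_all2$csd <- csd_all2$csd * 100
  csd_pre2 <- sc$csd_pre; csd_pre2$csd <- csd_pre2$csd * 100
  flt2 <- dics_filters(csd_all2, sc$lf)
  n2 <- nai(flt2, csd_pre2)
  expect_equal(n2$values, n1$values, tolerance = 1e-6)
})

test_that("NAI reduces the depth bias of raw beamformer power", {
  h <- head_model()
  sens <- sensor_array(64, head = h)
  grid <- voxel_grid(h, spacing = 0.016)
  lf <- meg_leadfield(h, grid, sens)
  deep <- c(0.0, 0.01, 0.015)
  shallow <- c(0.0, -0.04, 0.055)
  ori <- c(1, 0, 0)
  l_d <- as.vector(tacsdose:::point_leadfield(h, deep, sens) %*% ori)
  l_s <- as.vector(tacsdose:::point_leadfield(h, shallow, sens) %*% ori)
  C <- tcrossprod(l_d) + tcrossprod(l_s) +
    diag(0.05 * (mean(l_d^2) + mean(l_s^2)), length(l_d))
  csd0 <- structure(list(csd = C, band = c(8, 12), n_epochs = 1, n_bins = 1,
                         freqs = NA), class = "csd_matrix")
  flt <- dics_filters(csd0, lf)
  pw <- project_power(flt, csd0)
  nm <- nai(flt, csd0)
  at <- function(map, pos) {
    d2 <- rowSums(sweep(map$grid$coords[map$vox_idx, ], 2, pos)^2)
    map$values[which.min(d2)]
  }
  ratio_pow <- at(pw, deep) / at(pw, shallow)
  ratio_nai <- at(nm, deep) / at(nm, shallow)
  expect_lt(abs(log(ratio_nai)), abs(log(ratio_pow)))
})

test_that("power difference is post minus pre and guards grid identity", {
  sc <- bf_scene()
  flt <- dics_filters(sc$csd_all, sc$lf)
  p_pre <- project_power(flt, sc$csd_pre)
  p_post <- project_power(flt, sc$csd_post)
  d <- power_difference(p_pre, p_post)
  expect_equal(d$values, p_post$values - p_pre$values)
  expect_equal(power_difference(p_pre, p_pre)$values,
               rep(0, length(p_pre$values)))
  p_bad <- p_post
  p_bad$vox_idx <- p_bad$vox_idx[-1]
  expect_error(power_difference(p_pre, p_bad), "same grid")
  # planted gain raises power at the source voxel
  d2 <- rowSums(sweep(sc$grid$coords[d$vox_idx, ], 2, sc$s$source_pos)^2)
  expect_gt(d$values[which.min(d2)], 0)
})

test_that("source maps survive a NIfTI-1 round trip", {
  sc <- bf_scene()
  flt <- dics_filters(sc$csd_all, sc$lf)
  m <- project_power(flt, sc$csd_pre)
  f <- tempfile(fileext = ".nii.gz")
  write_map_nifti(m, f)
  back <- read_grid_nifti(f)
  expect_equal(back$dims, sc$grid$dims)
  expect_equal(back$spacing, sc$grid$spacing, tolerance = 1e-6)
  expect_equal(back$origin, sc$grid$origin, tolerance = 1e-6)
  vol <- back$values
  expect_equal(vol[m$vox_idx], m$values, tolerance = 1e-6)
  expect_true(all(is.na(vol[-m$vox_idx])))
  unlink(f)
})
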