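#' Ground-truth dose-response parameters
#'
#' The generator-side dose-response function linking a subject's true
#' targeting quality to the planted post-stimulation alpha-amplitude gain:
#'
#' `gain = 1 + b0 + 1[tACS] * g + e`,  `e ~ N(0, noise_sd^2)`,
#'
#' with `g = g_max * f_spat(spat) * (strength / strength_ref) *
#' exp(-mismatch^2 / (2 tau^2))` — monotonically increasing in spatial
#' precision and field strength, decreasing in absolute frequency
#' mismatch. The spatial factor is `exp(gamma * spat)` for the default
#' `"exp"` form (log-linear dose scaling with targeting quality, with no
#' hard floor), `max(spat, 0.05)` for `"linear"`, or `(spat + 1)/2` for
#' `"affine"` (a compressed variant). `b0` is a condition-independent time-on-task gain applied to
#' both arms (the sham alpha increase commonly seen with vigilance
#' decrement); sham subjects receive no stimulation-dependent gain.
#'
#' @param b0 Condition-independent amplitude gain (unitless).
#' @param g_max Maximal stimulation-dependent gain at perfect targeting
#'   and reference strength.
#' @param tau Frequency-mismatch tolerance (Hz).
#' @param strength_ref Reference field strength (V/m) at which the
#'   strength factor equals 1.
#' @param noise_sd Gaussian amplitude-gain noise.
#' @param form Spatial-factor form: `"exp"`, `"linear"` or `"affine"`.
#' @param gamma Log-slope of the `"exp"` spatial factor.
#' @return Object of class `dose_response_truth`.
#' @export
dose_response_truth <- function(b0 = 0.08, g_max = 0.4, tau = 1.0,
                                strength_ref = 0.13, noise_sd = 0.04,
                                form = c("exp", "linear", "affine"),
                                gamma = 3) {
  form <- match.arg(form)
  structure(list(b0 = b0, g_max = g_max, tau = tau,
                 strength_ref = strength_ref, noise_sd = noise_sd,
                 form = form, gamma = gamma),
            class = "dose_response_truth")
}

#' Cohort generation settings
#'
#' Jitter ranges and design parameters for [sample_cohort()]. Defaults
#' emulate the study conditions: a between-subject design with 40 subjects
#' (20 tACS + 20 sham), individual alpha frequencies drawn from 8-12 Hz,
#' a 0.5 Hz session drift of the dominant frequency, and anatomical
#' variability expressed as global head-size scaling, shell-boundary
#' jitter and per-compartment conductivity jitter (largest for the skull,
#' the principal driver of inter-subject field-strength differences).
#'
#' @param design `"between"` (one condition per subject) or `"within"`
#'   (tACS and sham sessions per subject, order counterbalanced).
#' @param n_subjects Cohort size (40 between / 19 within in the emulated
#'   experiments).
#' @param head_scale_sd Log-sd of the global head-size factor.
#' @param shell_jitter_sd Relative sd of individual shell radii.
#' @param cond_sdlog Log-sd of shell conductivities (brain, CSF, skull,
#'   skin).
#' @param source_center Mean alpha-source location (m; posterior-superior
#'   cortex analog).
#' @param source_sd Isotropic sd of the source displacement (m).
#' @param iaf_mean,iaf_sd,iaf_range Individual alpha frequency
#'   distribution (Gaussian, truncated to `iaf_range`).
#' @param drift_mean,drift_sd Mean and sd of the baseline-block drift of
#'   the dominant frequency (Hz). The negative default mean reflects the
#'   slowing of the alpha rhythm with time-on-task between the screening
#'   recording and the baseline block.
#' @param truth A [dose_response_truth()].
#' @param base_head Template anatomy jittered per subject (a
#'   [head_model()]).
#' @return List of class `cohort_config`.
#' @export
cohort_config <- function(design = c("between", "within"), n_subjects = 40,
                          head_scale_sd = 0.025, shell_jitter_sd = 0.008,
                          cond_sdlog = c(0.10, 0.10, 0.35, 0.15),
                          source_center = c(0, -0.0448, 0.0320),
                          source_sd = 0.012,
                          iaf_mean = 10, iaf_sd = 1, iaf_range = c(8, 12),
                          drift_mean = -0.4, drift_sd = 0.5,
                          truth = dose_response_truth(),
                          base_head = head_model()) {
  design <- match.arg(design)
  structure(list(design = design, n_subjects = n_subjects,
                 base_head = base_head,
                 head_scale_sd = head_scale_sd,
                 shell_jitter_sd = shell_jitter_sd,
                 cond_sdlog = cond_sdlog, source_center = source_center,
                 source_sd = source_sd, iaf_mean = iaf_mean,
                 iaf_sd = iaf_sd, iaf_range = iaf_range,
                 drift_mean = drift_mean, drift_sd = drift_sd, truth = truth),
            class = "cohort_config")
}

#' Sample a synthetic cohort
#'
#' Draws a deterministic cohort of synthetic subjects: jittered
#' concentric-shell head geometry, an alpha source (brain location +
#' tangential orientation), a true individual alpha frequency with a
#' baseline-session drift, the integer stimulation frequency, and the
#' condition assignment (counterbalanced groups for the between design,
#' counterbalanced session order for the within design). Jitter draws that
#' produce infeasible geometry (non-increasing radii) or a source outside
#' the brain compartment are resampled; the number of resamples is
#' recorded in the `resampled` attribute.
#'
#' @param config A [cohort_config()].
#' @param seed Integer master seed; the same (config, seed) pair always
#'   yields the identical cohort.
#' @return List of `synthetic_subject`s, each with fields `id`, `head`,
#'   `source_pos`, `source_ori`, `iaf_true`, `drift`, `sf`, `condition`
#'   (between) or `session_order` (within), and `session_seeds`.
#' @export
sample_cohort <- function(config, seed) {
  set.seed(as.integer(seed))
  n <- config$n_subjects
  base <- config$base_head %||% head_model()
  base_radii <- base$shell_radii
  resampled <- 0L
  if (config$design == "between") {
    cond <- sample(rep(c("tacs", "sham"), length.out = n))
  } else {
    orders <- rep(list(c("tacs", "sham"), c("sham", "tacs")), length.out = n)
    orders <- orders[sample.int(n)]
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      scale <- exp(stats::rnorm(1, 0, config$head_scale_sd))
      radii <- base_radii * scale *
        (1 + stats::rnorm(length(base_radii), 0, config$shell_jitter_sd))
      if (all(diff(radii) > 0)) break
      resampled <- resampled + 1L
    }
    conds <- base$shell_conductivities *
      exp(stats::rnorm(length(base_radii), 0, config$cond_sdlog))
    eye_scale <- max(radii) / max(base_radii)   # keep eyes inside the jittered scalp
    head <- head_model(shell_radii = radii, shell_conductivities = conds,
                       eye_centers = base$eye_centers * eye_scale,
                       eye_radius = base$eye_radius * eye_scale)
    repeat {
      src <- config$source_center * scale + stats::rnorm(3, 0, config$source_sd)
      if (sqrt(sum(src^2)) < radii[1] * 0.95) break
      resampled <- resampled + 1L
    }
    rhat <- src / sqrt(sum(src^2))
    tang <- stats::rnorm(3)
    tang <- tang - sum(tang * rhat) * rhat
    tang <- tang / sqrt(sum(tang^2))
    repeat {
      iaf <- stats::rnorm(1, config$iaf_mean, config$iaf_sd)
      if (iaf >= config$iaf_range[1] && iaf <= config$iaf_range[2]) break
    }
    drift <- stats::rnorm(1, config$drift_mean, config$drift_sd)
    subjects[[i]] <- structure(list(
      id = sprintf("S%02d", i), head = head,
      source_pos = src, source_ori = tang,
      iaf_true = iaf, drift = drift,
      sf = stimulation_frequency(iaf),
      condition = if (config$design == "between") cond[i] else NA_character_,
      session_order = if (config$design == "within") orders[[i]] else NULL,
      session_seeds = sample.int(.Machine$integer.max %/% 2L, 6L)),
      class = "synthetic_subject")
  }
  structure(subjects, resampled = resampled, design = config$design,
            class = "synthetic_cohort")
}

#' True targeting predictors of a subject
#'
#' Ground-truth predictor values used by the generator: the top-k field
#' strength inside the subject's brain compartment, the spatial
#' correlation between the field magnitude and the subject's true alpha
#' topography, and the true frequency mismatch
#' `sf - (iaf_true + drift)`.
#'
#' The true alpha topography is, by default, the noise-free imaged
#' topography of the source: the NAI map the beamformer produces for the
#' subject's dipole in the absence of background activity and sensor
#' noise (`topography = "imaged"`, requires `leadfield`). This makes the
#' planted spatial-precision effect recoverable by the pipeline up to
#' estimation noise, rather than being bounded by the point-spread shape
#' mismatch of a purely geometric target. A geometric alternative
#' (`topography = "blob"`, a Gaussian blob of width `blob_sd` around the
#' source) is kept for sensitivity analyses.
#'
#' @param subject A `synthetic_subject`.
#' @param efield The subject's [tes_efield()] map.
#' @param blob_sd Width of the blob topography variant (m).
#' @param leadfield Optional [meg_leadfield()] on the same grid (required
#'   for the imaged topography).
#' @param topography `"imaged"` or `"blob"`.
#' @param acq The [acquisition_config()] whose expected in-band CSD
#'   defines the noise-free imaged topography (source dipole + isotropic
#'   1/f background through the leadfield + sensor noise).
#' @return List `spat`, `strength`, `mismatch`.
#' @export
true_predictors <- function(subject, efield, blob_sd = 0.02,
                            leadfield = NULL,
                            topography = c("imaged", "blob"),
                            acq = acquisition_config()) {
  topography <- match.arg(topography)
  grid <- efield$grid
  if (topography == "imaged" && is.null(leadfield))
    stop("the imaged topography requires a leadfield")
  if (topography == "imaged") {
    csd_clean <- expected_band_csd(subject, leadfield, acq)
    flt <- dics_filters(csd_clean, leadfield)
    topo <- nai(flt, csd_clean)
    spat <- stats::cor(efield$magnitude[leadfield$vox_idx], topo$values)
  } else {
    br <- grid$labels == "brain"
    d2 <- rowSums(sweep(grid$coords[br, , drop = FALSE], 2,
                        subject$source_pos)^2)
    blob <- exp(-d2 / (2 * blob_sd^2))
    spat <- stats::cor(efield$magnitude[br], blob)
  }
  list(spat = spat,
       strength = topk_strength(efield, "brain"),
       mismatch = subject$sf - (subject$iaf_true + subject$drift))
}

#' Expected alpha-band sensor CSD of a subject
#'
#' Analytic expectation of the in-band cross-spectral density implied by
#' the acquisition model: the alpha dipole (all of its power inside the
#' band), the 1/f background dipoles averaged over their random positions
#' and orientations (approximated by the grid-average leadfield outer
#' product, with the in-band fraction of a 1/f power spectrum), and flat
#' sensor noise. Used as the noise-free reference CSD that defines the
#' imaged alpha topography of [true_predictors()].
#'
#' @param subject A `synthetic_subject`.
#' @param leadfield A [meg_leadfield()].
#' @param acq An [acquisition_config()].
#' @param band_width Analysis bandwidth (Hz) for the in-band fractions.
#' @return A `csd_matrix`-classed object (arbitrary overall scale).
#' @export
expected_band_csd <- function(subject, leadfield, acq, band_width = 4) {
  lsrc <- as.vector(point_leadfield(subject$head, subject$source_pos,
                                    leadfield$sensors) %*% subject$source_ori)
  nchan <- length(lsrc)
  # source: amplitude-modulated sinusoid, fully inside the band
  p_src <- 0.5 * (1 + acq$envelope_depth^2) * acq$source_moment^2
  C <- p_src * tcrossprod(lsrc)
  if (acq$n_background > 0) {
    # 1/f power spectrum (flat below 0.5 Hz): in-band fraction around 10 Hz
    f_hi <- acq$fs / 2
    frac <- log(12 / 8) / (1 + log(f_hi / 0.5))
    nv3 <- ncol(leadfield$matrix)
    c_iso <- tcrossprod(leadfield$matrix) / nv3
    C <- C + acq$n_background * acq$background_moment^2 * frac * c_iso
  }
  p_noise <- acq$sensor_noise_sd^2 * band_width / (acq$fs / 2)
  C <- C + diag(p_noise, nchan)
  structure(list(csd = C, band = c(NA, NA), n_epochs = NA, n_bins = NA,
                 freqs = NA),
            class = "csd_matrix")
}

#' Planted post-stimulation amplitude gain
#'
#' Evaluates the ground-truth dose-response function for one subject:
#' sham subjects (or sessions) receive only the condition-independent
#' gain plus noise; tACS adds the targeting-dependent term (see
#' [dose_response_truth()]).
#'
#' @param subject A `synthetic_subject`.
#' @param truth A [dose_response_truth()].
#' @param efield The subject's [tes_efield()] map.
#' @param condition `"tacs"` or `"sham"` (default: the subject's own).
#' @param noise_seed Seed for the gain noise draw (default: the subject's
#'   4th session seed).
#' @param leadfield Optional [meg_leadfield()]; when given, the true
#'   spatial precision uses the imaged topography (see
#'   [true_predictors()]).
#' @return Amplitude gain (unitless), with attribute `truth_g` (the
#'   noiseless stimulation-dependent term).
#' @export
planted_gain <- function(subject, truth, efield,
                         condition = subject$condition,
                         noise_seed = subject$session_seeds[4],
                         leadfield = NULL, acq = acquisition_config()) {
  tp <- true_predictors(subject, efield, leadfield = leadfield,
                        topography = if (is.null(leadfield)) "blob" else "imaged",
                        acq = acq)
  f_spat <- switch(truth$form,
                   affine = (tp$spat + 1) / 2,
                   linear = pmax(tp$spat, 0.05),
                   exp = exp((truth$gamma %||% 3) * tp$spat))
  g <- truth$g_max * f_spat * (tp$strength / truth$strength_ref) *
    exp(-tp$mismatch^2 / (2 * truth$tau^2))
  set.seed(noise_seed)
  eps <- stats::rnorm(1, 0, truth$noise_sd)
  gain <- 1 + truth$b0 + (condition == "tacs") * g + eps
  structure(max(gain, 0.05), truth_g = g, true_predictors = tp)
}

#' Acquisition settings
#'
#' @param fs Sampling rate (Hz).
#' @param duration_s Block duration (s); 520 s = 260 2-s epochs at the
#'   full-scale default.
#' @param iaf_block_s Duration of the short alpha-frequency screening
#'   recording (s).
#' @param source_moment Alpha dipole moment (A m).
#' @param n_background Number of 1/f background dipoles.
#' @param background_moment Moment scale of each background dipole (A m).
#' @param sensor_noise_sd White sensor noise sd per sample (T).
#' @param envelope_depth Relative depth of the slow alpha amplitude
#'   modulation.
#' @param n_sensors,helmet_radius Synthetic magnetometer array geometry.
#' @return List of class `acquisition_config`.
#' @export
acquisition_config <- function(fs = 250, duration_s = 520, iaf_block_s = 180,
                               source_moment = 2e-8, n_background = 12,
                               background_moment = 6e-9,
                               sensor_noise_sd = 3e-14,
                               envelope_depth = 0.25,
                               n_sensors = 64, helmet_radius = 0.11) {
  structure(list(fs = fs, duration_s = duration_s, iaf_block_s = iaf_block_s,
                 source_moment = source_moment, n_background = n_background,
                 background_moment = background_moment,
                 sensor_noise_sd = sensor_noise_sd,
                 envelope_depth = envelope_depth, n_sensors = n_sensors,
                 helmet_radius = helmet_radius),
            class = "acquisition_config")
}

# Smooth positive amplitude envelope: low-pass (< 0.5 Hz) Gaussian noise,
# standardized and clipped away from zero.
slow_envelope <- function(n, fs, depth) {
  if (depth <= 0) return(rep(1, n))
  spec <- stats::rnorm(n) + 1i * stats::rnorm(n)
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  spec[f > 0.5] <- 0
  e <- Re(stats::fft(spec, inverse = TRUE))
  e <- (e - mean(e)) / max(stats::sd(e), 1e-12)
  pmax(1 + depth * e, 0.1)
}

# 1/f-amplitude background signals: k x n matrix.
pink_noise <- function(k, n, fs) {
  f <- (seq_len(n) - 1) * fs / n
  f <- pmin(f, fs - f)
  shape <- ifelse(f > 0.5, 1 / sqrt(f), 1 / sqrt(0.5))
  out <- matrix(0, k, n)
  for (j in seq_len(k)) {
    spec <- (stats::rnorm(n) + 1i * stats::rnorm(n)) * shape
    x <- Re(stats::fft(spec, inverse = TRUE))
    out[j, ] <- x / max(stats::sd(x), 1e-300)
  }
  out
}

#' Simulate one MEG-like session block
#'
#' Generates the sensor time series of one experimental block: the
#' subject's alpha dipole (amplitude-modulated sinusoid at the true
#' individual alpha frequency, shifted by the session drift in the
#' baseline block and scaled by the planted gain in the post block),
#' projected through the spherical-conductor leadfield, plus 1/f
#' background dipole activity and white sensor noise. Deterministic given
#' `(subject, block, gain, seed)`.
#'
#' @param subject A `synthetic_subject`.
#' @param block `"pre"`, `"post"` or `"iaf"` (the short screening block).
#' @param gain Amplitude gain; applied only when `block = "post"`.
#' @param seed Integer seed.
#' @param acq An [acquisition_config()].
#' @param sensors Optional [sensor_array()] (built from `acq` otherwise).
#' @param lf_src Optional precomputed source leadfield column (sensors x 1).
#' @return Object of class `session_recording`: `data` (channels x
#'   samples, T), `fs`, `block`, `duration_s`, `freq_used`.
#' @export
simulate_session <- function(subject, block = c("pre", "post", "iaf"),
                             gain = 1, seed, acq = acquisition_config(),
                             sensors = NULL, lf_src = NULL) {
  block <- match.arg(block)
  set.seed(as.integer(seed))
  if (is.null(sensors))
    sensors <- sensor_array(acq$n_sensors, acq$helmet_radius,
                            head = subject$head)
  dur <- if (block == "iaf") acq$iaf_block_s else acq$duration_s
  n <- as.integer(round(dur * acq$fs))
  tt <- (seq_len(n) - 1) / acq$fs
  f <- if (block == "pre") subject$iaf_true + subject$drift else subject$iaf_true
  amp <- acq$source_moment * (if (block == "post") gain else 1)
  env <- slow_envelope(n, acq$fs, acq$envelope_depth)
  s <- amp * env * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
  if (is.null(lf_src)) {
    lf3 <- point_leadfield(subject$head, subject$source_pos, sensors)
    lf_src <- as.vector(lf3 %*% subject$source_ori)
  }
  data <- outer(lf_src, s)
  if (acq$n_background > 0) {
    nb <- acq$n_background
    rb <- subject$head$shell_radii[1]
    bg_pos <- matrix(stats::rnorm(3 * nb), ncol = 3)
    bg_pos <- bg_pos / sqrt(rowSums(bg_pos^2)) *
      (rb * stats::runif(nb, 0.3, 0.85))
    rhat <- bg_pos / sqrt(rowSums(bg_pos^2))
    o <- matrix(stats::rnorm(3 * nb), ncol = 3)
    o <- o - rowSums(o * rhat) * rhat
    o <- o / sqrt(rowSums(o^2))
    lf3_all <- point_leadfield(subject$head, bg_pos, sensors)
    bg_lf <- vapply(seq_len(nb), function(k)
      as.vector(lf3_all[, (3 * k - 2):(3 * k)] %*% o[k, ]),
      numeric(nrow(sensors$positions)))
    data <- data + (bg_lf * acq$background_moment) %*% pink_noise(nb, n, acq$fs)
  }
  data <- data + matrix(stats::rnorm(length(data), 0, acq$sensor_noise_sd),
                        nrow(data), ncol(data))
  structure(list(data = data, fs = acq$fs, block = block, duration_s = dur,
                 freq_used = f, gain_applied = if (block == "post") gain else 1),
            class = "session_recording")
}

#' Write a cohort manifest as TSV
#'
#' One row per subject: id, condition / session order, true alpha
#' frequency, stimulation frequency, drift, session seeds.
#'
#' @param cohort A [sample_cohort()] result.
#' @param path Output path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- data.frame(
    id = vapply(cohort, `[[`, character(1), "id"),
    condition = vapply(cohort, function(s)
      if (is.na(s$condition) && !is.null(s$session_order))
        paste(s$session_order, collapse = "/") else s$condition, character(1)),
    iaf_true = vapply(cohort, `[[`, numeric(1), "iaf_true"),
    sf = vapply(cohort, `[[`, integer(1), "sf"),
    drift = vapply(cohort, `[[`, numeric(1), "drift"))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
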