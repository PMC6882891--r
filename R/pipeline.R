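#' Pipeline configuration
#'
#' Assembles the full configuration of a synthetic experiment run:
#' cohort block (design, sizes, jitter, dose-response truth), acquisition
#' block (durations, rates, FFT parameters), and analysis block (bands,
#' regularization, grid spacing, top-k fractions, permutations,
#' thresholds, cross-validation definition). Two profiles are bundled:
#' `"full"` mirrors the emulated experiment (520-s blocks = 260 2-s
#' epochs, 10,000 permutations, 10-mm predictor grids) and `"ci"` is the
#' scaled-down profile used by the test suite (short blocks, 1,000
#' permutations, coarser grid).
#'
#' @param profile `"ci"` or `"full"`.
#' @param design `"between"` or `"within"`.
#' @param n_subjects Cohort size (defaults: 40 between, 19 within).
#' @param overrides Nested list merged over the profile defaults (same
#'   structure as the return value).
#' @return Nested list of class `pipeline_config` with blocks `cohort`,
#'   `acquisition`, `analysis`, `design`, `profile`.
#' @export
pipeline_config <- function(profile = c("ci", "full"),
                            design = c("between", "within"),
                            n_subjects = NULL, overrides = NULL) {
  profile <- match.arg(profile)
  design <- match.arg(design)
  if (is.null(n_subjects)) n_subjects <- if (design == "between") 40L else 19L
  full <- profile == "full"
  cfg <- list(
    design = design,
    profile = profile,
    cohort = list(n_subjects = n_subjects,
                  head_scale_sd = 0.025, shell_jitter_sd = 0.008,
                  cond_sdlog = c(0.10, 0.10, 0.35, 0.15),
                  source_center = c(0, -0.0448, 0.0320), source_sd = 0.012,
                  iaf_mean = 10, iaf_sd = 1, iaf_range = c(8, 12),
                  drift_mean = -0.4, drift_sd = 0.5,
                  truth = list(b0 = 0.08, g_max = 0.4, tau = 1.0,
                               strength_ref = 0.13, noise_sd = 0.04,
                               form = "exp", gamma = 3)),
    acquisition = list(fs = 250,
                       duration_s = if (full) 520 else 48,
                       iaf_block_s = if (full) 180 else 16,
                       source_moment = 2e-8, n_background = 12,
                       background_moment = 6e-9, sensor_noise_sd = 3e-14,
                       envelope_depth = 0.25, n_sensors = 64,
                       helmet_radius = 0.11),
    analysis = list(grid_spacing = if (full) 0.010 else 0.016,
                    series_order = 60, cap_angle = 0.26,
                    lambda = 1e-12, lambda_mode = "absolute",
                    epoch_s = 2, pad_to_s = 4, window = "hanning",
                    iaf_band = c(8, 12), band_halfwidth = 2,
                    series_order_peripheral = 150,
                    n_perm = if (full) 10000 else 1000,
                    alpha = 0.05, alpha_form = 0.05,
                    connectivity = 6,
                    montage = list(anode = c(0, 0, 1),
                                   cathode = c(0, -1, 0),
                                   current = 5e-4),
                    frac_brain = 0.007, frac_skin = 0.007, frac_eye = 0.03,
                    bandpass = FALSE, bandpass_range = c(1, 40),
                    r2cv_definition = "corr2",
                    response = "relative",
                    control_bands = full,
                    abs_mismatch = FALSE))
  if (!is.null(overrides)) cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file with the [pipeline_config()] structure; missing
#' entries fall back to the profile defaults named in the file
#' (`profile:` and `design:` keys).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  profile <- y$profile %||% "ci"
  design <- y$design %||% "between"
  n <- y$cohort$n_subjects
  pipeline_config(profile = profile, design = design, n_subjects = n,
                  overrides = y[intersect(names(y),
                                          c("cohort", "acquisition", "analysis"))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Hash of a pipeline configuration
#'
#' Stable content hash recorded in every report for provenance.
#'
#' @param config A `pipeline_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) rlang::hash(unclass(config))

cohort_config_from <- function(config) {
  co <- config$cohort
  cohort_config(design = config$design, n_subjects = co$n_subjects,
                head_scale_sd = co$head_scale_sd,
                shell_jitter_sd = co$shell_jitter_sd,
                cond_sdlog = co$cond_sdlog, source_center = co$source_center,
                source_sd = co$source_sd, iaf_mean = co$iaf_mean,
                iaf_sd = co$iaf_sd, iaf_range = co$iaf_range,
                drift_mean = co$drift_mean, drift_sd = co$drift_sd,
                truth = do.call(dose_response_truth, co$truth))
}

acq_config_from <- function(config) do.call(acquisition_config, config$acquisition)

# Analyze one subject-session pair (pre/post) end to end.
# Returns predictors, difference maps on the common voxel set, and
# band-specific difference maps when requested.
analyze_subject <- function(subject, condition, config, grid, common_brain,
                            seeds, truth, acq, sensors_template = NULL) {
  an <- config$analysis
  sensors <- sensor_array(acq$n_sensors, acq$helmet_radius, head = subject$head)
  mg <- an$montage %||% list(anode = c(0, 0, 1), cathode = c(0, -1, 0),
                             current = 5e-4)
  montage <- electrode_pair(mg$anode, mg$cathode, mg$current,
                            head = subject$head)
  sgrid <- grid
  sgrid$labels <- label_compartments(subject$head, grid$coords)
  efield <- tes_efield(subject$head, montage, sgrid,
                       L = an$series_order, cap_angle = an$cap_angle)
  lf_src <- as.vector(point_leadfield(subject$head, subject$source_pos,
                                      sensors) %*% subject$source_ori)
  # screening block: measured IAF -> integer stimulation frequency
  # (only the posterior channels used for peak detection are transformed)
  post_ch <- posterior_channels(sensors)
  iaf_rec <- simulate_session(subject, "iaf", 1, seeds[1], acq, sensors,
                              lf_src = lf_src)
  iaf_rec$data <- iaf_rec$data[post_ch, , drop = FALSE]
  iaf_sp <- epoch_spectrum(epoch(iaf_rec, an$epoch_s), an$window, an$pad_to_s)
  iaf_hat <- as.numeric(detect_iaf(iaf_sp, an$iaf_band))
  sf <- stimulation_frequency(iaf_hat)
  bgrid <- grid
  bgrid$labels <- ifelse(common_brain, "brain", "outside")
  lf <- meg_leadfield(subject$head, bgrid, sensors)
  gain <- planted_gain(subject, truth, efield, condition = condition,
                       noise_seed = seeds[4], leadfield = lf, acq = acq)
  pre <- simulate_session(subject, "pre", 1, seeds[2], acq, sensors,
                          lf_src = lf_src)
  post <- simulate_session(subject, "post", gain, seeds[3], acq, sensors,
                           lf_src = lf_src)
  if (isTRUE(an$bandpass)) {
    pre <- bandpass_filter(pre, an$bandpass_range[1], an$bandpass_range[2])
    post <- bandpass_filter(post, an$bandpass_range[1], an$bandpass_range[2])
  }
  ep_pre <- epoch(pre, an$epoch_s)
  ep_post <- epoch(post, an$epoch_s)
  ef_pre <- epoch_fourier(ep_pre, an$window, an$pad_to_s)
  ef_post <- epoch_fourier(ep_post, an$window, an$pad_to_s)
  sp_pre <- spectrum_from_fourier(ef_pre, ep_pre, an$window, an$pad_to_s)
  fp <- frequency_mismatch(sf, sp_pre, band = an$iaf_band,
                           abs_mismatch = an$abs_mismatch)
  # beamformer on the cohort-common brain voxel set
  band <- iaf_hat + c(-1, 1) * an$band_halfwidth
  csd_all <- csd_from_fourier(list(ef_pre, ef_post), band)
  flt <- dics_filters(csd_all, lf, lambda = an$lambda,
                      lambda_mode = an$lambda_mode)
  csd_pre <- csd_from_fourier(list(ef_pre), band)
  csd_post <- csd_from_fourier(list(ef_post), band)
  nai_pre <- nai(flt, csd_pre)
  pow_pre <- project_power(flt, csd_pre)
  dpow <- power_difference(pow_pre, project_power(flt, csd_post))
  dnai <- power_difference(nai_pre, nai(flt, csd_post))
  band_dpow <- NULL
  if (isTRUE(an$control_bands)) {
    band_dpow <- lapply(band_definitions(iaf_hat)[c("theta", "beta")],
                        function(b) {
      b[1] <- max(b[1], 1); b[2] <- min(b[2], acq$fs / 2 - 1)
      csd_b <- csd_from_fourier(list(ef_pre, ef_post), b)
      flt_b <- dics_filters(csd_b, lf, lambda = an$lambda,
                            lambda_mode = an$lambda_mode)
      power_difference(
        project_power(flt_b, csd_from_fourier(list(ef_pre), b)),
        project_power(flt_b, csd_from_fourier(list(ef_post), b)))
    })
  }
  # thin skin shell and eye balls are under-sampled by the analysis grid;
  # evaluate peripheral strengths on dedicated compartment point samples
  skin_mag <- tes_efield_points(subject$head, montage,
                                compartment_points(subject$head, "skin", 2000),
                                L = an$series_order_peripheral %||% 150,
                                cap_angle = an$cap_angle)
  eye_mag <- tes_efield_points(subject$head, montage,
                               compartment_points(subject$head, "eye", 600),
                               L = an$series_order,
                               cap_angle = an$cap_angle)
  strengths <- list(
    strength_skin = topk_strength(skin_mag, frac = an$frac_skin),
    strength_eye = topk_strength(eye_mag, frac = an$frac_eye))
  pred <- data.frame(
    id = subject$id, condition = condition,
    iaf_hat = iaf_hat, sf = sf, df = fp$df,
    precision_freq = fp$mismatch,
    precision_spat = spatial_precision(efield, nai_pre),
    strength = topk_strength(efield, "brain", frac = an$frac_brain),
    strength_skin = strengths$strength_skin,
    strength_eye = strengths$strength_eye)
  truth_row <- data.frame(
    id = subject$id, condition = condition,
    gain = as.numeric(gain), truth_g = attr(gain, "truth_g"),
    spat_true = attr(gain, "true_predictors")$spat,
    strength_true = attr(gain, "true_predictors")$strength,
    mismatch_true = attr(gain, "true_predictors")$mismatch,
    iaf_true = subject$iaf_true, drift = subject$drift)
  list(pred = pred, dpow = dpow, dnai = dnai, pow_pre = pow_pre,
       band_dpow = band_dpow, truth = truth_row, efield = efield)
}

# Pick the ROI from a cluster result: most significant cluster if any is
# below alpha, otherwise the largest-mass cluster (flagged in the log).
select_roi <- function(result, alpha) {
  if (length(result$clusters) == 0)
    return(list(mask = integer(0), note = "no suprathreshold cluster"))
  if (result$p[1] <= alpha)
    list(mask = result$clusters[[1]], note = "significant cluster")
  else
    list(mask = result$clusters[[which.max(result$mass)]],
         note = "no significant cluster; largest-mass cluster used")
}

#' Run a full synthetic experiment
#'
#' Executes the complete analysis chain on a generated cohort:
#' cohort sampling, per-subject electric-field simulation, MEG-like
#' session simulation, spectral analysis and frequency predictors, DICS
#' source projection with NAI, group cluster permutation statistics with
#' ROI extraction, and the dose-response regression stage (full-factorial
#' model, all-subsets AIC ranking, per-group models, peripheral control
#' model, LOOCV). The between-subject design reproduces the two-group
#' analysis chain; the within-subject design reproduces the
#' sham-controlled replication chain.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer master seed; the full report is deterministic given
#'   `(config, seed)`.
#' @param verbose Print stage progress.
#' @return Object of class `run_report`; see the package vignette for the
#'   field inventory.
#' @export
run_experiment <- function(config, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  an <- config$analysis
  t_start <- Sys.time()
  log <- character(0)
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  cohort <- sample_cohort(cohort_config_from(config), seed)
  if (attr(cohort, "resampled") > 0)
    say("cohort jitter resamples: %d", attr(cohort, "resampled"))
  truth <- cohort_config_from(config)$truth
  acq <- acq_config_from(config)
  template <- head_model()
  grid <- voxel_grid(template, spacing = an$grid_spacing)
  subj_brain <- vapply(cohort, function(s)
    label_compartments(s$head, grid$coords) == "brain",
    logical(nrow(grid$coords)))
  common_brain <- grid$labels == "brain" & rowSums(!subj_brain) == 0
  say("common grid: %d brain voxels at %.0f mm spacing",
      sum(common_brain), an$grid_spacing * 1000)
  adj_grid <- grid
  adj_grid$labels <- ifelse(common_brain, "brain", "outside")
  adjacency <- grid_adjacency(adj_grid, "brain", an$connectivity)

  if (config$design == "between") {
    res <- lapply(cohort, function(s)
      analyze_subject(s, s$condition, config, grid, common_brain,
                      s$session_seeds[1:4], truth, acq))
    preds <- do.call(rbind, lapply(res, `[[`, "pred"))
    truths <- do.call(rbind, lapply(res, `[[`, "truth"))
    dpow <- vapply(res, function(r) r$dpow$values, numeric(sum(common_brain)))
    is_tacs <- preds$condition == "tacs"
    contrast <- cluster_perm_test(dpow[, is_tacs], dpow[, !is_tacs],
                                  adjacency, paired = FALSE,
                                  n_perm = an$n_perm,
                                  alpha_form = an$alpha_form, tail = "pos",
                                  seed = seed + 1L)
    base_tacs <- cluster_perm_test(dpow[, is_tacs], NULL, adjacency,
                                   paired = TRUE, n_perm = an$n_perm,
                                   alpha_form = an$alpha_form, tail = "pos",
                                   seed = seed + 2L)
    base_sham <- cluster_perm_test(dpow[, !is_tacs], NULL, adjacency,
                                   paired = TRUE, n_perm = an$n_perm,
                                   alpha_form = an$alpha_form, tail = "pos",
                                   seed = seed + 3L)
    roi_tacs <- select_roi(base_tacs, an$alpha)
    roi_sham <- select_roi(base_sham, an$alpha)
    say("tACS ROI: %s (%d voxels); sham ROI: %s (%d voxels)",
        roi_tacs$note, length(roi_tacs$mask),
        roi_sham$note, length(roi_sham$mask))
    fallback <- select_roi(contrast, an$alpha)$mask
    if (length(roi_tacs$mask) == 0) roi_tacs$mask <- fallback
    if (length(roi_sham$mask) == 0) roi_sham$mask <- fallback
    vox_sel <- function(mask) match(mask, adjacency$vox_idx)
    prepow <- vapply(res, function(r) r$pow_pre$values,
                     numeric(sum(common_brain)))
    roi_resp <- function(mask, cols) {
      dv <- colMeans(dpow[vox_sel(mask), cols, drop = FALSE])
      if (identical(an$response, "relative"))
        dv <- dv / colMeans(prepow[vox_sel(mask), cols, drop = FALSE])
      dv
    }
    response <- numeric(nrow(preds))
    response[is_tacs] <- roi_resp(roi_tacs$mask, is_tacs)
    response[!is_tacs] <- roi_resp(roi_sham$mask, !is_tacs)
    preds$response <- response
    pool4 <- c("condition", "precision_spat", "precision_freq", "strength")
    pool3 <- pool4[-1]
    full_fit <- fit_ols(build_design(preds, pool4), response)
    ranking <- all_subsets_selection(preds, pool4, response)
    fit_tacs <- fit_ols(build_design(preds[is_tacs, ], pool3), response[is_tacs])
    fit_sham <- fit_ols(build_design(preds[!is_tacs, ], pool3), response[!is_tacs])
    rank_tacs <- all_subsets_selection(preds[is_tacs, ], pool3, response[is_tacs])
    rank_sham <- all_subsets_selection(preds[!is_tacs, ], pool3, response[!is_tacs])
    periph <- peripheral_model(preds[is_tacs, ], response[is_tacs])
    cv <- loocv(build_design(preds[is_tacs, ], pool3), response[is_tacs],
                definition = an$r2cv_definition)
    band_tests <- NULL
    if (isTRUE(an$control_bands)) {
      band_tests <- lapply(c(theta = "theta", beta = "beta"), function(bn) {
        bmaps <- vapply(res, function(r) r$band_dpow[[bn]]$values,
                        numeric(sum(common_brain)))
        cluster_perm_test(bmaps[, is_tacs], bmaps[, !is_tacs], adjacency,
                          paired = FALSE, n_perm = an$n_perm,
                          alpha_form = an$alpha_form, tail = "pos",
                          seed = seed + 4L)
      })
    }
    report <- list(design = "between", predictors = preds, truth = truths,
                   contrast = contrast, baseline_tacs = base_tacs,
                   baseline_sham = base_sham,
                   roi_tacs = roi_tacs, roi_sham = roi_sham,
                   full_fit = full_fit, ranking = ranking,
                   fit_tacs = fit_tacs, fit_sham = fit_sham,
                   rank_tacs = rank_tacs, rank_sham = rank_sham,
                   peripheral = periph, loocv = cv,
                   band_tests = band_tests,
                   dpow = dpow, grid = grid, common_brain = common_brain,
                   adjacency = adjacency)
  } else {
    n <- length(cohort)
    dpow_tacs <- matrix(0, sum(common_brain), n)
    dpow_sham <- matrix(0, sum(common_brain), n)
    prepow_tacs <- matrix(0, sum(common_brain), n)
    prepow_sham <- matrix(0, sum(common_brain), n)
    pred_rows <- vector("list", n)
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      s <- cohort[[i]]
      for (k in 1:2) {
        condition <- s$session_order[k]
        seeds <- s$session_seeds[(3 * (k - 1) + 1):(3 * k)]
        seeds <- c(seeds, s$session_seeds[4])
        r <- analyze_subject(s, condition, config, grid, common_brain,
                             seeds[c(1, 2, 3, 4)], truth, acq)
        if (condition == "tacs") {
          dpow_tacs[, i] <- r$dpow$values
          prepow_tacs[, i] <- r$pow_pre$values
          pred_rows[[i]] <- r$pred        # predictors from the tACS session
          truth_rows[[i]] <- r$truth
        } else {
          dpow_sham[, i] <- r$dpow$values
          prepow_sham[, i] <- r$pow_pre$values
        }
      }
    }
    preds <- do.call(rbind, pred_rows)
    truths <- do.call(rbind, truth_rows)
    contrast <- cluster_perm_test(dpow_tacs, dpow_sham, adjacency,
                                  paired = TRUE, n_perm = an$n_perm,
                                  alpha_form = an$alpha_form, tail = "pos",
                                  seed = seed + 1L)
    roi <- select_roi(contrast, an$alpha)
    say("condition-contrast ROI: %s (%d voxels)", roi$note, length(roi$mask))
    vox <- match(roi$mask, adjacency$vox_idx)
    resp_tacs <- colMeans(dpow_tacs[vox, , drop = FALSE])
    resp_sham <- colMeans(dpow_sham[vox, , drop = FALSE])
    if (identical(an$response, "relative")) {
      resp_tacs <- resp_tacs / colMeans(prepow_tacs[vox, , drop = FALSE])
      resp_sham <- resp_sham / colMeans(prepow_sham[vox, , drop = FALSE])
    }
    response <- sham_controlled_response(resp_tacs, resp_sham)
    preds$response <- response
    pool3 <- c("precision_spat", "precision_freq", "strength")
    fit3 <- fit_ols(build_design(preds, pool3), response)
    ranking <- all_subsets_selection(preds, pool3, response)
    cv <- loocv(build_design(preds, pool3), response,
                definition = an$r2cv_definition)
    report <- list(design = "within", predictors = preds, truth = truths,
                   contrast = contrast, roi = roi,
                   response_tacs = resp_tacs, response_sham = resp_sham,
                   fit = fit3, ranking = ranking, loocv = cv,
                   dpow_tacs = dpow_tacs, dpow_sham = dpow_sham,
                   grid = grid, common_brain = common_brain,
                   adjacency = adjacency)
  }
  report$seed <- seed
  report$config <- config
  report$config_hash <- config_hash(config)
  report$version <- as.character(utils::packageVersion("tacsdose"))
  report$log <- log
  report$elapsed_s <- as.numeric(Sys.time() - t_start, units = "secs")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> design =", x$design, " seed =", x$seed,
      " hash =", substr(x$config_hash, 1, 8), "\n")
  cat("  subjects:", nrow(x$predictors), "\n")
  if (x$design == "between") {
    cat(sprintf("  tACS vs sham cluster p = %.4g\n",
                if (length(x$contrast$p)) x$contrast$p[1] else NA))
    cat(sprintf("  full model R2 = %.3f; tACS R2 = %.3f; sham R2 = %.3f; LOOCV R2 = %.3f\n",
                x$full_fit$r_squared, x$fit_tacs$r_squared,
                x$fit_sham$r_squared, x$loocv$r_squared_cv))
  } else {
    cat(sprintf("  condition contrast cluster p = %.4g\n",
                if (length(x$contrast$p)) x$contrast$p[1] else NA))
    cat(sprintf("  sham-controlled model R2 = %.3f; LOOCV R2 = %.3f\n",
                x$fit$r_squared, x$loocv$r_squared_cv))
  }
  invisible(x)
}

#' Write report tables and summary
#'
#' Writes the predictor table, model term tables, AIC rankings, cluster
#' summaries and LOOCV predictions as TSV, plus a JSON summary with
#' provenance (config hash, seed, package version).
#'
#' @param report A [run_experiment()] report.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(report$predictors, p("predictors.tsv"))
  write_cluster_tsv(report$contrast, p("cluster_contrast.tsv"))
  if (report$design == "between") {
    write_model_tsv(report$full_fit, report$ranking,
                    p("model_full_terms.tsv"), p("model_ranking.tsv"))
    write_model_tsv(report$fit_tacs, report$rank_tacs,
                    p("model_tacs_terms.tsv"), p("model_ranking_tacs.tsv"))
    write_model_tsv(report$fit_sham, report$rank_sham,
                    p("model_sham_terms.tsv"), p("model_ranking_sham.tsv"))
    write_model_tsv(ranking = report$peripheral$peripheral,
                    path_ranking = p("model_ranking_peripheral.tsv"))
    cvfit <- report$loocv
  } else {
    write_model_tsv(report$fit, report$ranking,
                    p("model_terms.tsv"), p("model_ranking.tsv"))
    cvfit <- report$loocv
  }
  write_tsv(data.frame(observed = cvfit$observed,
                       predicted = cvfit$predictions),
            p("loocv_predictions.tsv"))
  summary <- list(
    design = report$design, seed = report$seed,
    config_hash = report$config_hash, version = report$version,
    n_subjects = nrow(report$predictors),
    contrast_p = if (length(report$contrast$p)) report$contrast$p[1] else NA,
    r_squared_cv = cvfit$r_squared_cv, log = report$log)
  if (report$design == "between") {
    summary$r_squared_full <- report$full_fit$r_squared
    summary$r_squared_tacs <- report$fit_tacs$r_squared
    summary$r_squared_sham <- report$fit_sham$r_squared
    summary$brain_beats_peripheral <- report$peripheral$brain_wins
  } else {
    summary$r_squared <- report$fit$r_squared
  }
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Diagnostic figures from a report
#'
#' Deterministic figure files: predicted-vs-observed scatter of the fitted
#' and cross-validated dose-response model (with the identity diagonal,
#' the line of perfect prediction) and the response against each
#' targeting predictor. Figures whose inputs are empty (e.g. no cluster)
#' are skipped with a logged notice.
#'
#' @param report A [run_experiment()] report.
#' @param dir Output directory.
#' @param format `"pdf"` or `"png"`.
#' @return Character vector of written paths, invisibly.
#' @export
make_figures <- function(report, dir, format = c("pdf", "png")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dev <- if (format == "pdf") grDevices::pdf else
    function(f, ...) grDevices::png(f, width = 900, height = 700, res = 130)
  paths <- character(0)
  emit <- function(name, plot_obj) {
    f <- file.path(dir, paste0(name, ".", format))
    dev(f)
    print(plot_obj)
    grDevices::dev.off()
    paths <<- c(paths, f)
  }
  fit <- if (report$design == "between") report$fit_tacs else report$fit
  dfit <- data.frame(observed = fit$response, predicted = fit$fitted,
                     kind = "fitted")
  dcv <- data.frame(observed = report$loocv$observed,
                    predicted = report$loocv$predictions,
                    kind = "cross-validated")
  dd <- rbind(dfit, dcv)
  emit("predicted_vs_observed",
       ggplot2::ggplot(dd, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
         ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
         ggplot2::geom_point() +
         ggplot2::facet_wrap(~kind) +
         ggplot2::labs(x = "observed Δpower", y = "predicted Δpower",
                       title = "Dose-response model predictions") +
         ggplot2::theme_minimal())
  pr <- report$predictors
  long <- do.call(rbind, lapply(c("precision_spat", "precision_freq", "strength"),
                                function(v) data.frame(predictor = v,
                                                       value = pr[[v]],
                                                       response = pr$response)))
  emit("response_by_predictor",
       ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$response)) +
         ggplot2::geom_point() +
         ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                              linewidth = 0.4) +
         ggplot2::facet_wrap(~predictor, scales = "free_x") +
         ggplot2::labs(x = "predictor value", y = "Δpower") +
         ggplot2::theme_minimal())
  if (length(report$contrast$clusters) > 0) {
    tv <- report$contrast$t
    dnull <- data.frame(mass = report$contrast$null_max_mass)
    emit("cluster_null_distribution",
         ggplot2::ggplot(dnull, ggplot2::aes(x = .data$mass)) +
           ggplot2::geom_histogram(bins = 40) +
           ggplot2::geom_vline(xintercept = report$contrast$mass[1],
                               linetype = 2) +
           ggplot2::labs(x = "max cluster mass (null)",
                         title = "Permutation null vs observed cluster mass") +
           ggplot2::theme_minimal())
  } else {
    message("no cluster in contrast; cluster figure skipped")
  }
  invisible(paths)
}
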