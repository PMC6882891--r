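# Shared cohort-recovery simulations for the acceptance checks: the same
# 50 seeded end-to-end runs serve both the cluster-power check and the
# regression-recovery checks. Cached per session.
recovery_cache <- new.env(parent = emptyenv())

acceptance_profile <- function() {
  pipeline_config("ci", "between",
                  overrides = list(
                    analysis = list(n_perm = 300, grid_spacing = 0.018),
                    acquisition = list(duration_s = 40, iaf_block_s = 12)))
}

recovery_stats <- function(n_seeds = 50) {
  key <- paste0("runs_", n_seeds)
  if (!is.null(recovery_cache[[key]])) return(recovery_cache[[key]])
  cfg <- acceptance_profile()
  rows <- vector("list", n_seeds)
  for (sd in seq_len(n_seeds)) {
    rep <- suppressWarnings(run_experiment(cfg, seed = sd))
    # does the significant contrast cluster cover the cohort source region?
    src_mean <- colMeans(do.call(rbind, lapply(
      sample_cohort(cohort_config_from(cfg), sd), `[[`, "source_pos")))
    src_vox <- rep$adjacency$vox_idx[which.min(rowSums(
      sweep(rep$grid$coords[rep$adjacency$vox_idx, ], 2, src_mean)^2))]
    sig <- length(rep$contrast$p) > 0 && rep$contrast$p[1] <= 0.05
    covered <- sig && src_vox %in% rep$contrast$clusters[[1]]
    rows[[sd]] <- data.frame(
      seed = sd,
      p_contrast = if (length(rep$contrast$p)) rep$contrast$p[1] else NA,
      significant = sig, source_covered = covered,
      r2_tacs = rep$fit_tacs$r_squared,
      r2_sham = rep$fit_sham$r_squared,
      full_wins_tacs = rep$rank_tacs$table$n_factors[1] == 3,
      sham_winner = rep$rank_sham$table$model[1],
      brain_beats_peripheral = rep$peripheral$brain_wins,
      r2_cv = rep$loocv$r_squared_cv)
  }
  out <- do.call(rbind, rows)
  recovery_cache[[key]] <- out
  out
}
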