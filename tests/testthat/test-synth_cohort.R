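test_that("cohort sampling is deterministic and counterbalanced", {
  cfg <- cohort_config(n_subjects = 12)
  c1 <- sample_cohort(cfg, 99)
  c2 <- sample_cohort(cfg, 99)
  expect_identical(c1, c2)
  c3 <- sample_cohort(cfg, 100)
  expect_false(identical(c1[[1]]$head, c3[[1]]$head))
  conds <- vapply(c1, `[[`, character(1), "condition")
  expect_equal(sum(conds == "tacs"), 6)
  expect_equal(sum(conds == "sham"), 6)
  iafs <- vapply(c1, `[[`, numeric(1), "iaf_true")
  expect_true(all(iafs >= 8 & iafs <= 12))
  for (s in c1) {
    expect_true(all(diff(s$head$shell_radii) > 0))
    expect_lt(sqrt(sum(s$source_pos^2)), s$head$shell_radii[1])
    expect_equal(sum(s$source_ori * s$source_pos), 0, tolerance = 1e-9)
    expect_equal(sqrt(sum(s$source_ori^2)), 1, tolerance = 1e-12)
    expect_identical(s$sf, stimulation_frequency(s$iaf_true))
  }
})

test_that("a 40-subject between cohort splits 20 tACS / 20 sham", {
  conds <- vapply(sample_cohort(cohort_config(n_subjects = 40), 1),
                  `[[`, character(1), "condition")
  expect_equal(as.vector(table(conds)[c("sham", "tacs")]), c(20, 20))
})

test_that("within-design cohorts counterbalance session order", {
  cfg <- cohort_config(design = "within", n_subjects = 10)
  cohort <- sample_cohort(cfg, 3)
  orders <- vapply(cohort, function(s) s$session_order[1], character(1))
  expect_equal(sort(as.vector(table(orders))), c(5, 5))
  expect_true(all(vapply(cohort, function(s)
    setequal(s$session_order, c("tacs", "sham")), logical(1))))
})

test_that("zero jitter collapses anatomy to the template", {
  cfg <- cohort_config(n_subjects = 3, head_scale_sd = 0, shell_jitter_sd = 0,
                       cond_sdlog = rep(0, 4), source_sd = 0)
  cohort <- sample_cohort(cfg, 5)
  base <- head_model()
  for (s in cohort) {
    expect_equal(s$head$shell_radii, base$shell_radii)
    expect_equal(s$head$shell_conductivities, base$shell_conductivities)
    expect_equal(s$source_pos, cfg$source_center)
  }
})

test_that("planted gain obeys the dose-response construction", {
  cfg <- cohort_config(n_subjects = 2)
  cohort <- sample_cohort(cfg, 21)
  s <- cohort[[1]]
  grid <- voxel_grid(s$head, spacing = 0.016)
  ef <- tes_efield(s$head, electrode_pair(head = s$head), grid)
  truth <- dose_response_truth(noise_sd = 0)
  g_tacs <- planted_gain(s, truth, ef, condition = "tacs")
  g_sham <- planted_gain(s, truth, ef, condition = "sham")
  # sham gain is field-independent: 1 + b0 exactly at zero noise
  expect_equal(as.numeric(g_sham), 1 + truth$b0)
  expect_gt(as.numeric(g_tacs), as.numeric(g_sham))
  expect_equal(as.numeric(g_tacs) - as.numeric(g_sham),
               attr(g_tacs, "truth_g"))
  # monotonicity: zero mismatch and boosted spat/strength raise g
  tp <- attr(g_tacs, "true_predictors")
  s2 <- s; s2$drift <- s$sf - s$iaf_true       # zero true mismatch
  g_best <- planted_gain(s2, truth, ef, condition = "tacs")
  expect_gte(attr(g_best, "truth_g"), attr(g_tacs, "truth_g") - 1e-12)
})

test_that("gain noise matches its analytic moments over many draws", {
  cfg <- cohort_config(n_subjects = 2)
  cohort <- sample_cohort(cfg, 31)
  s <- cohort[[1]]
  grid <- voxel_grid(s$head, spacing = 0.018)
  ef <- tes_efield(s$head, electrode_pair(head = s$head), grid)
  truth <- dose_response_truth(noise_sd = 0.05)
  draws <- vapply(seq_len(1000), function(k)
    as.numeric(planted_gain(s, truth, ef, condition = "sham",
                            noise_seed = k)), numeric(1))
  # gain ~ N(1 + b0, noise_sd^2): Monte-Carlo check of both moments
  expect_equal(mean(draws), 1 + truth$b0, tolerance = 4 * 0.05 / sqrt(1000))
  expect_equal(stats::sd(draws), 0.05, tolerance = 0.1)
})

test_that("session simulation is deterministic and the planted gain scales alpha power", {
  cfg <- cohort_config(n_subjects = 2)
  cohort <- sample_cohort(cfg, 41)
  s <- cohort[[1]]
  acq <- acquisition_config(duration_s = 48, n_background = 0,
                            sensor_noise_sd = 1e-16)
  r1 <- simulate_session(s, "post", 1.5, seed = 77, acq)
  r2 <- simulate_session(s, "post", 1.5, seed = 77, acq)
  expect_identical(r1$data, r2$data)
  band_power <- function(rec) {
    sp <- epoch_spectrum(epoch(rec, 2))
    sel <- sp$freqs >= s$iaf_true - 2 & sp$freqs <= s$iaf_true + 2
    mean(sp$power[, sel])
  }
  g <- 1.7
  p_pre <- band_power(simulate_session(s, "post", 1, seed = 5, acq))
  p_post <- band_power(simulate_session(s, "post", g, seed = 5, acq))
  expect_equal(p_post / p_pre, g^2, tolerance = 1e-3)
  # gain = 1: pre and post alpha power agree in expectation (same seed)
  p_pre2 <- band_power(simulate_session(s, "pre", 1, seed = 6, acq))
  p_post2 <- band_power(simulate_session(s, "post", 1, seed = 6, acq))
  expect_equal(p_post2 / p_pre2, 1, tolerance = 0.2)
})

test_that("the session spectrum peaks at the planted frequency", {
  cfg <- cohort_config(n_subjects = 3)
  cohort <- sample_cohort(cfg, 51)
  acq <- acquisition_config(duration_s = 48, iaf_block_s = 16)
  for (s in cohort[1:2]) {
    rec <- simulate_session(s, "iaf", 1, s$session_seeds[1], acq)
    sp <- epoch_spectrum(epoch(rec, 2))
    sens <- sensor_array(acq$n_sensors, acq$helmet_radius, head = s$head)
    iaf_hat <- detect_iaf(sp, channels = posterior_channels(sens))
    expect_lt(abs(as.numeric(iaf_hat) - s$iaf_true), 0.25 + 1e-9)
  }
})

test_that("default jitter produces a field-strength spread on the reported order", {
  cfg <- cohort_config(n_subjects = 12)
  cohort <- sample_cohort(cfg, 61)
  grid <- voxel_grid(head_model(), spacing = 0.016)
  strengths <- vapply(cohort, function(s) {
    sg <- grid
    sg$labels <- label_compartments(s$head, grid$coords)
    ef <- tes_efield(s$head, electrode_pair(head = s$head), sg)
    topk_strength(ef, "brain")
  }, numeric(1))
  # order-of-magnitude check against the observed 0.08-0.36 V/m range
  expect_gt(stats::median(strengths), 0.02)
  expect_lt(stats::median(strengths), 0.8)
  expect_gt(max(strengths) / min(strengths), 1.5)
})

test_that("cohort manifests are written as TSV", {
  cohort <- sample_cohort(cohort_config(n_subjects = 4), 71)
  f <- tempfile(fileext = ".tsv")
  write_cohort_tsv(cohort, f)
  tab <- utils::read.delim(f)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("id", "condition", "iaf_true", "sf", "drift") %in%
                    names(tab)))
  unlink(f)
})
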