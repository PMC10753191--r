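test_that("baseline correction removes offsets and estimates noise", {
  p <- twitch_params(baseline_Nm = 0.3, noise_sd_Nm = 0)
  tr <- baseline_correct(simulate_twitch(p))
  expect_equal(trace_meta(tr)$baseline_Nm, 0.3, tolerance = 1e-12)
  expect_equal(max(tr$torque_Nm), p$amplitude_Nm, tolerance = 1e-10)
  # offset-added trace equals the original after correction
  tr0 <- simulate_twitch(twitch_params(noise_sd_Nm = 0))
  tr1 <- tr0; tr1$torque_Nm <- tr1$torque_Nm + 0.3
  expect_equal(baseline_correct(tr1)$torque_Nm, baseline_correct(tr0)$torque_Nm,
               tolerance = 1e-12)
  # window must fit before the stimulus
  early <- simulate_twitch(twitch_params(t0_s = 0.002))
  expect_error(baseline_correct(early, 0.05), "too early")
  # Monte-Carlo: baseline error is CLT-sized for a 50 ms window
  errs <- vapply(1:200, function(s) {
    trn <- simulate_twitch(twitch_params(noise_sd_Nm = 0.1, baseline_Nm = 1), seed = s)
    trace_meta(baseline_correct(trn, 0.05))$baseline_Nm - 1
  }, numeric(1))
  expect_lt(max(abs(errs)), 4 * 0.1 / sqrt(50))
})

test_that("contraction times interpolate threshold crossings from stimulus onset", {
  # linear ramp: torque(t) = t on [0, 1], peak 1 -> time to 50% = 0.5 s
  tt <- seq(0, 1, 1e-3)
  tr <- make_test_trace(tt, tt, kind = "twitch", stim_onset = 0, stim_end = 1)
  tr <- musclephys:::set_trace_meta(tr, baseline_corrected = TRUE, baseline_Nm = 0,
                                    prestim_noise_sd_Nm = 0)
  con <- contraction_features(tr)
  ct <- con$contraction_times[[1]]
  expect_equal(ct$time_s[ct$fraction == 0.5], 0.5, tolerance = 1e-9)
  expect_equal(con$absolute_force_N, con$reference_Nm / 0.1)
  expect_equal(con$relative_force_N_per_kg, con$absolute_force_N / 10)
  # tetanus closed form: time to 95% of end-stim torque
  te <- baseline_correct(simulate_tetanus(tetanus_params(tau_rise_s = 0.1,
                                                         noise_sd_Nm = 0)))
  cte <- contraction_features(te)$contraction_times[[1]]
  expect_equal(cte$time_s[cte$fraction == 0.95],
               -0.1 * log(1 - 0.95 * (1 - exp(-10))), tolerance = 1e-3)
  expect_true(all(diff(cte$time_s) >= 0))
})

test_that("coarse-grid decile times agree with a dense-grid oracle within 1 ms", {
  p_coarse <- twitch_params(tau_rise_s = 0.012, tau_fast_relax_s = 0.05,
                            slow_fraction = 0.2, noise_sd_Nm = 0, sampling_hz = 1000)
  p_dense <- p_coarse; p_dense$sampling_hz <- 100000
  f_coarse <- contraction_features(baseline_correct(simulate_twitch(p_coarse)))
  f_dense <- contraction_features(baseline_correct(simulate_twitch(p_dense)))
  expect_lt(max(abs(f_coarse$contraction_times[[1]]$time_s -
                      f_dense$contraction_times[[1]]$time_s)), 1e-3)
  r_coarse <- relaxation_features(baseline_correct(simulate_twitch(p_coarse)))
  r_dense <- relaxation_features(baseline_correct(simulate_twitch(p_dense)))
  expect_lt(max(abs(r_coarse$relaxation_times[[1]]$time_s -
                      r_dense$relaxation_times[[1]]$time_s)), 1e-3)
})

test_that("relaxation features match closed forms and flag unreached fractions", {
  tr <- baseline_correct(simulate_twitch(twitch_params(slow_fraction = 0,
                                                       tau_fast_relax_s = 0.05,
                                                       noise_sd_Nm = 0)))
  rl <- relaxation_features(tr)$relaxation_times[[1]]
  expect_equal(rl$time_s[rl$fraction == 0.95], -0.05 * log(0.05), tolerance = 1e-3)
  # biexponential vs brute-force root find
  tr2 <- baseline_correct(simulate_twitch(twitch_params(slow_fraction = 0.3,
                                                        tau_fast_relax_s = 0.04,
                                                        tau_slow_relax_s = 1.0,
                                                        duration_s = 3,
                                                        noise_sd_Nm = 0)))
  rl2 <- relaxation_features(tr2)$relaxation_times[[1]]
  for (fr in c(0.5, 0.9, 0.95)) {
    expect_equal(rl2$time_s[rl2$fraction == fr],
                 oracle_twitch_relax_time(fr, 0.04, 1.0, 0.3), tolerance = 1e-3)
  }
  expect_true(all(diff(rl2$time_s) >= 0))
  # truncated record: 95% unreached but earlier deciles reported
  tr3 <- baseline_correct(simulate_twitch(twitch_params(slow_fraction = 0.4,
                                                        tau_slow_relax_s = 2,
                                                        duration_s = 0.4,
                                                        noise_sd_Nm = 0)))
  rl3 <- relaxation_features(tr3)$relaxation_times[[1]]
  expect_false(rl3$reached[rl3$fraction == 0.95])
  expect_true(rl3$reached[rl3$fraction == 0.5])
})

test_that("twitch:tetanus ratio divides peak by end-stimulation torque", {
  tw <- contraction_features(baseline_correct(
    simulate_twitch(twitch_params(amplitude_Nm = 3.7, tau_rise_s = 0.005,
                                  noise_sd_Nm = 0))))
  te <- contraction_features(baseline_correct(
    simulate_tetanus(tetanus_params(plateau_Nm = 14.8, tau_rise_s = 0.02,
                                    noise_sd_Nm = 0))))
  expect_equal(twitch_tetanus_ratio(tw, te), 0.25, tolerance = 2e-3)
  te_eq <- contraction_features(baseline_correct(
    simulate_tetanus(tetanus_params(plateau_Nm = 3.7, tau_rise_s = 0.02,
                                    noise_sd_Nm = 0))))
  expect_equal(twitch_tetanus_ratio(tw, te_eq), 1, tolerance = 2e-3)
  bad <- te; bad$end_stim_torque_Nm <- 0
  expect_error(twitch_tetanus_ratio(tw, bad), "positive")
})

test_that("QC rules fire on constructed defects and pass clean traces", {
  cfg <- default_config()
  clean <- baseline_correct(simulate_twitch(twitch_params(noise_sd_Nm = 0.01), seed = 3))
  expect_equal(qc_trace(clean, cfg)$qc_status, "pass")
  expect_equal(qc_trace(clean, cfg)$qc_reasons, "")
  # (b) inserted negative dip of -0.5 peak
  dip <- clean
  dip$torque_Nm[300:320] <- -0.5 * max(dip$torque_Nm)
  expect_match(qc_trace(dip, cfg)$qc_reasons, "negative_deflection")
  # (c) double-peaked twitch
  dbl <- clean
  dbl$torque_Nm[400:450] <- 0.9 * max(clean$torque_Nm)
  dbl$torque_Nm[350:399] <- 0.1 * max(clean$torque_Nm)
  dbl$torque_Nm[500:550] <- 0.8 * max(clean$torque_Nm)
  dbl$torque_Nm[451:499] <- 0.1 * max(clean$torque_Nm)
  expect_match(qc_trace(dbl, cfg)$qc_reasons, "multiple_peaks")
  # (d) plateau collapse in a tetanus
  tet <- baseline_correct(simulate_tetanus(tetanus_params(noise_sd_Nm = 0.01), seed = 4))
  expect_equal(qc_trace(tet, cfg)$qc_status, "pass")
  coll <- tet
  mid <- which(coll$time_s > 0.6 & coll$time_s < 0.8)
  coll$torque_Nm[mid] <- 0.3 * coll$torque_Nm[mid]
  expect_match(qc_trace(coll, cfg)$qc_reasons, "plateau_collapse")
})

test_that("a corrupted batch is rejected exactly where corrupted", {
  corrupt_idx <- as.integer(seq(5, 95, by = 10))
  status <- vapply(1:100, function(i) {
    tr <- baseline_correct(simulate_twitch(twitch_params(noise_sd_Nm = 0.02), seed = i))
    if (i %in% corrupt_idx) tr$torque_Nm[250:270] <- -0.6 * max(tr$torque_Nm)
    qc_trace(tr)$qc_status
  }, character(1))
  expect_identical(which(status == "reject"), corrupt_idx)
})
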