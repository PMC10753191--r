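test_that("plateau torque reads the pre-rotation window correctly", {
  pp <- ecd_protocol_params(tetanus = tetanus_params(plateau_Nm = 5, tau_rise_s = 0.02,
                                                     stim_duration_s = 0.8,
                                                     post_window_s = 0.5,
                                                     noise_sd_Nm = 0),
                            r_inf = 1)
  tr <- simulate_ecd_protocol(pp, seed = 1)$traces[[1]]
  expect_equal(plateau_torque(tr, 0.010), 5, tolerance = 1e-4)
  # degenerate window: single-sample read just before rotation
  expect_equal(plateau_torque(tr, 0), 5, tolerance = 1e-4)
  expect_error(plateau_torque(tr, 0.6), "before stimulus onset")
  # window-length robustness under noise: 10 vs 20 ms reads stay close
  ppn <- ecd_protocol_params(tetanus = tetanus_params(plateau_Nm = 5,
                                                      stim_duration_s = 0.8,
                                                      post_window_s = 0.5,
                                                      noise_sd_Nm = 0.05),
                             r_inf = 1)
  diffs <- vapply(1:40, function(s) {
    trn <- simulate_ecd_protocol(ppn, seed = s)$traces[[1]]
    plateau_torque(trn, 0.010) - plateau_torque(trn, 0.020)
  }, numeric(1))
  expect_lt(sd(diffs), 0.05 / sqrt(10))
})

test_that("decrement series normalises by the protocol maximum", {
  mk_protocol <- function(plateaus) {
    lapply(seq_along(plateaus), function(k) {
      pp <- ecd_protocol_params(tetanus = tetanus_params(plateau_Nm = plateaus[k],
                                                         stim_duration_s = 0.8,
                                                         post_window_s = 0.3,
                                                         noise_sd_Nm = 0),
                                r_inf = 1)
      simulate_ecd_protocol(pp, seed = 1)$traces[[1]]
    })
  }
  # all plateaus equal -> every N_k = 100, decrement 0
  res <- ecd_series(mk_protocol(rep(4, 5)))
  expect_equal(res$normalised_series_pct, rep(100, 5), tolerance = 1e-6)
  expect_equal(res$final_decrement_pct, 0, tolerance = 1e-6)
  expect_equal(max(res$normalised_series_pct), 100)
  # declining plateaus 10 ... 8 -> N_last = 80, decrement 20
  res2 <- ecd_series(mk_protocol(c(10, 9, 8.5, 8)))
  expect_equal(res2$final_remaining_pct, 80, tolerance = 0.01)
  expect_equal(res2$final_decrement_pct, 20, tolerance = 0.01)
  # scale invariance: multiplying all plateaus by c leaves N_k unchanged
  res3 <- ecd_series(mk_protocol(3 * c(10, 9, 8.5, 8)))
  expect_equal(res3$normalised_series_pct, res2$normalised_series_pct,
               tolerance = 1e-6)
})

test_that("zero-noise protocol recovers the generator decrement curve", {
  pp <- ecd_protocol_params(tetanus = tetanus_params(plateau_Nm = 5,
                                                     stim_duration_s = 0.8,
                                                     post_window_s = 0.5,
                                                     noise_sd_Nm = 0),
                            r_inf = 0.24, kappa = 5)
  prot <- simulate_ecd_protocol(pp, seed = 1)
  res <- ecd_series(prot$traces)
  expect_equal(res$n_detected, 30)
  expect_equal(res$final_decrement_pct, 100 * (1 - prot$truth$a_k[30]),
               tolerance = 0.1)
  expect_equal(res$final_decrement_pct, 76, tolerance = 0.5)
  expect_equal(res$max_abs_force_N, res$max_torque_Nm / 0.1)
  # glance/tidy views are consistent
  expect_equal(nrow(tidy(res)), 30)
  expect_equal(glance(res)$final_decrement_pct, res$final_decrement_pct)
})

test_that("protocol QC rejects dislodged-electrode contractions and bad protocols", {
  pp <- ecd_protocol_params(tetanus = tetanus_params(noise_sd_Nm = 0.02,
                                                     stim_duration_s = 0.8,
                                                     post_window_s = 0.3),
                            r_inf = 0.8)
  prot <- simulate_ecd_protocol(pp, seed = 6)
  qc_clean <- protocol_qc(prot$traces)
  expect_equal(sum(qc_clean$accepted), 30)
  expect_true(attr(qc_clean, "protocol_accepted"))
  # zero out contraction 17 (electrode dislodged)
  traces <- prot$traces
  traces[[17]]$torque_Nm <- rnorm(nrow(traces[[17]]), 0, 0.02)
  qc <- protocol_qc(traces)
  expect_false(qc$accepted[17])
  expect_equal(sum(qc$accepted), 29)
  expect_true(attr(qc, "protocol_accepted"))
  res <- ecd_series(traces, qc = qc)
  expect_true(is.na(res$normalised_series_pct[17]))
  expect_true(res$final_position_accepted)
  # 10 corrupted of 30 at min_frac 0.8 -> whole protocol rejected
  traces2 <- prot$traces
  for (k in 1:10) traces2[[k]]$torque_Nm <- rnorm(nrow(traces2[[k]]), 0, 0.02)
  expect_false(attr(protocol_qc(traces2), "protocol_accepted"))
  # rejected final contraction: last accepted position reported with flag
  traces3 <- prot$traces
  traces3[[30]]$torque_Nm <- rnorm(nrow(traces3[[30]]), 0, 0.02)
  res3 <- ecd_series(traces3)
  expect_false(res3$final_position_accepted)
  expect_equal(res3$final_position, 29)
})

test_that("linear_fit matches hand-computed OLS and rejects degenerate input", {
  # exact line
  d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
  f <- suppressWarnings(linear_fit(d, x, y))  # lm warns on an exact fit
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # hand-computable: x = (1,2,3), y = (1,2,4)
  f2 <- linear_fit(data.frame(x = 1:3, y = c(1, 2, 4)), x, y)
  expect_equal(f2$slope, 1.5, tolerance = 1e-12)
  expect_equal(f2$intercept, -2 / 3, tolerance = 1e-12)
  expect_equal(f2$r_squared, 27 / 28, tolerance = 1e-12)
  expect_error(linear_fit(data.frame(x = rep(1, 5), y = rnorm(5)), x, y),
               "zero variance")
  expect_error(linear_fit(data.frame(x = 1:2, y = 1:2), x, y), "at least 3")
  # independent y: R^2 near 0 and p roughly uniform over seeds
  ps <- vapply(1:60, function(s) {
    withr::with_seed(s, linear_fit(data.frame(x = 1:100, y = rnorm(100)), x, y)$p_value)
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 0)
})
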