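#' Baseline-correct a torque trace
#'
#' Subtracts the mean torque over a pre-stimulus window ending at stimulus
#' onset and records the estimate in the trace metadata (`baseline_Nm`,
#' `baseline_corrected`, `prestim_noise_sd_Nm`).
#'
#' @param trace A [force_trace()].
#' @param window_s Window length (s) immediately before `stim_onset_s`; must
#'   fit before the stimulus and span at least 5 samples.
#' @return The corrected `force_trace`.
#' @export
baseline_correct <- function(trace, window_s = 0.05) {
  meta <- trace_meta(trace)
  w0 <- meta$stim_onset_s - window_s
  if (w0 < trace$time_s[1] - 1e-9) {
    abort("stimulus onset too early for the requested baseline window")
  }
  in_win <- trace$time_s >= w0 - 1e-9 & trace$time_s < meta$stim_onset_s - 1e-9
  if (sum(in_win) < 5) abort("baseline window must span at least 5 samples")
  b <- mean(trace$torque_Nm[in_win])
  trace$torque_Nm <- trace$torque_Nm - b
  set_trace_meta(trace, baseline_Nm = b, baseline_corrected = TRUE,
                 prestim_noise_sd_Nm = sd(trace$torque_Nm[in_win]))
}

assert_corrected <- function(trace) {
  if (!isTRUE(trace_meta(trace)$baseline_corrected)) {
    abort("trace must be baseline-corrected first (see baseline_correct())")
  }
  invisible(trace)
}

# first upward crossing of `level` at/after time t_from, linear interpolation
first_up_crossing <- function(time_s, torque, level, t_from) {
  idx <- which(time_s >= t_from - 1e-12)
  tt <- time_s[idx]; yy <- torque[idx]
  if (!length(yy)) return(NA_real_)
  if (yy[1] >= level) return(tt[1])
  hits <- which(yy[-1] >= level & yy[-length(yy)] < level)
  if (!length(hits)) return(NA_real_)
  i <- hits[1]
  tt[i] + (level - yy[i]) / (yy[i + 1] - yy[i]) * (tt[i + 1] - tt[i])
}

# first downward crossing of `level` at/after time t_from
first_down_crossing <- function(time_s, torque, level, t_from) {
  idx <- which(time_s >= t_from - 1e-12)
  tt <- time_s[idx]; yy <- torque[idx]
  if (!length(yy)) return(NA_real_)
  if (yy[1] <= level) return(tt[1])
  hits <- which(yy[-1] <= level & yy[-length(yy)] > level)
  if (!length(hits)) return(NA_real_)
  i <- hits[1]
  tt[i] + (level - yy[i]) / (yy[i + 1] - yy[i]) * (tt[i + 1] - tt[i])
}

contraction_fractions <- function(kind) {
  # twitch: deciles to 100% (time-to-peak); tetanus/eccentric: deciles to 90%
  # plus the 95% proxy, because tetanic force fluctuates too much for a
  # reliable 100% read
  if (kind == "twitch") seq(0.1, 1.0, by = 0.1) else c(seq(0.1, 0.9, by = 0.1), 0.95)
}

relaxation_fractions <- function() c(seq(0.1, 0.9, by = 0.1), 0.95)

#' Contraction features of a baseline-corrected trace
#'
#' For a twitch the contraction reference is the maximum torque; for a tetanus
#' (or the isometric phase convention generally) it is the torque at the end
#' of stimulation. Times to each decile of the reference (plus 95% for
#' tetani, and 100% = time-to-peak for twitches) are measured from stimulus
#' onset via linear interpolation of the first upward crossing.
#'
#' @param trace A baseline-corrected [force_trace()].
#' @return One-row tibble: `trace_kind`, `peak_torque_Nm`, `peak_time_s`,
#'   `end_stim_torque_Nm`, `reference_Nm`, `absolute_force_N`,
#'   `relative_force_N_per_kg`, and a `contraction_times` list-column
#'   (tibble `fraction`, `time_s`, `reached`).
#' @export
contraction_features <- function(trace) {
  assert_corrected(trace)
  meta <- trace_meta(trace)
  kind <- meta$trace_kind
  peak_i <- which.max(trace$torque_Nm)
  peak <- trace$torque_Nm[peak_i]
  peak_time <- trace$time_s[peak_i]
  end_stim <- trace_value_at(trace, meta$stim_end_s)
  reference <- if (kind == "twitch") peak else end_stim
  if (!is.finite(reference) || reference <= 0) {
    abort("non-positive contraction reference; trace fails QC",
          class = "musclephys_qc_error")
  }
  fr <- contraction_fractions(kind)
  tt <- vapply(fr, function(q) {
    first_up_crossing(trace$time_s, trace$torque_Nm, q * reference, meta$stim_onset_s)
  }, numeric(1)) - meta$stim_onset_s
  tibble::tibble(
    trace_kind = kind,
    peak_torque_Nm = peak,
    peak_time_s = peak_time,
    end_stim_torque_Nm = end_stim,
    reference_Nm = reference,
    absolute_force_N = reference / meta$lever_arm_m,
    relative_force_N_per_kg = reference / meta$lever_arm_m / meta$bodyweight_kg,
    contraction_times = list(tibble::tibble(fraction = fr, time_s = tt,
                                            reached = is.finite(tt)))
  )
}

#' Relaxation features of a baseline-corrected trace
#'
#' Relaxation is timed from the contraction reference point (peak for a
#' twitch, end of stimulation for a tetanus): the x% relaxation time is the
#' first time at which torque falls to `reference * (1 - x/100)`, linearly
#' interpolated. Deciles and the 95% proxy for full relaxation are reported;
#' fractions never reached within the record are flagged, not errors.
#'
#' @param trace A baseline-corrected [force_trace()].
#' @return One-row tibble: `trace_kind`, `reference_Nm`, `reference_time_s`
#'   and a `relaxation_times` list-column (tibble `fraction`, `time_s`,
#'   `reached`; `time_s` measured from the reference point).
#' @export
relaxation_features <- function(trace) {
  assert_corrected(trace)
  meta <- trace_meta(trace)
  kind <- meta$trace_kind
  if (kind == "twitch") {
    ref_i <- which.max(trace$torque_Nm)
    ref_time <- trace$time_s[ref_i]
    reference <- trace$torque_Nm[ref_i]
  } else {
    ref_time <- meta$stim_end_s
    reference <- trace_value_at(trace, ref_time)
  }
  fr <- relaxation_fractions()
  tt <- vapply(fr, function(x) {
    first_down_crossing(trace$time_s, trace$torque_Nm, reference * (1 - x), ref_time)
  }, numeric(1)) - ref_time
  tibble::tibble(
    trace_kind = kind,
    reference_Nm = reference,
    reference_time_s = ref_time,
    relaxation_times = list(tibble::tibble(fraction = fr, time_s = tt,
                                           reached = is.finite(tt)))
  )
}

#' Quality control of a torque trace
#'
#' Applies the trace-level rejection rules (causes reported for the study's
#' recordings are aberrant co-stimulation of non-target muscle groups and
#' abnormal trace conformations; numeric rules are package defaults, logged
#' per run):
#' (a) peak below `kinetics.qc_k_snr` times the pre-stimulus noise sd;
#' (b) negative deflection below `-kinetics.qc_f_neg * peak` (antagonist
#' co-stimulation); (c) more than `kinetics.qc_m_peaks` distinct excursions
#' above 50% of peak during a twitch; (d) plateau collapse by more than
#' `kinetics.qc_f_drop` of the running plateau maximum during tetanic
#' stimulation (before rotation onset for eccentric traces). QC never raises.
#'
#' @param trace A baseline-corrected [force_trace()].
#' @param config A [run_config()] list.
#' @return One-row tibble: `qc_status` (`"pass"`/`"reject"`), `qc_reasons`
#'   (comma-separated rule letters, empty on pass).
#' @export
qc_trace <- function(trace, config = default_config()) {
  assert_corrected(trace)
  meta <- trace_meta(trace)
  y <- trace$torque_Nm
  peak <- max(y)
  noise_sd <- meta$prestim_noise_sd_Nm %||% 0
  reasons <- character(0)
  if (peak < config$kinetics.qc_k_snr * noise_sd) {
    reasons <- c(reasons, "a:low_snr_peak")
  }
  if (min(y) < -config$kinetics.qc_f_neg * max(peak, 0)) {
    reasons <- c(reasons, "b:negative_deflection")
  }
  if (meta$trace_kind == "twitch" && peak > 0) {
    # count distinct excursions above 50% of peak with a hysteresis band
    # (re-arm below 40%) so noise jitter around the threshold is not
    # mistaken for repeated peaks
    high <- y >= 0.5 * peak
    low <- y < 0.4 * peak
    armed <- TRUE
    n_excursions <- 0L
    for (i in seq_along(y)) {
      if (armed && high[i]) {
        n_excursions <- n_excursions + 1L
        armed <- FALSE
      } else if (!armed && low[i]) {
        armed <- TRUE
      }
    }
    if (n_excursions > config$kinetics.qc_m_peaks) {
      reasons <- c(reasons, "c:multiple_peaks")
    }
  }
  if (meta$trace_kind %in% c("tetanus", "eccentric")) {
    stim_stop <- if (meta$trace_kind == "eccentric") {
      meta$rotation_onset_s %||% meta$stim_end_s
    } else {
      meta$stim_end_s
    }
    in_stim <- trace$time_s >= meta$stim_onset_s & trace$time_s <= stim_stop
    ys <- y[in_stim]
    if (length(ys) > 1) {
      run_max <- cummax(ys)
      if (any(ys < (1 - config$kinetics.qc_f_drop) * run_max &
                run_max > config$kinetics.qc_k_snr * max(noise_sd, .Machine$double.eps))) {
        reasons <- c(reasons, "d:plateau_collapse")
      }
    }
  }
  tibble::tibble(qc_status = if (length(reasons)) "reject" else "pass",
                 qc_reasons = paste(reasons, collapse = ","))
}

#' Full per-trace kinetics feature set
#'
#' Convenience wrapper: baseline correction, QC and (for passing traces)
#' contraction and relaxation features, in one row.
#'
#' @param trace A raw [force_trace()].
#' @param config A [run_config()] list.
#' @return One-row tibble combining subject metadata, QC and features; feature
#'   columns are `NA` for rejected traces.
#' @export
kinetics_features <- function(trace, config = default_config()) {
  tr <- baseline_correct(trace, config$kinetics.baseline_window_s)
  meta <- trace_meta(tr)
  qc <- qc_trace(tr, config)
  base <- tibble::tibble(subject_id = meta$subject_id, genotype = meta$genotype,
                         trace_kind = meta$trace_kind, nerve_target = meta$nerve_target,
                         baseline_Nm = meta$baseline_Nm)
  if (qc$qc_status == "reject") {
    return(dplyr::bind_cols(base, qc,
                            tibble::tibble(peak_torque_Nm = NA_real_,
                                           end_stim_torque_Nm = NA_real_,
                                           reference_Nm = NA_real_,
                                           absolute_force_N = NA_real_,
                                           relative_force_N_per_kg = NA_real_,
                                           contraction_times = list(NULL),
                                           relaxation_times = list(NULL))))
  }
  con <- contraction_features(tr)
  rel <- relaxation_features(tr)
  dplyr::bind_cols(base, qc,
                   con[c("peak_torque_Nm", "peak_time_s", "end_stim_torque_Nm",
                         "reference_Nm", "absolute_force_N",
                         "relative_force_N_per_kg", "contraction_times")],
                   rel[c("relaxation_times")])
}

#' Twitch to tetanus torque ratio
#'
#' The fraction of maximal tetanic torque generated by a single stimulus
#' twitch: twitch peak torque divided by tetanus end-of-stimulation torque.
#'
#' @param twitch Feature row from [contraction_features()] for the twitch.
#' @param tetanus Feature row for the tetanus from the same electrode
#'   placement.
#' @return Dimensionless ratio, > 0.
#' @export
twitch_tetanus_ratio <- function(twitch, tetanus) {
  if (!is.finite(tetanus$end_stim_torque_Nm) || tetanus$end_stim_torque_Nm <= 0) {
    abort("tetanus end-of-stimulation torque must be positive")
  }
  twitch$peak_torque_Nm / tetanus$end_stim_torque_Nm
}
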