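#' Plateau torque of an eccentric contraction
#'
#' Tetanic torque is read at the end of the 0.5 s isometric (non-lengthening)
#' phase: the mean baseline-corrected torque over a trailing window ending at
#' rotation onset. A window mean (rather than a single sample) is used for
#' noise robustness; `window_s = 0` degenerates to the last pre-rotation
#' sample.
#'
#' @param trace An eccentric [force_trace()] (baseline-corrected traces are
#'   used as-is; raw traces are corrected first).
#' @param window_s Trailing window length (s), default 10 ms.
#' @param config A [run_config()] list (baseline window).
#' @return Plateau torque (N m).
#' @export
plateau_torque <- function(trace, window_s = 0.010, config = default_config()) {
  meta <- trace_meta(trace)
  if (!isTRUE(meta$baseline_corrected)) {
    trace <- baseline_correct(trace, config$kinetics.baseline_window_s)
    meta <- trace_meta(trace)
  }
  rot <- meta$rotation_onset_s
  if (is.null(rot)) abort("trace has no rotation_onset_s metadata; not an eccentric trace?")
  if (rot - window_s < meta$stim_onset_s) {
    abort("plateau window extends before stimulus onset")
  }
  if (window_s == 0) {
    i <- max(which(trace$time_s < rot - 1e-12))
    return(trace$torque_Nm[i])
  }
  in_win <- trace$time_s >= rot - window_s - 1e-12 & trace$time_s < rot - 1e-12
  mean(trace$torque_Nm[in_win])
}

#' Per-contraction protocol quality control
#'
#' Flags contractions whose recording is implausible: plateau below
#' `ecd.qc_k_snr` times the pre-stimulus noise sd (dislodged electrode),
#' sample-to-sample discontinuities larger than `ecd.qc_f_jump` of the plateau
#' during the isometric phase, or a negative deflection (antagonist
#' stimulation, rule shared with [qc_trace()]). The whole protocol is
#' rejected when fewer than `ecd.min_frac` of the contractions are accepted.
#'
#' @param traces List of eccentric [force_trace()]s in protocol order.
#' @param config A [run_config()] list.
#' @return Tibble `k`, `accepted`, `reasons`, with attribute
#'   `protocol_accepted`.
#' @export
protocol_qc <- function(traces, config = default_config()) {
  res <- purrr::map_dfr(seq_along(traces), function(k) {
    tr <- traces[[k]]
    meta0 <- trace_meta(tr)
    if (!isTRUE(meta0$baseline_corrected)) {
      tr <- baseline_correct(tr, config$kinetics.baseline_window_s)
    }
    meta <- trace_meta(tr)
    noise_sd <- meta$prestim_noise_sd_Nm %||% 0
    pl <- tryCatch(plateau_torque(tr, config$ecd.plateau_window_s, config),
                   error = function(e) NA_real_)
    reasons <- character(0)
    if (!is.finite(pl) || pl < config$ecd.qc_k_snr * noise_sd || pl <= 0) {
      reasons <- c(reasons, "low_plateau")
    }
    iso <- tr$time_s >= meta$stim_onset_s &
      tr$time_s < (meta$rotation_onset_s %||% meta$stim_end_s)
    jumps <- abs(diff(tr$torque_Nm[iso]))
    # ignore the stimulus-onset ramp when judging discontinuities: compare
    # jumps against the plateau over the second half of the isometric phase
    if (is.finite(pl) && pl > 0) {
      half <- jumps[seq(ceiling(length(jumps) / 2), length(jumps))]
      if (length(half) && max(half) > config$ecd.qc_f_jump * pl) {
        reasons <- c(reasons, "discontinuity")
      }
    }
    if (min(tr$torque_Nm) < -config$kinetics.qc_f_neg * max(max(tr$torque_Nm), 0)) {
      reasons <- c(reasons, "negative_deflection")
    }
    tibble::tibble(k = k, accepted = !length(reasons),
                   reasons = paste(reasons, collapse = ","),
                   plateau_Nm = pl)
  })
  attr(res, "protocol_accepted") <- mean(res$accepted) >= config$ecd.min_frac
  res
}

#' Eccentric-contraction decrement series
#'
#' Divides each accepted plateau torque by the maximum plateau torque produced
#' during the protocol (max over accepted isometric-phase reads, not over raw
#' traces including the lengthening spike) to give the normalised series
#' `N_k` in percent; the final decrement is `100 - N_k` at the last protocol
#' position. Rejected or missing contractions leave gaps: the series stays
#' indexed by protocol position, and if the final position was rejected the
#' last accepted position is reported with `final_position_accepted = FALSE`.
#'
#' @param traces List of 1-30 eccentric [force_trace()]s in protocol order.
#' @param config A [run_config()] list.
#' @param qc Optional precomputed [protocol_qc()] table.
#' @return An `ecd_result` object; see [tidy.ecd_result()] /
#'   [glance.ecd_result()].
#' @export
ecd_series <- function(traces, config = default_config(), qc = NULL) {
  if (!length(traces)) abort("no traces supplied")
  if (is.null(qc)) qc <- protocol_qc(traces, config)
  n_pos <- length(traces)
  plateau <- ifelse(qc$accepted, qc$plateau_Nm, NA_real_)
  if (!any(is.finite(plateau))) abort("no accepted contractions")
  t_max <- max(plateau, na.rm = TRUE)
  if (t_max <= 0) abort("maximum plateau torque is non-positive")
  norm_pct <- 100 * plateau / t_max
  last_pos <- n_pos
  final_ok <- isTRUE(qc$accepted[last_pos])
  final_idx <- if (final_ok) last_pos else max(which(qc$accepted))
  lever <- trace_meta(traces[[1]])$lever_arm_m
  structure(list(
    plateau_torques_Nm = plateau,
    max_torque_Nm = t_max,
    normalised_series_pct = norm_pct,
    final_remaining_pct = norm_pct[final_idx],
    final_decrement_pct = 100 - norm_pct[final_idx],
    final_position = final_idx,
    final_position_accepted = final_ok,
    max_abs_force_N = t_max / lever,
    n_detected = sum(qc$accepted),
    protocol_accepted = attr(qc, "protocol_accepted"),
    subject_id = trace_meta(traces[[1]])$subject_id,
    genotype = trace_meta(traces[[1]])$genotype,
    qc = qc
  ), class = "ecd_result")
}

#' @export
print.ecd_result <- function(x, ...) {
  cat(sprintf("<ecd_result %s: %d/%d contractions, Tmax %.3g N m, final decrement %.1f%%%s>\n",
              x$subject_id, x$n_detected, length(x$plateau_torques_Nm),
              x$max_torque_Nm, x$final_decrement_pct,
              if (x$final_position_accepted) "" else " (last accepted position)"))
  invisible(x)
}

#' Tidy an ECD result into a per-contraction tibble
#' @param x An `ecd_result`.
#' @param ... Unused.
#' @return Tibble `k`, `plateau_Nm`, `normalised_pct`, `accepted`.
#' @export
tidy.ecd_result <- function(x, ...) {
  tibble::tibble(k = seq_along(x$plateau_torques_Nm),
                 plateau_Nm = x$plateau_torques_Nm,
                 normalised_pct = x$normalised_series_pct,
                 accepted = x$qc$accepted)
}

#' One-row summary of an ECD result
#' @param x An `ecd_result`.
#' @param ... Unused.
#' @return One-row tibble with the headline protocol quantities.
#' @export
glance.ecd_result <- function(x, ...) {
  tibble::tibble(subject_id = x$subject_id, genotype = x$genotype,
                 n_detected = x$n_detected,
                 max_torque_Nm = x$max_torque_Nm,
                 max_abs_force_N = x$max_abs_force_N,
                 final_remaining_pct = x$final_remaining_pct,
                 final_decrement_pct = x$final_decrement_pct,
                 final_position_accepted = x$final_position_accepted,
                 protocol_accepted = x$protocol_accepted)
}

#' Ordinary least-squares regression summary
#'
#' Simple linear regression used for the decrement-versus-age and
#' decrement-versus-maximum-force relationships: slope, intercept, R^2 and the
#' two-sided p-value for the slope (t distribution, n - 2 df).
#'
#' @param data Data frame.
#' @param x,y Column names (tidy-eval) of predictor and response.
#' @return One-row tibble `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @examples
#' linear_fit(data.frame(a = 1:10, b = 2 * (1:10) + 1), a, b)
#' @export
linear_fit <- function(data, x, y) {
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("linear_fit needs at least 3 finite observations")
  if (stats::var(xv) == 0) abort("zero variance in x")
  fit <- lm(yv ~ xv)
  sm <- summary(fit)
  p <- sm$coefficients["xv", "Pr(>|t|)"]
  tibble::tibble(slope = unname(coef(fit)["xv"]),
                 intercept = unname(coef(fit)["(Intercept)"]),
                 r_squared = sm$r.squared, p_value = p, n = n)
}
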