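#' Twitch simulation parameters
#'
#' The twitch model is a saturating exponential rise from stimulus onset to a
#' peak at `t0_s + 5 * tau_rise_s` (normalised so the noise-free peak equals
#' `amplitude_Nm` exactly), followed by a biexponential decay
#' `(1 - slow_fraction) * exp(-d/tau_fast) + slow_fraction * exp(-d/tau_slow)`.
#' The slow component emulates the prolonged terminal relaxation seen in
#' dystrophic muscle. Gaussian noise of sd `noise_sd_Nm` is added per sample.
#'
#' @param amplitude_Nm Peak torque above baseline (N m), > 0.
#' @param t0_s Stimulus onset (s).
#' @param tau_rise_s,tau_fast_relax_s,tau_slow_relax_s Time constants (s), > 0.
#' @param slow_fraction Weight of the slow relaxation component, in `[0, 1]`.
#' @param baseline_Nm Resting torque offset (N m).
#' @param noise_sd_Nm Additive Gaussian noise sd (N m), >= 0.
#' @param duration_s Total record length (s).
#' @param sampling_hz Sampling rate (Hz).
#' @param subject Named list merged into trace metadata (subject_id, genotype,
#'   age_months, bodyweight_kg, lever_arm_m, nerve_target).
#' @return Parameter list of class `twitch_params`.
#' @export
twitch_params <- function(amplitude_Nm = 1, t0_s = 0.05, tau_rise_s = 0.01,
                          tau_fast_relax_s = 0.04, tau_slow_relax_s = 0.3,
                          slow_fraction = 0.15, baseline_Nm = 0,
                          noise_sd_Nm = 0, duration_s = 0.85,
                          sampling_hz = 1000, subject = list()) {
  p <- list(amplitude_Nm = amplitude_Nm, t0_s = t0_s, tau_rise_s = tau_rise_s,
            tau_fast_relax_s = tau_fast_relax_s, tau_slow_relax_s = tau_slow_relax_s,
            slow_fraction = slow_fraction, baseline_Nm = baseline_Nm,
            noise_sd_Nm = noise_sd_Nm, duration_s = duration_s,
            sampling_hz = sampling_hz, subject = subject)
  stopifnot(amplitude_Nm > 0, tau_rise_s > 0, tau_fast_relax_s > 0,
            tau_slow_relax_s > 0, slow_fraction >= 0, slow_fraction <= 1,
            noise_sd_Nm >= 0)
  structure(p, class = "twitch_params")
}

# rise phase length in units of tau_rise; peak is reached (and normalised to
# amplitude) at t0 + TWITCH_RISE_SPAN * tau_rise
TWITCH_RISE_SPAN <- 5

default_subject <- function(subject = list()) {
  modifyList(list(subject_id = "SIM-01", genotype = "WT", age_months = 12,
                  bodyweight_kg = 10, lever_arm_m = 0.1, nerve_target = "fibular"),
             subject)
}

#' Simulate a twitch torque trace
#'
#' Pure function of (params, seed): the same seed reproduces the same trace.
#'
#' @param params A [twitch_params()] list.
#' @param seed Integer seed for the additive noise (ignored when
#'   `noise_sd_Nm = 0`); `NULL` uses the session RNG stream.
#' @return A [force_trace()] of kind `"twitch"`.
#' @examples
#' tr <- simulate_twitch(twitch_params(amplitude_Nm = 2), seed = 1)
#' max(tr$torque_Nm)
#' @export
simulate_twitch <- function(params, seed = NULL) {
  p <- params
  t <- seq(0, p$duration_s, by = 1 / p$sampling_hz)
  y <- twitch_model(t, p)
  y <- add_trace_noise(y, p$noise_sd_Nm, seed)
  meta <- c(default_subject(p$subject),
            list(trace_kind = "twitch", stim_onset_s = p$t0_s,
                 stim_end_s = p$t0_s + 1e-4,  # 0.1 ms pulse
                 sampling_hz = p$sampling_hz, true_baseline_Nm = p$baseline_Nm))
  force_trace(t, y, meta)
}

# noise-free twitch model evaluated on an arbitrary grid
twitch_model <- function(t, p) {
  t_peak <- p$t0_s + TWITCH_RISE_SPAN * p$tau_rise_s
  rise_norm <- 1 - exp(-TWITCH_RISE_SPAN)
  y <- numeric(length(t))
  rising <- t >= p$t0_s & t <= t_peak
  after <- t > t_peak
  y[rising] <- p$amplitude_Nm * (1 - exp(-(t[rising] - p$t0_s) / p$tau_rise_s)) / rise_norm
  d <- t[after] - t_peak
  y[after] <- p$amplitude_Nm *
    ((1 - p$slow_fraction) * exp(-d / p$tau_fast_relax_s) +
       p$slow_fraction * exp(-d / p$tau_slow_relax_s))
  p$baseline_Nm + y
}

add_trace_noise <- function(y, noise_sd, seed) {
  if (noise_sd <= 0) return(y)
  if (is.null(seed)) return(y + rnorm(length(y), 0, noise_sd))
  withr::with_seed(seed, y + rnorm(length(y), 0, noise_sd))
}

#' Tetanus simulation parameters
#'
#' The tetanus model rises as `(plateau + drift * d) * (1 - exp(-d/tau_rise))`
#' during stimulation (`d` = time since stimulus onset); `drift_Nm_per_s`
#' emulates the very gradual force increase towards the end of a 50 Hz, 1 s
#' stimulation. After `stim_duration_s` the trace relaxes biexponentially from
#' its end-of-stimulation value and the recording continues for
#' `post_window_s` (the post-stimulus analysis window).
#'
#' @param plateau_Nm Plateau torque (N m), > 0.
#' @param tau_rise_s Rise time constant (s).
#' @param drift_Nm_per_s Linear plateau drift during stimulation, >= 0.
#' @param stim_duration_s Stimulation length (s), default 1 (fifty pulses at
#'   50 Hz).
#' @param post_window_s Recording window after stimulation end (s), default 0.8.
#' @param tau_fast_relax_s,tau_slow_relax_s,slow_fraction Relaxation
#'   parameters as in [twitch_params()].
#' @param baseline_Nm,noise_sd_Nm,sampling_hz,t0_s,subject As in
#'   [twitch_params()].
#' @return Parameter list of class `tetanus_params`.
#' @export
tetanus_params <- function(plateau_Nm = 5, tau_rise_s = 0.05,
                           drift_Nm_per_s = 0, stim_duration_s = 1,
                           post_window_s = 0.8, tau_fast_relax_s = 0.06,
                           tau_slow_relax_s = 0.4, slow_fraction = 0.15,
                           baseline_Nm = 0, noise_sd_Nm = 0, t0_s = 0.1,
                           sampling_hz = 1000, subject = list()) {
  stopifnot(plateau_Nm > 0, tau_rise_s > 0, drift_Nm_per_s >= 0,
            stim_duration_s > 0, post_window_s >= 0, noise_sd_Nm >= 0)
  structure(list(plateau_Nm = plateau_Nm, tau_rise_s = tau_rise_s,
                 drift_Nm_per_s = drift_Nm_per_s, stim_duration_s = stim_duration_s,
                 post_window_s = post_window_s, tau_fast_relax_s = tau_fast_relax_s,
                 tau_slow_relax_s = tau_slow_relax_s, slow_fraction = slow_fraction,
                 baseline_Nm = baseline_Nm, noise_sd_Nm = noise_sd_Nm, t0_s = t0_s,
                 sampling_hz = sampling_hz, subject = subject),
            class = "tetanus_params")
}

#' Simulate a tetanus torque trace
#'
#' @param params A [tetanus_params()] list.
#' @param seed Integer noise seed; `NULL` uses the session RNG stream.
#' @return A [force_trace()] of kind `"tetanus"`.
#' @export
simulate_tetanus <- function(params, seed = NULL) {
  p <- params
  t <- seq(0, p$t0_s + p$stim_duration_s + p$post_window_s, by = 1 / p$sampling_hz)
  y <- tetanus_model(t, p)
  y <- add_trace_noise(y, p$noise_sd_Nm, seed)
  meta <- c(default_subject(p$subject),
            list(trace_kind = "tetanus", stim_onset_s = p$t0_s,
                 stim_end_s = p$t0_s + p$stim_duration_s,
                 sampling_hz = p$sampling_hz, true_baseline_Nm = p$baseline_Nm))
  force_trace(t, y, meta)
}

tetanus_model <- function(t, p, transient = NULL) {
  stim_end <- p$t0_s + p$stim_duration_s
  y <- numeric(length(t))
  d <- t - p$t0_s
  during <- t >= p$t0_s & t <= stim_end
  y[during] <- (p$plateau_Nm + p$drift_Nm_per_s * d[during]) *
    (1 - exp(-d[during] / p$tau_rise_s))
  y_end <- (p$plateau_Nm + p$drift_Nm_per_s * p$stim_duration_s) *
    (1 - exp(-p$stim_duration_s / p$tau_rise_s))
  after <- t > stim_end
  da <- t[after] - stim_end
  y[after] <- y_end * ((1 - p$slow_fraction) * exp(-da / p$tau_fast_relax_s) +
                         p$slow_fraction * exp(-da / p$tau_slow_relax_s))
  if (!is.null(transient)) {
    # additive raised-cosine lengthening transient confined to the rotation
    # window; plateau torque is read before rotation onset, so any confined
    # shape is admissible
    r0 <- p$t0_s + transient$onset_s
    inwin <- t >= r0 & t <= r0 + transient$duration_s
    ph <- (t[inwin] - r0) / transient$duration_s
    y[inwin] <- y[inwin] + transient$amplitude_Nm * 0.5 * (1 - cos(2 * pi * ph))
  }
  p$baseline_Nm + y
}

#' Eccentric-contraction protocol parameters
#'
#' Thirty eccentric contractions in three sets of ten: 4 s between
#' contractions within a set and a 4 min rest between sets. Each contraction
#' is a tetanus whose isometric plateau lasts 0.5 s before the foot-pedal
#' rotation (29 degrees over 0.2 s), modelled as an additive raised-cosine
#' torque transient confined to the rotation window. The plateau of
#' contraction `k` is scaled by the decrement curve
#' `a_k = r_inf + (1 - r_inf) * exp(-(k - 1) / kappa)`, so `a_1 = 1` and the
#' final torque loss is `100 * (1 - a_30)` percent when `kappa << 30`.
#'
#' @param tetanus Base [tetanus_params()] for a single contraction (its
#'   `stim_duration_s` should cover the 0.5 s isometric phase plus the 0.2 s
#'   rotation; default 0.8 s).
#' @param n_contractions Number of contractions (default 30).
#' @param set_size Contractions per set (default 10).
#' @param intra_gap_s Gap between contractions within a set (s, default 4).
#' @param inter_set_gap_s Rest between sets (s, default 240).
#' @param r_inf Asymptote of the decrement curve in `[0, 1]`
#'   (`1 - final_decrement/100`).
#' @param kappa Decrement-curve time constant (contractions), > 0.
#' @param rotation_onset_s Rotation onset after stimulus onset (s, default 0.5).
#' @param rotation_duration_s Rotation length (s, default 0.2).
#' @param transient_amp_Nm Amplitude of the lengthening transient (N m).
#' @return Parameter list of class `ecd_protocol_params`.
#' @export
ecd_protocol_params <- function(tetanus = tetanus_params(stim_duration_s = 0.8,
                                                         post_window_s = 0.5),
                                n_contractions = 30, set_size = 10,
                                intra_gap_s = 4, inter_set_gap_s = 240,
                                r_inf = 0.8, kappa = 5,
                                rotation_onset_s = 0.5, rotation_duration_s = 0.2,
                                transient_amp_Nm = 0.5 * tetanus$plateau_Nm) {
  stopifnot(r_inf >= 0, r_inf <= 1, kappa > 0,
            rotation_onset_s + rotation_duration_s <= tetanus$stim_duration_s)
  structure(list(tetanus = tetanus, n_contractions = n_contractions,
                 set_size = set_size, intra_gap_s = intra_gap_s,
                 inter_set_gap_s = inter_set_gap_s, r_inf = r_inf, kappa = kappa,
                 rotation_onset_s = rotation_onset_s,
                 rotation_duration_s = rotation_duration_s,
                 transient_amp_Nm = transient_amp_Nm),
            class = "ecd_protocol_params")
}

#' Decrement curve of plateau scales
#' @param params An [ecd_protocol_params()] list.
#' @return Numeric vector `a_k`, `k = 1..n_contractions` (non-increasing,
#'   `a_1 = 1`).
#' @export
decrement_curve <- function(params) {
  k <- seq_len(params$n_contractions)
  params$r_inf + (1 - params$r_inf) * exp(-(k - 1) / params$kappa)
}

#' Simulate a full eccentric-contraction protocol
#'
#' @param params An [ecd_protocol_params()] list.
#' @param seed Integer seed; per-contraction noise seeds are derived from it.
#' @return List with `traces` (list of `n_contractions` eccentric
#'   [force_trace()]s, each carrying `protocol_time_s`, `contraction_index`,
#'   `rotation_onset_s`, `rotation_duration_s` metadata) and `truth` (tibble
#'   `k`, `a_k`, `plateau_Nm`, `protocol_time_s`).
#' @export
simulate_ecd_protocol <- function(params, seed = NULL) {
  p <- params
  a <- decrement_curve(p)
  n <- p$n_contractions
  set_idx <- (seq_len(n) - 1) %/% p$set_size
  within_idx <- (seq_len(n) - 1) %% p$set_size
  start_s <- set_idx * ((p$set_size - 1) * p$intra_gap_s + p$inter_set_gap_s) +
    within_idx * p$intra_gap_s
  sub_seeds <- if (is.null(seed)) rep(list(NULL), n) else as.list(seed * 1000L + seq_len(n))
  traces <- purrr::map(seq_len(n), function(k) {
    tp <- p$tetanus
    tp$plateau_Nm <- tp$plateau_Nm * a[k]
    tr <- simulate_eccentric_trace(tp, p, a[k], sub_seeds[[k]])
    set_trace_meta(tr, protocol_time_s = start_s[k], contraction_index = k)
  })
  truth <- tibble::tibble(k = seq_len(n), a_k = a,
                          plateau_Nm = p$tetanus$plateau_Nm * a,
                          protocol_time_s = start_s)
  list(traces = traces, truth = truth)
}

simulate_eccentric_trace <- function(tp, p, a_k, seed) {
  t <- seq(0, tp$t0_s + tp$stim_duration_s + tp$post_window_s, by = 1 / tp$sampling_hz)
  transient <- list(onset_s = p$rotation_onset_s, duration_s = p$rotation_duration_s,
                    amplitude_Nm = p$transient_amp_Nm * a_k)
  y <- tetanus_model(t, tp, transient = transient)
  y <- add_trace_noise(y, tp$noise_sd_Nm, seed)
  meta <- c(default_subject(tp$subject),
            list(trace_kind = "eccentric", stim_onset_s = tp$t0_s,
                 stim_end_s = tp$t0_s + tp$stim_duration_s,
                 sampling_hz = tp$sampling_hz, true_baseline_Nm = tp$baseline_Nm,
                 rotation_onset_s = tp$t0_s + p$rotation_onset_s,
                 rotation_duration_s = p$rotation_duration_s))
  force_trace(t, y, meta)
}

#' Cohort specification for group-level decrement recovery
#'
#' Per-subject true final decrements are drawn from a normal distribution
#' truncated to `[0, 100]` percent and mapped to a decrement curve with
#' `r_inf = 1 - decrement/100` and a fixed `kappa`.
#'
#' @param n_subjects Number of subjects, >= 1.
#' @param decrement_mean_pct,decrement_sd_pct Group mean and sd of the true
#'   final decrement (%).
#' @param genotype Genotype label attached to the subjects.
#' @param kappa Decrement-curve time constant shared by the cohort.
#' @param tetanus Base single-contraction parameters.
#' @param noise_sd_Nm Per-sample trace noise (N m).
#' @return Spec list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, decrement_mean_pct, decrement_sd_pct,
                        genotype = "WT", kappa = 5,
                        tetanus = tetanus_params(stim_duration_s = 0.8,
                                                 post_window_s = 0.5),
                        noise_sd_Nm = 0.05) {
  stopifnot(n_subjects >= 1, decrement_sd_pct >= 0)
  structure(list(n_subjects = n_subjects, decrement_mean_pct = decrement_mean_pct,
                 decrement_sd_pct = decrement_sd_pct, genotype = genotype,
                 kappa = kappa, tetanus = tetanus, noise_sd_Nm = noise_sd_Nm),
            class = "cohort_spec")
}

# location parameter of a [lower, upper]-truncated normal with scale `sd`
# whose truncated mean equals `target`: truncating a percentage
# distribution shifts its mean, so the stated group mean is taken as the
# mean of the truncated distribution and the location is calibrated to it
truncnorm_location <- function(target, sd, lower = 0, upper = 100) {
  if (sd == 0) return(target)
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd; b <- (upper - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target,
                 lower = target - 4 * sd, upper = target + 4 * sd,
                 tol = 1e-10)$root
}

rtruncnorm01 <- function(n, mean, sd, lower = 0, upper = 100) {
  if (sd == 0) return(rep(mean, n))
  mu <- truncnorm_location(mean, sd, lower, upper)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2 * (n - length(out)) + 10, mu, sd)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of eccentric-contraction protocols
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed driving both the truth draws and the trace noise.
#' @return Tibble with one row per subject: `subject_id`, `genotype`,
#'   `true_decrement_pct`, `r_inf`, and a `protocol` list-column, each entry
#'   the trace list of [simulate_ecd_protocol()].
#' @export
simulate_cohort <- function(spec, seed = 1) {
  withr::with_seed(seed, {
    d <- rtruncnorm01(spec$n_subjects, spec$decrement_mean_pct, spec$decrement_sd_pct)
    sub_seed <- sample.int(2^20, spec$n_subjects)
  })
  purrr::map_dfr(seq_len(spec$n_subjects), function(i) {
    tp <- spec$tetanus
    tp$noise_sd_Nm <- spec$noise_sd_Nm
    tp$subject <- modifyList(tp$subject %||% list(),
                             list(subject_id = sprintf("%s-%03d", spec$genotype, i),
                                  genotype = spec$genotype))
    pp <- ecd_protocol_params(tetanus = tp, r_inf = 1 - d[i] / 100, kappa = spec$kappa)
    prot <- simulate_ecd_protocol(pp, seed = sub_seed[i])
    tibble::tibble(subject_id = tp$subject$subject_id, genotype = spec$genotype,
                   true_decrement_pct = d[i], r_inf = pp$r_inf,
                   protocol = list(prot$traces))
  })
}
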