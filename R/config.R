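#' Default run configuration
#'
#' Every tunable of the downstream modules lives in a flat, namespaced
#' key-value set. Keys use `module.option` naming. All defaults are documented
#' here; unknown keys are rejected by [run_config()].
#'
#' Key groups:
#' \describe{
#'   \item{trace.sampling_hz}{Default trace sampling rate (Hz). The recording
#'     instrument's rate is not fixed by the acquisition software version used
#'     in the field, so 1000 Hz is the package default.}
#'   \item{kinetics.*}{Baseline window (s) and QC rule constants: `qc_k_snr`
#'     (peak must exceed this multiple of pre-stimulus noise sd), `qc_f_neg`
#'     (maximum tolerated negative deflection as a fraction of peak),
#'     `qc_m_peaks` (maximum number of distinct excursions above 50% of peak
#'     in a twitch), `qc_f_drop` (maximum tolerated plateau collapse during
#'     tetanic stimulation, as a fraction of the running plateau maximum).}
#'   \item{ecd.*}{Plateau read window (s), protocol QC constants and the
#'     minimum accepted fraction below which a whole protocol is rejected.}
#'   \item{sim.*}{Synthetic-trace generator defaults (see [twitch_params()],
#'     [tetanus_params()], [ecd_protocol_params()]); `sim.kappa` is the
#'     decrement-curve time constant used when mapping a target final
#'     decrement to a plateau-scale curve.}
#'   \item{fibretype.*}{Mask threshold (`min_level`, 8-bit intensity),
#'     watershed tolerance (distance-map units), particle-filter settings
#'     (`min_area_px`, `circ_min`, `circ_max`) and the minimum number of ROIs
#'     required for automatic thresholding.}
#'   \item{power.*}{Within-subject correlation, number of timepoints, alpha
#'     and target power for the repeated-measures sample-size machinery.}
#' }
#'
#' @return Named list of default configuration values.
#' @export
default_config <- function() {
  list(
    trace.sampling_hz      = 1000,
    kinetics.baseline_window_s = 0.05,
    kinetics.qc_k_snr      = 5,
    kinetics.qc_f_neg      = 0.2,
    kinetics.qc_m_peaks    = 2,
    kinetics.qc_f_drop     = 0.3,
    ecd.plateau_window_s   = 0.010,
    ecd.qc_k_snr           = 5,
    ecd.qc_f_jump          = 0.5,
    ecd.min_frac           = 0.8,
    sim.kappa              = 5,
    fibretype.min_level    = 1,
    fibretype.ws_tolerance = 2,
    fibretype.min_area_px  = 300,
    fibretype.circ_min     = 0.40,
    fibretype.circ_max     = 1.00,
    fibretype.min_rois     = 20,
    power.rho              = 0.7,
    power.n_timepoints     = 6,
    power.alpha            = 0.05,
    power.target_power     = 0.8
  )
}

#' Build a validated run configuration
#'
#' @param ... Named overrides of [default_config()] entries.
#' @param overrides Optional named list of overrides (merged after `...`).
#' @return Named list with every documented key present.
#' @examples
#' cfg <- run_config(ecd.plateau_window_s = 0.02)
#' cfg$ecd.plateau_window_s
#' @export
run_config <- function(..., overrides = NULL) {
  ov <- c(list(...), overrides)
  cfg <- default_config()
  if (length(ov)) {
    if (is.null(names(ov)) || any(names(ov) == "")) {
      abort("all configuration overrides must be named")
    }
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown)) {
      abort(paste0("unknown configuration key(s): ", paste(unknown, collapse = ", ")))
    }
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Read a configuration file
#'
#' Parses a minimal TOML-style text format: `key = value` lines, optional
#' `[section]` headers that prefix subsequent keys with `section.`, `#`
#' comments and blank lines. Values are parsed as numbers where possible,
#' `true`/`false` as logicals, and quoted or bare strings otherwise.
#' Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return Validated configuration list (see [run_config()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- ""
  ov <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("cannot parse config line: '", ln, "'"))
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (nzchar(section)) key <- paste0(section, ".", key)
    ov[[key]] <- parse_config_value(val)
  }
  run_config(overrides = ov)
}

parse_config_value <- function(x) {
  if (grepl('^".*"$', x)) return(gsub('^"|"$', "", x))
  if (tolower(x) %in% c("true", "false")) return(tolower(x) == "true")
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  x
}

#' Write a configuration file
#'
#' Inverse of [read_config()]; writes flat `key = value` lines.
#'
#' @param config Configuration list from [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.character(v)) paste0('"', v, '"')
    else if (is.logical(v)) tolower(as.character(v))
    else format(v, digits = 15)
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}
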