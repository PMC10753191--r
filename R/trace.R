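#' Force-trace container
#'
#' A force trace is a tibble with columns `time_s` (seconds, strictly
#' increasing on a uniform grid) and `torque_Nm` (newton-metres), carrying the
#' recording metadata as attributes: `subject_id`, `genotype` (`"WT"` or
#' `"DE50-MD"`), `age_months`, `bodyweight_kg`, `lever_arm_m`, `nerve_target`
#' (`"fibular"` or `"tibial"`), `trace_kind` (`"twitch"`, `"tetanus"` or
#' `"eccentric"`), `stim_onset_s`, `stim_end_s` and `sampling_hz`. Eccentric
#' traces additionally carry `rotation_onset_s` and `rotation_duration_s`, and
#' protocol traces carry `protocol_time_s` and `contraction_index`.
#'
#' @param time_s Numeric vector of sample times (s), uniform grid.
#' @param torque_Nm Numeric vector of torques (N m), same length.
#' @param meta Named list of metadata (see above); missing recording keys are
#'   an error, optional keys (`baseline_Nm`, rotation/protocol fields) are not.
#' @return A `force_trace` tibble.
#' @export
force_trace <- function(time_s, torque_Nm, meta) {
  tr <- tibble::tibble(time_s = as.numeric(time_s), torque_Nm = as.numeric(torque_Nm))
  class(tr) <- c("force_trace", class(tr))
  attr(tr, "meta") <- meta
  validate_force_trace(tr)
  tr
}

trace_required_meta <- c(
  "subject_id", "genotype", "age_months", "bodyweight_kg", "lever_arm_m",
  "nerve_target", "trace_kind", "stim_onset_s", "stim_end_s", "sampling_hz"
)

#' Metadata of a force trace
#' @param trace A `force_trace`.
#' @return Named list of metadata.
#' @export
trace_meta <- function(trace) attr(trace, "meta")

set_trace_meta <- function(trace, ...) {
  attr(trace, "meta") <- modifyList(attr(trace, "meta"), list(...))
  trace
}

validate_force_trace <- function(trace) {
  meta <- trace_meta(trace)
  missing_keys <- setdiff(trace_required_meta, names(meta))
  if (length(missing_keys)) {
    abort(paste0("trace metadata missing key(s): ", paste(missing_keys, collapse = ", ")),
          class = "musclephys_format_error")
  }
  if (nrow(trace) == 0) {
    abort("trace has no samples", class = "musclephys_validation_error")
  }
  if (anyNA(trace$torque_Nm) || anyNA(trace$time_s)) {
    abort("trace contains missing values", class = "musclephys_validation_error")
  }
  if (nrow(trace) > 1) {
    dt <- diff(trace$time_s)
    if (any(dt <= 0)) {
      abort("trace time must be strictly increasing", class = "musclephys_validation_error")
    }
    # constant step to within 1 ppm, and sampling_hz * dt = 1 +/- 1e-6
    if ((max(dt) - min(dt)) > 1e-6 * mean(dt)) {
      abort("trace time grid is not uniform", class = "musclephys_validation_error")
    }
    if (abs(meta$sampling_hz * mean(dt) - 1) > 1e-6) {
      abort("sampling_hz inconsistent with time step", class = "musclephys_validation_error")
    }
  }
  if (!meta$stim_onset_s < meta$stim_end_s) {
    abort("stim_onset_s must precede stim_end_s", class = "musclephys_validation_error")
  }
  if (meta$stim_end_s > trace$time_s[nrow(trace)] + 1e-9) {
    abort("stim_end_s lies beyond the recording", class = "musclephys_validation_error")
  }
  invisible(trace)
}

#' @export
print.force_trace <- function(x, ...) {
  meta <- trace_meta(x)
  cat(sprintf("<force_trace: %s %s, %s, %d samples @ %g Hz, stim %g-%g s>\n",
              meta$subject_id, meta$trace_kind, meta$nerve_target,
              nrow(x), meta$sampling_hz, meta$stim_onset_s, meta$stim_end_s))
  NextMethod()
}

#' Read a torque trace CSV
#'
#' The on-disk format is a long CSV with a `#`-prefixed `key: value` header
#' block followed by `time_s,torque_Nm` rows (or `time_ms`/`torque_mNm`, which
#' are converted to SI). The header must carry all required metadata keys.
#'
#' @param path Path to a trace CSV.
#' @return A validated [force_trace()].
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) abort(paste0("trace file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  meta <- parse_trace_header(lines[hdr])
  body <- lines[!hdr]
  if (length(body) < 1) abort("trace file has no data rows", class = "musclephys_format_error")
  cols <- strsplit(body[[1]], ",", fixed = TRUE)[[1]]
  dat <- utils::read.csv(text = body, check.names = FALSE)
  time_col <- intersect(c("time_s", "time_ms"), cols)
  torque_col <- intersect(c("torque_Nm", "torque_mNm"), cols)
  if (length(time_col) != 1 || length(torque_col) != 1) {
    abort("trace CSV must have time_s/time_ms and torque_Nm/torque_mNm columns",
          class = "musclephys_format_error")
  }
  time_s <- dat[[time_col]] * if (time_col == "time_ms") 1e-3 else 1
  torque <- dat[[torque_col]] * if (torque_col == "torque_mNm") 1e-3 else 1
  force_trace(time_s, torque, meta)
}

parse_trace_header <- function(hlines) {
  hlines <- sub("^#\\s*", "", hlines)
  hlines <- hlines[grepl(":", hlines)]
  keys <- trimws(sub(":.*$", "", hlines))
  vals <- trimws(sub("^[^:]*:", "", hlines))
  meta <- as.list(vals)
  names(meta) <- keys
  numeric_keys <- c("age_months", "bodyweight_kg", "lever_arm_m", "stim_onset_s",
                    "stim_end_s", "sampling_hz", "baseline_Nm", "rotation_onset_s",
                    "rotation_duration_s", "protocol_time_s", "contraction_index")
  for (k in intersect(numeric_keys, names(meta))) meta[[k]] <- as.numeric(meta[[k]])
  missing_keys <- setdiff(trace_required_meta, names(meta))
  if (length(missing_keys)) {
    abort(paste0("trace header missing key(s): ", paste(missing_keys, collapse = ", ")),
          class = "musclephys_format_error")
  }
  meta
}

#' Write a torque trace CSV
#'
#' Inverse of [read_trace()]: emits the full metadata header and the
#' `time_s,torque_Nm` body with enough digits for an exact round trip.
#'
#' @param trace A valid [force_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  validate_force_trace(trace)
  meta <- trace_meta(trace)
  fmt_val <- function(v) if (is.numeric(v)) format(v, digits = 17) else as.character(v)
  hdr <- paste0("# ", names(meta), ": ", vapply(meta, fmt_val, character(1)))
  body <- paste(format(trace$time_s, digits = 17, trim = TRUE, scientific = FALSE),
                format(trace$torque_Nm, digits = 17, trim = TRUE),
                sep = ",")
  writeLines(c(hdr, "time_s,torque_Nm", body), path)
  invisible(path)
}

# linear-interpolated torque at an exact time (grid-aligned times hit samples)
trace_value_at <- function(trace, t) {
  stats::approx(trace$time_s, trace$torque_Nm, xout = t, rule = 2)$y
}
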