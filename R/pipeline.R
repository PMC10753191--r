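#' Build a study manifest
#'
#' A manifest lists subjects and their recording files: one row per subject
#' with the subject metadata and list-columns of file paths by protocol.
#'
#' @param subjects Tibble with columns `subject_id`, `genotype`,
#'   `age_months`, `bodyweight_kg`, `lever_arm_m`.
#' @param twitch_files,tetanus_files,ecd_files Named lists (by subject id) of
#'   character vectors of trace CSV paths; ECD entries must be in protocol
#'   order.
#' @param qpcr_file Optional Cq CSV covering the cohort.
#' @return Tibble manifest of class `study_manifest`.
#' @export
study_manifest <- function(subjects, twitch_files = list(),
                           tetanus_files = list(), ecd_files = list(),
                           qpcr_file = NULL) {
  stopifnot(!anyDuplicated(subjects$subject_id))
  all_files <- unlist(c(twitch_files, tetanus_files, ecd_files, qpcr_file))
  missing_files <- all_files[!file.exists(all_files)]
  if (length(missing_files)) {
    abort(paste0("manifest references missing file(s): ",
                 paste(head(missing_files, 5), collapse = ", ")))
  }
  by_subject <- function(lst) {
    lapply(subjects$subject_id, function(id) lst[[id]] %||% character(0))
  }
  m <- subjects
  m$twitch_files <- by_subject(twitch_files)
  m$tetanus_files <- by_subject(tetanus_files)
  m$ecd_files <- by_subject(ecd_files)
  attr(m, "qpcr_file") <- qpcr_file
  class(m) <- c("study_manifest", class(m))
  m
}

#' Run the full study pipeline from a manifest
#'
#' For every subject: per-trace kinetics with QC (keeping, per the study
#' convention, the twitch/tetanus set with the highest torque when several
#' were recorded), the ECD protocol pipeline, and optional qPCR summaries;
#' then group summary tables (mean, sd, n per genotype) computed from
#' per-subject values, never from pooled traces. Stage errors are collected
#' per subject and the pipeline continues for the others.
#'
#' @param manifest A [study_manifest()].
#' @param config A [run_config()] list.
#' @return List of class `study_results`: `kinetics` (per-trace features),
#'   `ecd` (per-subject glance rows), `qpcr` (relative quantities and
#'   proportions, or `NULL`), `group_summary`, `errors` (tibble
#'   `subject_id`, `stage`, `message`), and `config`.
#' @export
run_study <- function(manifest, config = default_config()) {
  if (!nrow(manifest)) abort("empty manifest")
  errors <- list()
  note_error <- function(id, stage, e) {
    errors[[length(errors) + 1]] <<- tibble::tibble(subject_id = id, stage = stage,
                                                    message = conditionMessage(e))
    NULL
  }
  kin <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    paths <- c(manifest$twitch_files[[i]], manifest$tetanus_files[[i]])
    purrr::map_dfr(paths, function(p) {
      tryCatch(kinetics_features(read_trace(p), config),
               error = function(e) note_error(id, paste0("kinetics:", basename(p)), e))
    })
  })
  if (nrow(kin)) {
    # one set per (subject, kind): keep the set with the highest torque
    kin <- kin |>
      dplyr::group_by(.data$subject_id, .data$trace_kind) |>
      dplyr::arrange(dplyr::desc(dplyr::coalesce(.data$reference_Nm, -Inf)),
                     .by_group = TRUE) |>
      dplyr::slice(1) |>
      dplyr::ungroup()
  }
  ecd <- purrr::map_dfr(seq_len(nrow(manifest)), function(i) {
    id <- manifest$subject_id[i]
    paths <- manifest$ecd_files[[i]]
    if (!length(paths)) return(NULL)
    tryCatch({
      traces <- lapply(paths, read_trace)
      glance(ecd_series(traces, config))
    }, error = function(e) note_error(id, "ecd", e))
  })
  qp <- NULL
  qpcr_file <- attr(manifest, "qpcr_file")
  if (!is.null(qpcr_file)) {
    qp <- tryCatch({
      collapsed <- collapse_replicates(read_qpcr(qpcr_file))
      list(relative = relative_quantity(collapsed),
           proportions_all = isoform_proportions(collapsed, "all"),
           proportions_nonregen = isoform_proportions(collapsed, "nonregenerative"))
    }, error = function(e) note_error(NA_character_, "qpcr", e))
  }
  summarise_group <- function(df, value_col, metric) {
    if (is.null(df) || !nrow(df)) return(NULL)
    df |>
      dplyr::filter(is.finite(.data[[value_col]])) |>
      dplyr::group_by(.data$genotype) |>
      dplyr::summarise(metric = metric, mean = mean(.data[[value_col]]),
                       sd = sd(.data[[value_col]]), n = dplyr::n(),
                       .groups = "drop")
  }
  group_summary <- dplyr::bind_rows(
    if (nrow(kin)) kin |> dplyr::filter(.data$trace_kind == "twitch") |>
      summarise_group("absolute_force_N", "twitch_absolute_force_N"),
    if (nrow(kin)) kin |> dplyr::filter(.data$trace_kind == "tetanus") |>
      summarise_group("absolute_force_N", "tetanus_absolute_force_N"),
    if (nrow(ecd)) summarise_group(ecd, "final_decrement_pct", "ecd_final_decrement_pct"),
    if (nrow(ecd)) summarise_group(ecd, "max_abs_force_N", "ecd_max_abs_force_N")
  )
  structure(list(kinetics = kin, ecd = ecd, qpcr = qp,
                 group_summary = group_summary,
                 errors = dplyr::bind_rows(errors), config = config),
            class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results: %d kinetics rows, %d ECD subjects, %d error(s)>\n",
              nrow(x$kinetics), if (is.null(x$ecd)) 0L else nrow(x$ecd),
              nrow(x$errors)))
  invisible(x)
}

#' Write a study results bundle to CSV files
#'
#' Emits `kinetics.csv`, `ecd_results.csv`, `group_summary.csv`, optional
#' qPCR CSVs and a `run_log.txt` recording the configuration and package
#' version, into `dir`. Re-running with the same inputs and configuration
#' reproduces the files byte-identically.
#'
#' @param results A `study_results` bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  flat_kin <- dplyr::select(results$kinetics,
                            -dplyr::any_of(c("contraction_times", "relaxation_times")))
  utils::write.csv(flat_kin, file.path(dir, "kinetics.csv"), row.names = FALSE)
  if (!is.null(results$ecd) && nrow(results$ecd)) {
    utils::write.csv(results$ecd, file.path(dir, "ecd_results.csv"), row.names = FALSE)
  }
  if (!is.null(results$group_summary)) {
    utils::write.csv(results$group_summary, file.path(dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  if (!is.null(results$qpcr)) {
    utils::write.csv(results$qpcr$relative, file.path(dir, "rel_expression.csv"),
                     row.names = FALSE)
    utils::write.csv(results$qpcr$proportions_all, file.path(dir, "proportions.csv"),
                     row.names = FALSE)
  }
  log_lines <- c(paste0("musclephys version: ",
                        as.character(utils::packageVersion("musclephys"))),
                 "configuration:",
                 paste0("  ", names(results$config), " = ",
                        vapply(results$config, function(v) paste(format(v), collapse = ","),
                               character(1))))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}
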