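#' Bleed-through correction of the collagen boundary channel
#'
#' Aberrant signal bleed-through of the fast-myosin fluorophore (594) into
#' the collagen VI channel (647) is removed by channel subtraction:
#' `clip(collagen_647 - fast_594, 0, 255)` in integer arithmetic.
#'
#' @param image A [multichannel_image()].
#' @return Corrected boundary plane (integer matrix, 0-255).
#' @export
bleedthrough_correct <- function(image) {
  co <- image$channels$collagen_647
  fa <- image$channels$fast_594
  if (!identical(dim(co), dim(fa))) abort("channel shape mismatch")
  pmin(pmax(round(co - fa), 0), 255)
}

#' Fibre instance mask from the corrected boundary plane
#'
#' Mirrors the reference workflow: threshold the corrected boundary plane from
#' `min_level` to 255, take the complement as fibre interiors, then split
#' touching fibres with a watershed on the interior distance transform.
#' Isolated sub-threshold pixels inside fibres are removed by per-object hole
#' filling before the watershed so that speckle does not seed spurious
#' catchment basins.
#'
#' @param boundary_plane Corrected plane from [bleedthrough_correct()].
#' @param min_level Boundary threshold (8-bit intensity, default 1).
#' @param ws_tolerance Watershed tolerance (distance-map units); basins
#'   shallower than this merge with their neighbour.
#' @param despeckle_px Boundary connected components smaller than this are
#'   treated as speckle (isolated supra-threshold noise pixels inside fibres)
#'   and removed before segmentation; real boundary walls form components
#'   orders of magnitude larger.
#' @return Integer label matrix (0 = boundary/background).
#' @export
fibre_mask <- function(boundary_plane, min_level = 1, ws_tolerance = 2,
                       despeckle_px = 16) {
  bnd <- boundary_plane >= min_level
  if (all(bnd)) abort("all-boundary image: nothing to segment")
  if (!any(bnd)) abort("all-interior image: no boundaries at this threshold")
  bl <- EBImage::bwlabel(bnd)
  sizes <- tabulate(bl[bl > 0])
  speckle <- which(sizes < despeckle_px)
  if (length(speckle) == length(sizes)) speckle <- integer(0)  # keep something
  bnd[matrix(bl %in% speckle, nrow(bnd), ncol(bnd))] <- FALSE
  interior <- !bnd
  dm <- EBImage::distmap(interior)
  labels <- EBImage::watershed(dm, tolerance = ws_tolerance, ext = 1)
  matrix(as.integer(labels), nrow(boundary_plane), ncol(boundary_plane))
}

# one-pass per-label bookkeeping: area, bbox, edge contact
label_summary <- function(labels) {
  h <- nrow(labels); w <- ncol(labels)
  idx <- which(labels > 0)
  lab <- labels[idx]
  if (!length(lab)) {
    return(tibble::tibble(roi_id = integer(0), area_px = integer(0),
                          rmin = integer(0), rmax = integer(0),
                          cmin = integer(0), cmax = integer(0),
                          touches_edge = logical(0)))
  }
  ri <- (idx - 1L) %% h + 1L
  ci <- (idx - 1L) %/% h + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  tibble::tibble(
    roi_id = ids,
    area_px = as.integer(tabulate(f)),
    rmin = as.integer(tapply(ri, f, min)), rmax = as.integer(tapply(ri, f, max)),
    cmin = as.integer(tapply(ci, f, min)), cmax = as.integer(tapply(ci, f, max)),
    touches_edge = as.logical(tapply(ri == 1L | ri == h | ci == 1L | ci == w,
                                     f, any))
  )
}

# Moore-neighbour contour tracing of a single 8-connected object; returns the
# closed chain-code perimeter with sqrt(2) weighting for diagonal steps.
# Termination is Jacob's criterion (stop on re-tracing the initial move from
# the start pixel), which handles one-pixel-wide spurs passing through the
# start. A single isolated pixel is given perimeter 1.
chain_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask
  hh <- h + 2L
  start <- which(m)[1]  # column-major scan: the pixel above is background
  sr <- (start - 1L) %% hh + 1L
  sc <- (start - 1L) %/% hh + 1L
  # clockwise neighbour offsets starting North
  dr <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  dc <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  step_len <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  dir_of <- matrix(NA_integer_, 3, 3)
  for (d in 1:8) dir_of[dr[d] + 2L, dc[d] + 2L] <- d
  pr <- sr; pc <- sc          # current pixel
  br <- sr - 1L; bc <- sc     # backtrack: last examined background pixel
  perim <- 0
  first_dir <- NA_integer_
  max_steps <- 8L * (sum(m) + 2L)
  for (iter in seq_len(max_steps)) {
    db <- dir_of[br - pr + 2L, bc - pc + 2L]
    found <- 0L
    for (k in 1L:8L) {
      d <- (db - 1L + k) %% 8L + 1L
      nr <- pr + dr[d]; nc <- pc + dc[d]
      if (m[nr, nc]) { found <- d; break }
      br <- nr; bc <- nc
    }
    if (found == 0L) return(1)  # isolated pixel
    if (is.na(first_dir)) {
      first_dir <- found
    } else if (pr == sr && pc == sc && found == first_dir) {
      break
    }
    perim <- perim + step_len[found]
    pr <- pr + dr[found]; pc <- pc + dc[found]
  }
  perim
}

#' Particle filter over labelled fibre ROIs
#'
#' Reproduces the reference particle-analysis settings: keep ROIs with area
#' at least `min_area` px, chain-code circularity `4*pi*A/P^2` within
#' `circ_range` (values above 1 from digitisation are clamped to 1), and no
#' contact with the image border. The perimeter is the Moore-traced boundary
#' chain with `sqrt(2)` weighting for diagonal steps.
#'
#' @param labels Integer label matrix from [fibre_mask()].
#' @param min_area Minimum area (px), default 300.
#' @param circ_range Circularity interval, default `c(0.40, 1.00)`.
#' @return Tibble of accepted ROIs: `roi_id`, `area_px`, `perimeter_px`,
#'   `circularity`, `touches_edge`; attribute `all_rois` holds the same table
#'   before filtering.
#' @export
particle_filter <- function(labels, min_area = 300, circ_range = c(0.40, 1.00)) {
  info <- label_summary(labels)
  perim <- vapply(seq_len(nrow(info)), function(i) {
    sub <- labels[info$rmin[i]:info$rmax[i], info$cmin[i]:info$cmax[i], drop = FALSE]
    chain_perimeter(sub == info$roi_id[i])
  }, numeric(1))
  rois <- dplyr::mutate(
    info[c("roi_id", "area_px", "touches_edge")],
    perimeter_px = perim,
    circularity = pmin(4 * pi * .data$area_px / .data$perimeter_px^2, 1)
  )
  accepted <- dplyr::filter(
    rois,
    .data$area_px >= min_area,
    .data$circularity >= circ_range[1], .data$circularity <= circ_range[2],
    !.data$touches_edge
  )
  attr(accepted, "all_rois") <- rois
  accepted
}

#' Mean marker fluorescence within each ROI
#'
#' @param image A [multichannel_image()].
#' @param labels Integer label matrix aligned with `image`.
#' @param rois ROI table from [particle_filter()].
#' @return `rois` with `mean_slow`, `mean_regen`, `mean_fast` columns
#'   (arithmetic means of `slow_350`, `regen_488`, `fast_594`).
#' @export
measure_rois <- function(image, labels, rois) {
  if (!identical(dim(labels), image$dim)) abort("labels do not align with image shape")
  if (!nrow(rois)) abort("empty ROI set")
  sel <- labels > 0 & matrix(labels %in% rois$roi_id, nrow(labels), ncol(labels))
  lab <- labels[sel]
  f <- factor(lab, levels = rois$roi_id)
  if (any(tabulate(f) == 0)) abort("ROI with no pixels")
  ch_mean <- function(plane) as.numeric(tapply(plane[sel], f, mean))
  dplyr::mutate(rois,
                mean_slow = ch_mean(image$channels$slow_350),
                mean_regen = ch_mean(image$channels$regen_488),
                mean_fast = ch_mean(image$channels$fast_594))
}

# 1-D Otsu: exhaustive scan of midpoint cutoffs maximising the between-class
# variance of ROI mean intensities
otsu_1d <- function(v) {
  vs <- sort(unique(v))
  if (length(vs) < 2) return(list(cutoff = vs[1], separation_ok = FALSE))
  cand <- (vs[-1] + vs[-length(vs)]) / 2
  bcv <- vapply(cand, function(ct) {
    lo <- v < ct
    w1 <- mean(lo)
    w1 * (1 - w1) * (mean(v[lo]) - mean(v[!lo]))^2
  }, numeric(1))
  ct <- cand[which.max(bcv)]
  lo <- v < ct
  s1 <- if (sum(lo) > 1) sd(v[lo]) else 0
  s2 <- if (sum(!lo) > 1) sd(v[!lo]) else 0
  n1 <- sum(lo); n2 <- sum(!lo)
  pooled <- sqrt(((max(n1 - 1, 0)) * s1^2 + (max(n2 - 1, 0)) * s2^2) /
                   max(n1 + n2 - 2, 1))
  # bimodality check: splitting a single Gaussian at its Otsu cutoff already
  # yields a class separation of ~2.7 pooled within-class sd, so a threshold
  # of 2 cannot reject unimodal channels; 4 separates the unimodal case from
  # genuinely stained/unstained populations, which sit far apart
  list(cutoff = ct, separation_ok = (mean(v[!lo]) - mean(v[lo])) >= 4 * pooled)
}

#' Automatic classification thresholds from ROI measurements
#'
#' The reference workflow sets fibre-type thresholds interactively from ROI
#' clustering plots; this deterministic replacement computes, per marker
#' channel, a two-class Otsu cutoff on the ROI mean intensities, flagging
#' channels whose two classes are not clearly bimodal (class separation below
#' 2 pooled standard deviations, e.g. a channel with no positive fibres).
#' Manual thresholds (the `manual` argument) skip the automatic fit.
#'
#' @param measurements ROI table from [measure_rois()] (>= 20 ROIs).
#' @param manual Optional named vector `c(slow=, fast=, regen=)` of manual
#'   cutoffs on the 0-255 scale.
#' @param min_rois Minimum ROI count for the automatic fit.
#' @return Tibble `channel`, `cutoff`, `low_confidence`, `source`.
#' @export
auto_thresholds <- function(measurements, manual = NULL, min_rois = 20) {
  if (!is.null(manual)) {
    if (!setequal(names(manual), c("slow", "fast", "regen"))) {
      abort("manual thresholds must be named slow, fast, regen")
    }
    return(tibble::tibble(channel = c("slow", "fast", "regen"),
                          cutoff = unname(manual[c("slow", "fast", "regen")]),
                          low_confidence = FALSE, source = "manual"))
  }
  if (nrow(measurements) < min_rois) {
    abort(sprintf(paste0("only %d ROIs; at least %d are needed for automatic ",
                         "thresholds -- supply manual thresholds"),
                  nrow(measurements), min_rois))
  }
  res <- purrr::map(list(slow = measurements$mean_slow,
                         fast = measurements$mean_fast,
                         regen = measurements$mean_regen), otsu_1d)
  ok <- vapply(res, `[[`, logical(1), "separation_ok")
  cutoff <- vapply(res, `[[`, numeric(1), "cutoff")
  # a channel without a clearly separated positive population (e.g. no
  # regenerating fibres in a healthy section) has no meaningful Otsu cutoff:
  # fall back to the half-scale intensity so a single negative (or positive)
  # cluster is called uniformly, and flag the channel for review
  cutoff[!ok] <- 255 / 2
  tibble::tibble(channel = names(res), cutoff = unname(cutoff),
                 low_confidence = unname(!ok), source = "auto")
}

threshold_vector <- function(thresholds) {
  setNames(thresholds$cutoff, thresholds$channel)[c("slow", "fast", "regen")]
}

#' Classify ROIs into the seven fibre categories
#'
#' A channel is called positive when the ROI mean exceeds its cutoff; the
#' flag triplet determines the category uniquely; triple-negative ROIs are
#' `unclassified`. Reporting classes group the four regeneration-positive
#' categories into `regenerating`.
#'
#' @param measurements ROI table from [measure_rois()].
#' @param thresholds Threshold table from [auto_thresholds()].
#' @return `measurements` plus `slow_pos`, `fast_pos`, `regen_pos`,
#'   `category`, `reporting_class`.
#' @export
classify_fibres <- function(measurements, thresholds) {
  tv <- threshold_vector(thresholds)
  out <- dplyr::mutate(measurements,
                       slow_pos = .data$mean_slow > tv[["slow"]],
                       fast_pos = .data$mean_fast > tv[["fast"]],
                       regen_pos = .data$mean_regen > tv[["regen"]])
  cat_of <- function(s, f, r) {
    dplyr::case_when(
      !s & !f & !r ~ "unclassified",
      s & !f & !r ~ "slow",
      !s & f & !r ~ "fast",
      s & f & !r ~ "fast_slow",
      !s & !f & r ~ "regen",
      !s & f & r ~ "fast_regen",
      s & !f & r ~ "slow_regen",
      TRUE ~ "fast_slow_regen"
    )
  }
  dplyr::mutate(out,
                category = cat_of(.data$slow_pos, .data$fast_pos, .data$regen_pos),
                reporting_class = reporting_class_of(.data$category))
}

#' Per-image and per-subject fibre-type composition
#'
#' Per image, the percentage of each reporting class among all accepted ROIs
#' (classified plus unclassified); per subject, the unweighted mean over its
#' images, matching the study convention of averaging five fields of view
#' per muscle.
#'
#' @param calls Classified ROI table (from [classify_fibres()]) with
#'   `image_id` and `subject_id` columns.
#' @return Long tibble `image_id`, `subject_id`, `reporting_class`,
#'   `n_fibres`, `pct` (per image, percentages sum to 100).
#' @export
fibre_composition <- function(calls) {
  need <- c("image_id", "subject_id", "reporting_class")
  if (!all(need %in% names(calls))) {
    abort("calls must carry image_id and subject_id columns")
  }
  counts <- calls |>
    dplyr::count(.data$subject_id, .data$image_id, .data$reporting_class,
                 name = "n_fibres") |>
    tidyr::complete(tidyr::nesting(!!rlang::sym("subject_id"),
                                   !!rlang::sym("image_id")),
                    reporting_class = reporting_classes(),
                    fill = list(n_fibres = 0L))
  counts |>
    dplyr::group_by(.data$subject_id, .data$image_id) |>
    dplyr::mutate(pct = 100 * .data$n_fibres / sum(.data$n_fibres)) |>
    dplyr::ungroup()
}

#' @rdname fibre_composition
#' @param composition Per-image table from `fibre_composition()`.
#' @return For `subject_composition()`: tibble `subject_id`,
#'   `reporting_class`, `mean_pct`, `n_images`. Subjects with no accepted
#'   ROIs are dropped with a warning.
#' @export
subject_composition <- function(composition) {
  empty <- composition |>
    dplyr::group_by(.data$subject_id, .data$image_id) |>
    dplyr::summarise(tot = sum(.data$n_fibres), .groups = "drop") |>
    dplyr::filter(.data$tot == 0)
  if (nrow(empty)) {
    warn(paste0("images with zero accepted ROIs dropped: ",
                paste(unique(empty$image_id), collapse = ", ")))
    composition <- dplyr::anti_join(composition, empty,
                                    by = c("subject_id", "image_id"))
  }
  composition |>
    dplyr::group_by(.data$subject_id, .data$reporting_class) |>
    dplyr::summarise(mean_pct = mean(.data$pct),
                     n_images = dplyr::n_distinct(.data$image_id),
                     .groups = "drop")
}

#' Run the full fibre-typing pipeline on one image
#'
#' Bleed-through correction, mask and watershed segmentation, particle
#' filtering, ROI measurement, threshold fitting (unless supplied) and
#' classification.
#'
#' @param image A [multichannel_image()].
#' @param config A [run_config()] list.
#' @param thresholds Optional threshold table (e.g. fitted on a reference
#'   image, or manual); fitted per image when `NULL`.
#' @return List: `calls` (classified ROI table), `labels` (label matrix),
#'   `thresholds`.
#' @export
fibretype_image <- function(image, config = default_config(), thresholds = NULL) {
  bnd <- bleedthrough_correct(image)
  labels <- fibre_mask(bnd, config$fibretype.min_level, config$fibretype.ws_tolerance)
  rois <- particle_filter(labels, config$fibretype.min_area_px,
                          c(config$fibretype.circ_min, config$fibretype.circ_max))
  meas <- measure_rois(image, labels, rois)
  if (is.null(thresholds)) {
    thresholds <- auto_thresholds(meas, min_rois = config$fibretype.min_rois)
  }
  calls <- classify_fibres(meas, thresholds)
  list(calls = calls, labels = labels, thresholds = thresholds)
}

#' Score detected ROIs against synthetic ground truth
#'
#' Each accepted ROI is matched to the true fibre owning the majority (> 50%)
#' of its pixels. The detection fraction is the share of true fibres matched
#' by at least one ROI; the composition error is the maximum absolute
#' difference, over reporting classes, between the detected and true
#' composition percentages.
#'
#' @param labels Label matrix from [fibre_mask()].
#' @param calls Classified accepted ROI table.
#' @param truth Ground truth from [generate_section()] (`$truth`).
#' @return One-row tibble: `n_true`, `n_detected`, `n_matched`,
#'   `detection_fraction`, `composition_error_pct`.
#' @export
evaluate_detection <- function(labels, calls, truth) {
  tm <- truth$label_mask
  matched <- integer(0)
  for (id in calls$roi_id) {
    px <- tm[labels == id]
    tb <- table(px[px > 0])
    if (length(tb)) {
      best <- as.integer(names(tb)[which.max(tb)])
      if (max(tb) > 0.5 * length(px)) matched <- c(matched, best)
    }
  }
  matched <- unique(matched)
  true_comp <- 100 * prop.table(table(factor(truth$fibres$reporting_class,
                                             levels = reporting_classes())))
  det_comp <- 100 * prop.table(table(factor(calls$reporting_class,
                                            levels = reporting_classes())))
  tibble::tibble(
    n_true = nrow(truth$fibres),
    n_detected = nrow(calls),
    n_matched = length(matched),
    detection_fraction = length(matched) / nrow(truth$fibres),
    composition_error_pct = max(abs(as.numeric(true_comp) - as.numeric(det_comp)))
  )
}
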