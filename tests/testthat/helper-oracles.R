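# Independent oracles used across the suite. These deliberately re-derive
# quantities through different algorithms/code paths than the package.

# Counterclockwise Moore contour tracing started from the row-major first
# foreground pixel (the package traces clockwise from the column-major first
# pixel); the closed chain length is invariant to direction and start, so
# agreement is a genuine cross-check.
oracle_chain_perimeter <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  m <- matrix(FALSE, h + 2L, w + 2L)
  m[2:(h + 1L), 2:(w + 1L)] <- mask
  coords <- which(m, arr.ind = TRUE)
  ord <- order(coords[, 1], coords[, 2])  # row-major scan
  sr <- coords[ord[1], 1]; sc <- coords[ord[1], 2]
  # counterclockwise offsets starting West (the West neighbour of the
  # row-major first pixel is background)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  step_len <- ifelse(dr != 0L & dc != 0L, sqrt(2), 1)
  dir_of <- matrix(NA_integer_, 3, 3)
  for (d in 1:8) dir_of[dr[d] + 2L, dc[d] + 2L] <- d
  pr <- sr; pc <- sc
  br <- sr; bc <- sc - 1L
  perim <- 0
  first_dir <- NA_integer_
  for (iter in seq_len(8L * (sum(m) + 2L))) {
    db <- dir_of[br - pr + 2L, bc - pc + 2L]
    found <- 0L
    for (k in 1L:8L) {
      d <- (db - 1L + k) %% 8L + 1L
      nr <- pr + dr[d]; nc <- pc + dc[d]
      if (m[nr, nc]) { found <- d; break }
      br <- nr; bc <- nc
    }
    if (found == 0L) return(1)
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

# Brute-force per-ROI re-check of the particle filter: area by pixel count,
# edge contact from full-image masks, perimeter by the counterclockwise
# tracer above.
oracle_particle_check <- function(labels, min_area = 300, circ_range = c(0.40, 1.00)) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  h <- nrow(labels); w <- ncol(labels)
  purrr::map_dfr(ids, function(id) {
    msk <- labels == id
    area <- sum(msk)
    touches <- any(msk[1, ]) || any(msk[h, ]) || any(msk[, 1]) || any(msk[, w])
    idx <- which(msk, arr.ind = TRUE)
    sub <- msk[min(idx[, 1]):max(idx[, 1]), min(idx[, 2]):max(idx[, 2]), drop = FALSE]
    per <- oracle_chain_perimeter(sub)
    circ <- min(4 * pi * area / per^2, 1)
    tibble::tibble(roi_id = id, area_px = area, perimeter_px = per,
                   circularity = circ, touches_edge = touches,
                   keep = area >= min_area & circ >= circ_range[1] &
                     circ <= circ_range[2] & !touches)
  })
}

# noise-free twitch/tetanus models re-stated as closed forms for root finding
oracle_twitch_relax_time <- function(fraction, tau_fast, tau_slow, slow_frac) {
  f <- function(d) {
    (1 - slow_frac) * exp(-d / tau_fast) + slow_frac * exp(-d / tau_slow) -
      (1 - fraction)
  }
  stats::uniroot(f, c(0, 100), tol = 1e-12)$root
}

make_test_trace <- function(time_s, torque_Nm, kind = "twitch",
                            stim_onset = 0.05, stim_end = NULL,
                            sampling_hz = NULL, ...) {
  dt <- diff(time_s)[1]
  force_trace(time_s, torque_Nm, modifyList(list(
    subject_id = "T-01", genotype = "WT", age_months = 12, bodyweight_kg = 10,
    lever_arm_m = 0.1, nerve_target = "fibular", trace_kind = kind,
    stim_onset_s = stim_onset,
    stim_end_s = stim_end %||% (time_s[length(time_s)]),
    sampling_hz = sampling_hz %||% (1 / dt)), list(...)))
}
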