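#' Fibre categories and reporting classes
#'
#' Seven detectable categories from the three marker channels (slow MHC, fast
#' MHC, embryonic MHC), plus `unclassified` for triple-negative ROIs. For
#' reporting, the four regeneration-positive categories are grouped into a
#' single `regenerating` class.
#'
#' @return Character vector of the seven category names.
#' @export
fibre_categories <- function() {
  c("slow", "fast", "fast_slow", "regen", "fast_regen", "slow_regen",
    "fast_slow_regen")
}

#' @rdname fibre_categories
#' @return For `reporting_classes()`, the five reporting class names.
#' @export
reporting_classes <- function() {
  c("type_I", "type_II", "hybrid_I_II", "regenerating", "unclassified")
}

#' Map fibre categories to reporting classes
#' @param category Character vector of category names (or `unclassified`).
#' @return Character vector of reporting classes.
#' @export
reporting_class_of <- function(category) {
  map <- c(slow = "type_I", fast = "type_II", fast_slow = "hybrid_I_II",
           regen = "regenerating", fast_regen = "regenerating",
           slow_regen = "regenerating", fast_slow_regen = "regenerating",
           unclassified = "unclassified")
  unname(map[category])
}

#' Reference fibre-type compositions of the canine cranial tibial muscle
#'
#' Reporting-class compositions observed in 18-month-old dogs (wild type:
#' type I 41%, type II 58%, hybrid 1%, regenerating 0.2%; dystrophic DE50-MD:
#' 20% / 69% / 4% / 7%), expanded to the seven generator categories with the
#' regenerating share split across its four subclasses, and normalised to
#' sum to 1.
#'
#' @param genotype `"WT"` or `"DE50-MD"`.
#' @return Named numeric vector over [fibre_categories()], summing to 1.
#' @export
composition_cranial_tibial <- function(genotype = c("WT", "DE50-MD")) {
  genotype <- match.arg(genotype)
  cls <- if (genotype == "WT") {
    c(type_I = 41, type_II = 58, hybrid_I_II = 1, regenerating = 0.2)
  } else {
    c(type_I = 20, type_II = 69, hybrid_I_II = 4, regenerating = 7)
  }
  regen_split <- c(regen = 0.55, fast_regen = 0.2, slow_regen = 0.2,
                   fast_slow_regen = 0.05)
  comp <- c(slow = unname(cls["type_I"]), fast = unname(cls["type_II"]),
            fast_slow = unname(cls["hybrid_I_II"]),
            unname(cls["regenerating"]) * regen_split)
  comp / sum(comp)
}

#' Synthetic muscle-section parameters
#'
#' The generator emulates a transverse immunofluorescence section: fibres are
#' a nearest-seed tessellation of Poisson-disc seed points (minimum spacing
#' keeps cells above the 300 px particle-filter floor), outlined by a
#' collagen boundary of the stated width, with per-fibre marker intensities
#' drawn per pixel from the type's channel means, bleed-through of the fast
#' channel into the collagen channel, and additive background noise.
#'
#' @param shape Image shape `c(rows, cols)` in pixels.
#' @param n_fibres Target fibre count.
#' @param composition Named probability vector over [fibre_categories()].
#' @param boundary_width_px Collagen boundary width (px), >= 1.
#' @param intensity_pos,intensity_neg Channel mean for marker-positive /
#'   -negative fibres (8-bit scale).
#' @param intensity_sd Per-pixel intensity sd inside fibres.
#' @param boundary_intensity Collagen mean on fibre boundaries.
#' @param bleedthrough_beta Fraction of the fast (594) plane added into the
#'   collagen (647) plane, in `[0, 1)`.
#' @param background_noise_sd Additive Gaussian noise sd outside fibres.
#' @return Parameter list of class `section_params`.
#' @export
section_params <- function(shape = c(512, 512), n_fibres = 60,
                           composition = composition_cranial_tibial("WT"),
                           boundary_width_px = 3, intensity_pos = 180,
                           intensity_neg = 20, intensity_sd = 12,
                           boundary_intensity = 200, bleedthrough_beta = 0.3,
                           background_noise_sd = 2) {
  stopifnot(length(shape) == 2, boundary_width_px >= 1,
            bleedthrough_beta >= 0, bleedthrough_beta < 1,
            intensity_pos >= 0, intensity_pos <= 255,
            intensity_neg >= 0, intensity_neg <= 255)
  if (!setequal(names(composition), fibre_categories())) {
    abort(paste0("composition must be named over: ",
                 paste(fibre_categories(), collapse = ", ")))
  }
  if (abs(sum(composition) - 1) > 1e-8) abort("composition must sum to 1")
  structure(list(shape = shape, n_fibres = n_fibres,
                 composition = composition[fibre_categories()],
                 boundary_width_px = boundary_width_px,
                 intensity_pos = intensity_pos, intensity_neg = intensity_neg,
                 intensity_sd = intensity_sd,
                 boundary_intensity = boundary_intensity,
                 bleedthrough_beta = bleedthrough_beta,
                 background_noise_sd = background_noise_sd),
            class = "section_params")
}

# dart-throwing Poisson-disc sampler inside [lo_r, hi_r] x [lo_c, hi_c]
poisson_disc <- function(n, min_dist, lo_r, hi_r, lo_c, hi_c, max_attempts = 80 * n) {
  pr <- numeric(0); pc <- numeric(0)
  att <- 0
  while (length(pr) < n && att < max_attempts) {
    att <- att + 1
    r <- runif(1, lo_r, hi_r); c <- runif(1, lo_c, hi_c)
    if (!length(pr) || min((pr - r)^2 + (pc - c)^2) >= min_dist^2) {
      pr <- c(pr, r); pc <- c(pc, c)
    }
  }
  cbind(row = pr, col = pc)
}

# positivity of the three marker channels by category
category_flags <- function(category) {
  tibble::tibble(
    category = category,
    slow_pos = category %in% c("slow", "fast_slow", "slow_regen", "fast_slow_regen"),
    fast_pos = category %in% c("fast", "fast_slow", "fast_regen", "fast_slow_regen"),
    regen_pos = category %in% c("regen", "fast_regen", "slow_regen", "fast_slow_regen")
  )
}

#' Generate a synthetic labelled muscle section
#'
#' @param params A [section_params()] list.
#' @param seed Integer seed; the output is a pure function of
#'   (params, seed).
#' @return List of class `synthetic_section`: `image` (a
#'   [multichannel_image()]), `truth` (list with `label_mask` -- integer
#'   matrix, 0 = boundary/background -- and `fibres`, a tibble of `fibre_id`,
#'   `category`, `reporting_class`, `area_px`, `centroid_row`,
#'   `centroid_col`), and `params`.
#' @export
generate_section <- function(params, seed = 1) {
  p <- params
  withr::with_seed(seed, generate_section_impl(p))
}

generate_section_impl <- function(p) {
  h <- p$shape[1]; w <- p$shape[2]
  # minimum seed spacing from the saturation density of a Poisson-disc
  # process (~0.62 * area / spacing^2 points), iterated once for the margin
  r <- sqrt(0.62 * h * w / p$n_fibres)
  margin <- 1.35 * r + p$boundary_width_px + 2
  usable <- (h - 2 * margin) * (w - 2 * margin)
  if (usable <= 0) abort("n_fibres incompatible with shape (over-packing)")
  r <- sqrt(0.62 * usable / p$n_fibres)
  margin <- 1.35 * r + p$boundary_width_px + 2
  usable <- (h - 2 * margin) * (w - 2 * margin)
  if (usable <= 0 || usable / p$n_fibres < 350) {
    abort("n_fibres incompatible with shape (over-packing)")
  }
  seeds <- poisson_disc(p$n_fibres, r, margin, h - margin, margin, w - margin)
  if (nrow(seeds) < p$n_fibres) {
    abort("n_fibres incompatible with shape (over-packing)")
  }
  # trim radius 1.35x the seed spacing: cells stay polygonal at shared
  # bisector walls while interstitial gaps (rare empty pockets between
  # sparse seeds) close up, as in a confluent muscle section
  labels <- tessellate_labels(seeds[, "row"], seeds[, "col"], h, w,
                              p$boundary_width_px, 1.35 * r)
  n <- nrow(seeds)
  category <- sample(fibre_categories(), n, replace = TRUE, prob = p$composition)
  flags <- category_flags(category)

  interior <- labels > 0
  boundary <- labels == -1
  lab_vec <- labels[interior]

  mk_marker_plane <- function(pos_by_fibre) {
    mu <- matrix(p$intensity_neg, h, w)
    mu_fibre <- ifelse(pos_by_fibre, p$intensity_pos, p$intensity_neg)
    mu[interior] <- mu_fibre[lab_vec]
    noise_sd <- matrix(p$background_noise_sd, h, w)
    noise_sd[interior] <- p$intensity_sd
    plane <- mu + rnorm(h * w) * noise_sd
    matrix(pmin(pmax(round(plane), 0), 255), h, w)
  }
  slow_pl <- mk_marker_plane(flags$slow_pos)
  regen_pl <- mk_marker_plane(flags$regen_pos)
  fast_pl <- mk_marker_plane(flags$fast_pos)

  col_mu <- matrix(0, h, w)
  col_mu[boundary] <- p$boundary_intensity
  col_sd <- matrix(p$background_noise_sd, h, w)
  col_sd[boundary] <- p$intensity_sd
  col_pl <- col_mu + rnorm(h * w) * col_sd + p$bleedthrough_beta * fast_pl
  col_pl <- matrix(pmin(pmax(round(col_pl), 0), 255), h, w)

  image <- multichannel_image(list(slow_350 = slow_pl, regen_488 = regen_pl,
                                   fast_594 = fast_pl, collagen_647 = col_pl))
  label_mask <- labels
  label_mask[label_mask < 0] <- 0L
  area <- tabulate(lab_vec, nbins = n)
  rr <- row(labels)[interior]; cc <- col(labels)[interior]
  cen_r <- as.numeric(tapply(rr, lab_vec, mean))
  cen_c <- as.numeric(tapply(cc, lab_vec, mean))
  fibres <- tibble::tibble(fibre_id = seq_len(n), category = category,
                           reporting_class = reporting_class_of(category),
                           area_px = area, centroid_row = cen_r,
                           centroid_col = cen_c,
                           seed_row = seeds[, "row"], seed_col = seeds[, "col"])
  structure(list(image = image,
                 truth = list(label_mask = label_mask, fibres = fibres),
                 params = p),
            class = "synthetic_section")
}

#' @export
print.synthetic_section <- function(x, ...) {
  cat(sprintf("<synthetic_section %d x %d, %d fibres>\n",
              x$params$shape[1], x$params$shape[2], nrow(x$truth$fibres)))
  invisible(x)
}

#' Apply a named corruption to a synthetic section
#'
#' Robustness probes for the fibre-typing pipeline:
#' \describe{
#'   \item{crop}{Crops `crop_px` from each border so peripheral fibres touch
#'     the image edge; truth is cropped accordingly and partially lost fibres
#'     keep their (reduced) pixel support.}
#'   \item{darken}{Multiplies channel `channel` by `factor`.}
#'   \item{fuse}{Erases the collagen boundary between `n_pairs` randomly
#'     chosen adjacent fibre pairs, fusing their masks.}
#' }
#'
#' @param section A `synthetic_section` from [generate_section()].
#' @param mode One of `"crop"`, `"darken"`, `"fuse"`.
#' @param crop_px Border width removed by `crop`.
#' @param channel,factor Channel name and multiplier for `darken`.
#' @param n_pairs Number of fused pairs for `fuse`.
#' @param seed Seed for the pair choice in `fuse`.
#' @return The corrupted `synthetic_section`.
#' @export
corrupt_section <- function(section, mode, crop_px = 40, channel = "slow_350",
                            factor = 0.1, n_pairs = 1, seed = 1) {
  s <- section
  if (mode == "crop") {
    h <- s$params$shape[1]; w <- s$params$shape[2]
    rows <- (crop_px + 1):(h - crop_px); cols <- (crop_px + 1):(w - crop_px)
    s$image$channels <- lapply(s$image$channels, function(m) m[rows, cols])
    s$image$dim <- c(length(rows), length(cols))
    s$truth$label_mask <- s$truth$label_mask[rows, cols]
    keep_area <- tabulate(s$truth$label_mask[s$truth$label_mask > 0],
                          nbins = nrow(s$truth$fibres))
    s$truth$fibres$area_px <- keep_area
    s$truth$fibres <- s$truth$fibres[keep_area > 0, ]
    s$params$shape <- c(length(rows), length(cols))
  } else if (mode == "darken") {
    if (!channel %in% names(s$image$channels)) abort("unknown channel")
    s$image$channels[[channel]] <- round(s$image$channels[[channel]] * factor)
  } else if (mode == "fuse") {
    lm <- s$truth$label_mask
    h <- nrow(lm); w <- ncol(lm)
    col_pl <- s$image$channels$collagen_647
    # boundary pixels adjacent (in a 5x5 reach) to both members of a pair
    bnd <- which(lm == 0 & col_pl > s$params$boundary_intensity / 2)
    adj <- adjacent_label_pairs(lm)
    if (!nrow(adj)) abort("no adjacent pairs to fuse")
    withr::with_seed(seed, pick <- adj[sample.int(nrow(adj), min(n_pairs, nrow(adj))), ,
                                       drop = FALSE])
    br <- (bnd - 1) %% h + 1; bc <- (bnd - 1) %/% h + 1
    reach <- s$params$boundary_width_px + 2
    for (q in seq_len(nrow(pick))) {
      a <- pick[q, 1]; b <- pick[q, 2]
      near <- vapply(seq_along(bnd), function(i) {
        r0 <- max(1, br[i] - reach); r1 <- min(h, br[i] + reach)
        c0 <- max(1, bc[i] - reach); c1 <- min(w, bc[i] + reach)
        blk <- lm[r0:r1, c0:c1]
        any(blk == a) && any(blk == b)
      }, logical(1))
      col_pl[bnd[near]] <- 0
    }
    s$image$channels$collagen_647 <- col_pl
  } else {
    abort(paste0("unknown corruption mode: ", mode))
  }
  s
}

# unordered pairs of labels adjacent across a boundary of the stated width
adjacent_label_pairs <- function(lm) {
  h <- nrow(lm); w <- ncol(lm)
  gap <- 8
  pairs <- rbind(
    cbind(as.vector(lm[1:(h - gap), ]), as.vector(lm[(gap + 1):h, ])),
    cbind(as.vector(lm[, 1:(w - gap)]), as.vector(lm[, (gap + 1):w]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (!nrow(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- t(apply(pairs, 1, sort))
  unique(pairs)
}
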