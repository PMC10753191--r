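test_that("bleed-through subtraction is integer channel arithmetic", {
  mk <- function(col, fast) {
    multichannel_image(list(slow_350 = matrix(0, 4, 4), regen_488 = matrix(0, 4, 4),
                            fast_594 = matrix(fast, 4, 4),
                            collagen_647 = matrix(col, 4, 4)))
  }
  expect_true(all(bleedthrough_correct(mk(100, 30)) == 70))
  expect_true(all(bleedthrough_correct(mk(100, 0)) == 100))
  expect_true(all(bleedthrough_correct(mk(30, 100)) == 0))  # clipped at 0
  # simulated image: corrected plane inside fibres is at background level
  s <- generate_section(section_params(shape = c(256, 256), n_fibres = 14,
                                       bleedthrough_beta = 0.3), seed = 3)
  corr <- bleedthrough_correct(s$image)
  expect_lt(mean(corr[s$truth$label_mask > 0]), 3)
})

test_that("mask construction separates fibres and handles degenerate planes", {
  # two blocks separated by a 3 px boundary wall
  plane <- matrix(0L, 40, 40)
  plane[, 19:21] <- 200L
  labs <- fibre_mask(plane, min_level = 1)
  expect_equal(length(setdiff(unique(as.vector(labs)), 0)), 2)
  expect_error(fibre_mask(matrix(255L, 10, 10)), "all-boundary")
  expect_error(fibre_mask(matrix(0L, 10, 10)), "all-interior")
  # fused pair: watershed splits a waisted blob near the waist
  s <- generate_section(section_params(shape = c(300, 300), n_fibres = 20,
                                       intensity_sd = 0, background_noise_sd = 0),
                        seed = 9)
  fused <- corrupt_section(s, "fuse", n_pairs = 1, seed = 4)
  labs2 <- fibre_mask(bleedthrough_correct(fused$image), 1, 2)
  pf <- particle_filter(labs2)
  cal <- classify_fibres(measure_rois(fused$image, labs2, pf),
                         auto_thresholds(measure_rois(fused$image, labs2, pf),
                                         manual = c(slow = 100, fast = 100, regen = 100)))
  ev <- evaluate_detection(labs2, cal, fused$truth)
  expect_gte(ev$detection_fraction, 0.9)
})

test_that("particle filter reproduces the reference geometry rules", {
  # digital disc radius 20: area ~ 1257, circularity ~ 1 -> kept
  img <- matrix(0L, 64, 64)
  for (i in 1:64) for (j in 1:64) {
    if ((i - 32)^2 + (j - 32)^2 <= 20^2) img[i, j] <- 1L
  }
  pf <- particle_filter(img)
  expect_equal(nrow(pf), 1)
  expect_equal(pf$area_px, sum(img), tolerance = 0)
  expect_gt(pf$circularity, 0.9)
  expect_lte(pf$circularity, 1)
  # 10 x 20 rectangle: area 200 < 300 -> removed; chain perimeter 2h+2w-4
  rect <- matrix(0L, 40, 40); rect[11:20, 11:30] <- 1L
  pf2 <- particle_filter(rect)
  expect_equal(nrow(pf2), 0)
  all2 <- attr(pf2, "all_rois")
  expect_equal(all2$area_px, 200)
  expect_equal(all2$perimeter_px, 2 * 10 + 2 * 20 - 4)
  # 4 x 300 strip: circularity ~ 0.041 << 0.40 -> removed
  strip <- matrix(0L, 20, 320); strip[9:12, 11:310] <- 1L
  all3 <- attr(particle_filter(strip), "all_rois")
  expect_equal(all3$area_px, 1200)
  expect_equal(all3$perimeter_px, 2 * 4 + 2 * 300 - 4)
  expect_equal(all3$circularity, 4 * pi * 1200 / 604^2, tolerance = 1e-9)
  expect_equal(nrow(particle_filter(strip)), 0)
  # edge-touching blob is excluded
  edge <- matrix(0L, 50, 50); edge[1:30, 10:40] <- 1L
  expect_equal(nrow(particle_filter(edge)), 0)
  expect_true(attr(particle_filter(edge), "all_rois")$touches_edge)
})

test_that("particle filter agrees with the brute-force oracle on random sections", {
  for (s in 1:6) {
    p <- section_params(shape = c(256, 256), n_fibres = sample(10:16, 1))
    sec <- generate_section(p, seed = s)
    labs <- fibre_mask(bleedthrough_correct(sec$image))
    pf <- particle_filter(labs)
    oracle <- oracle_particle_check(labs)
    expect_setequal(pf$roi_id, oracle$roi_id[oracle$keep])
    all_rois <- attr(pf, "all_rois")
    m <- merge(as.data.frame(all_rois), as.data.frame(oracle), by = "roi_id")
    expect_equal(m$area_px.x, m$area_px.y)
    expect_equal(m$perimeter_px.x, m$perimeter_px.y, tolerance = 1e-9)
    expect_identical(m$touches_edge.x, m$touches_edge.y)
  }
})

test_that("ROI means are exact on constructed intensities and CLT-tight on noise", {
  labs <- matrix(0L, 30, 30)
  labs[5:14, 5:14] <- 1L   # uniform 180
  labs[20:29 - 2, 20:29 - 2] <- 2L  # half 100 / half 200
  ch <- matrix(0, 30, 30)
  ch[labs == 1L] <- 180
  half <- which(labs == 2L)
  ch[half[seq_along(half) <= length(half) / 2]] <- 100
  ch[half[seq_along(half) > length(half) / 2]] <- 200
  img <- multichannel_image(list(slow_350 = ch, regen_488 = ch * 0,
                                 fast_594 = ch * 0, collagen_647 = ch * 0))
  rois <- tibble::tibble(roi_id = c(1L, 2L), area_px = c(100L, 100L),
                         perimeter_px = c(36, 36), circularity = c(1, 1),
                         touches_edge = c(FALSE, FALSE))
  m <- measure_rois(img, labs, rois)
  expect_equal(m$mean_slow, c(180, 150))
  # generator fibre with mu 180, sigma 12: ROI mean within 4 sd / sqrt(area)
  s <- generate_section(section_params(shape = c(256, 256), n_fibres = 12,
                                       composition = setNames(c(1, 0, 0, 0, 0, 0, 0),
                                                              fibre_categories())),
                        seed = 12)
  labs2 <- s$truth$label_mask
  rois2 <- particle_filter(labs2)
  m2 <- measure_rois(s$image, labs2, rois2)
  expect_true(all(abs(m2$mean_slow - 180) <= 4 * 12 / sqrt(m2$area_px)))
})

test_that("automatic thresholds find bimodal cutoffs and flag unimodal channels", {
  withr::with_seed(21, {
    meas <- tibble::tibble(
      roi_id = 1:60,
      mean_slow = c(rnorm(30, 20, 12), rnorm(30, 180, 12)),
      mean_fast = rnorm(60, 20, 12),            # unimodal: no positives
      mean_regen = c(rnorm(50, 20, 12), rnorm(10, 180, 12))
    )
  })
  th <- auto_thresholds(meas)
  slow_ct <- th$cutoff[th$channel == "slow"]
  expect_gt(slow_ct, 60); expect_lt(slow_ct, 140)
  expect_false(th$low_confidence[th$channel == "slow"])
  expect_true(th$low_confidence[th$channel == "fast"])
  # exhaustive-scan oracle: the chosen cutoff attains the maximal
  # between-class variance (the maximiser is a plateau across the empty gap,
  # so values are compared, not locations)
  bcv_at <- function(ct) {
    lo <- meas$mean_slow < ct
    if (!any(lo) || all(lo)) return(0)
    mean(lo) * (1 - mean(lo)) * (mean(meas$mean_slow[lo]) - mean(meas$mean_slow[!lo]))^2
  }
  grid <- seq(min(meas$mean_slow) + 0.5, max(meas$mean_slow) - 0.5, by = 0.25)
  expect_equal(bcv_at(slow_ct), max(vapply(grid, bcv_at, numeric(1))),
               tolerance = 1e-6)
  # too few ROIs directs to manual thresholds
  expect_error(auto_thresholds(meas[1:10, ]), "manual")
  # manual override skips the fit
  thm <- auto_thresholds(meas[1:10, ], manual = c(slow = 90, fast = 110, regen = 100))
  expect_identical(thm$source, rep("manual", 3))
  expect_equal(thm$cutoff, c(90, 110, 100))
})

test_that("flag triplets map to the seven categories and grouped classes", {
  th <- tibble::tibble(channel = c("slow", "fast", "regen"), cutoff = 100,
                       low_confidence = FALSE, source = "manual")
  cases <- tibble::tibble(
    roi_id = 1:8,
    mean_slow = c(180, 20, 180, 20, 20, 180, 180, 20),
    mean_fast = c(20, 180, 180, 20, 180, 20, 180, 20),
    mean_regen = c(20, 20, 20, 180, 180, 180, 180, 20)
  )
  out <- classify_fibres(cases, th)
  expect_equal(out$category,
               c("slow", "fast", "fast_slow", "regen", "fast_regen",
                 "slow_regen", "fast_slow_regen", "unclassified"))
  expect_equal(out$reporting_class,
               c("type_I", "type_II", "hybrid_I_II", "regenerating",
                 "regenerating", "regenerating", "regenerating", "unclassified"))
  # classification order-invariance
  perm <- sample(nrow(cases))
  expect_equal(classify_fibres(cases[perm, ], th)$category, out$category[perm])
})

test_that("composition percentages sum to 100 and subject means are unweighted", {
  calls <- tibble::tibble(
    subject_id = rep("D1", 140),
    image_id = rep(c("i1", "i2"), c(100, 40)),
    reporting_class = c(rep("type_I", 20), rep("type_II", 80),  # image 1: 20%
                        rep("type_I", 12), rep("type_II", 28))  # image 2: 30%
  )
  comp <- fibre_composition(calls)
  sums <- comp |> dplyr::group_by(image_id) |> dplyr::summarise(s = sum(pct))
  expect_equal(sums$s, rep(100, 2), tolerance = 1e-9)
  expect_equal(comp$pct[comp$image_id == "i1" & comp$reporting_class == "type_I"], 20)
  sc <- subject_composition(comp)
  expect_equal(sc$mean_pct[sc$reporting_class == "type_I"], 25)  # (20 + 30) / 2
  expect_error(fibre_composition(calls["reporting_class"]), "image_id")
})

test_that("detection scoring is exact for perfect and cropped segmentations", {
  s <- generate_section(section_params(shape = c(300, 300), n_fibres = 20), seed = 2)
  labs <- s$truth$label_mask  # perfect segmentation: truth itself
  rois <- particle_filter(labs)
  calls <- classify_fibres(measure_rois(s$image, labs, rois),
                           auto_thresholds(measure_rois(s$image, labs, rois),
                                           manual = c(slow = 100, fast = 100,
                                                      regen = 100)))
  ev <- evaluate_detection(labs, calls, s$truth)
  expect_equal(ev$detection_fraction, 1)
  expect_lt(ev$composition_error_pct, 1e-9)
  # cropping hides border fibres: the edge filter drops exactly those
  cs <- corrupt_section(s, "crop", crop_px = 55)
  ft <- fibretype_image(cs$image,
                        thresholds = auto_thresholds(NULL, manual = c(slow = 100,
                                                                      fast = 100,
                                                                      regen = 100)))
  ev2 <- evaluate_detection(ft$labels, ft$calls, cs$truth)
  expect_lt(ev2$detection_fraction, 1)
  n_edge <- sum(cs$truth$label_mask[c(1, nrow(cs$truth$label_mask)), ] > 0) +
    sum(cs$truth$label_mask[, c(1, ncol(cs$truth$label_mask))] > 0)
  expect_gt(n_edge, 0)
})

test_that("end-to-end pipeline recovers section composition on default images", {
  s <- generate_section(section_params(shape = c(512, 512), n_fibres = 60,
                                       composition = composition_cranial_tibial("DE50-MD")),
                        seed = 31)
  ft <- fibretype_image(s$image)
  ev <- evaluate_detection(ft$labels, ft$calls, s$truth)
  expect_gte(ev$detection_fraction, 0.9)
  expect_lte(ev$composition_error_pct, 2)
})
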