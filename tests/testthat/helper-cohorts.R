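# drivers shared by the acceptance-level tests

run_ecd_cohort <- function(n_subjects, mean_pct, sd_pct, genotype, seed) {
  co <- simulate_cohort(cohort_spec(n_subjects, mean_pct, sd_pct,
                                    genotype = genotype), seed = seed)
  rec <- vapply(co$protocol, function(trs) glance(ecd_series(trs))$final_decrement_pct,
                numeric(1))
  list(recovered = rec, truth = co$true_decrement_pct)
}

# generate a genotype arm of the synthetic image cohort and push every image
# through the full segmentation/classification pipeline
run_image_cohort <- function(genotype, n_subjects, n_images = 5,
                             shape = c(1024, 1024), n_fibres = 220, seed = 1) {
  comp <- composition_cranial_tibial(genotype)
  p <- section_params(shape = shape, n_fibres = n_fibres, composition = comp)
  res <- purrr::map_dfr(seq_len(n_subjects), function(si) {
    purrr::map_dfr(seq_len(n_images), function(ii) {
      sec <- generate_section(p, seed = seed + 97L * si + ii)
      ft <- fibretype_image(sec$image)
      calls <- dplyr::mutate(ft$calls,
                             subject_id = sprintf("%s-%02d", genotype, si),
                             image_id = sprintf("%s-%02d-i%d", genotype, si, ii))
      truth <- dplyr::mutate(sec$truth$fibres,
                             subject_id = sprintf("%s-%02d", genotype, si),
                             image_id = sprintf("%s-%02d-i%d", genotype, si, ii))
      dplyr::bind_rows(dplyr::mutate(calls[c("subject_id", "image_id", "reporting_class")],
                                     source = "detected"),
                       dplyr::mutate(truth[c("subject_id", "image_id", "reporting_class")],
                                     source = "truth"))
    })
  })
  res
}

# genotype-level mean of per-subject means (each subject averaging its images)
cohort_class_means <- function(calls_long, src) {
  sc <- subject_composition(fibre_composition(calls_long[calls_long$source == src, ]))
  out <- tapply(sc$mean_pct, sc$reporting_class, mean)
  tibble::tibble(reporting_class = names(out), mean_pct = as.numeric(out))
}
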