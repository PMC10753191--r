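# musclephys

Analysis toolkit for in vivo canine muscle physiology, built around the
endpoints used to characterise the DE50-MD dog model of Duchenne muscular
dystrophy against wild-type littermates:

- **Torque-trace kinetics** — nerve-stimulated tibiotarsal joint twitch and
  tetanus recordings: baseline correction, peak and end-of-stimulation
  torque, absolute force (torque / lever arm, N) and relative force
  (N/kg bodyweight), decile contraction and relaxation time courses with the
  95% proxies, twitch:tetanus ratio, and rule-based trace QC.
- **Eccentric-contraction decrement (ECD)** — the study's headline
  biomarker. Thirty eccentric contractions (three sets of ten; 4 s gaps,
  4 min between sets; 0.5 s isometric phase before a 29°/0.2 s pedal
  rotation). Each plateau torque `T_k` is normalised by the protocol
  maximum, `N_k = 100·T_k / max_j T_j`, and the final decrement is
  `100 − N_30` — the percentage of maximal tetanic torque lost across the
  protocol.
- **Fibre typing** — a deterministic re-implementation of the semi-automated
  ImageJ workflow for 4-channel MHC immunofluorescence: bleed-through
  subtraction (647 − 594), mask + distance-transform watershed, the
  300 px / circularity 0.40–1.00 / edge-exclusion particle filter, ROI mean
  fluorescence, 7-way classification and grouped (type I / type II /
  hybrid / regenerating) composition summaries.
- **qPCR** — reference-normalised log relative quantities and within-sample
  MHC isoform proportions `p_i = 2^{−Cq_i} / Σ_j 2^{−Cq_j}`, with and
  without the regenerative isoforms.
- **Statistics & power** — Welch t-tests with Holm–Šídák step-down
  adjustment, and repeated-measures sample-size calculations (noncentral F,
  compound symmetry) for detecting fractional treatment rescues of each
  biomarker.
- **Synthetic generators** — parametric twitch/tetanus/ECD trace simulators
  and a ground-truth-labelled synthetic muscle-section generator (Poisson-disc
  tessellation, per-type channel intensities, bleed-through, corruption
  modes), so every pipeline stage is validated by parameter recovery.

## Worked example

Simulate one affected-genotype ECD protocol (plateau 5 N m, true final
decrement 76%) and recover the statistic:

```r
library(musclephys)

params <- ecd_protocol_params(
  tetanus = tetanus_params(plateau_Nm = 5, stim_duration_s = 0.8,
                           post_window_s = 0.5, noise_sd_Nm = 0.05),
  r_inf = 0.24, kappa = 5)          # r_inf = 1 - 76/100
protocol <- simulate_ecd_protocol(params, seed = 1)
glance(ecd_series(protocol$traces))
#>   n_detected max_torque_Nm max_abs_force_N final_remaining_pct final_decrement_pct
#> 1         30          4.97            49.7                24.2                75.8
```

All 30 contractions are detected; the maximum plateau torque is 4.97 N m
(49.7 N absolute force over a 0.1 m lever arm); 24.2% of maximal torque
remains after 30 contractions, i.e. a 75.8% decrement — recovering the 76%
ground truth from noisy traces.

Fibre-type a synthetic section generated at the affected cranial-tibial
composition (type I 20%, type II 69%, hybrid 4%, regenerating 7%):

```r
section <- generate_section(
  section_params(shape = c(512, 512), n_fibres = 60,
                 composition = composition_cranial_tibial("DE50-MD")),
  seed = 31)
ft <- fibretype_image(section$image)
evaluate_detection(ft$labels, ft$calls, section$truth)
#>   n_true n_detected n_matched detection_fraction composition_error_pct
#> 1     60         60        60                  1                     0
table(ft$calls$reporting_class)
#>  hybrid_I_II regenerating       type_I      type_II
#>            2            4           12           42
```

Every fibre is detected and the recovered class counts match the section's
ground truth exactly.

How many animals per genotype would detect a treatment recovering half the
genotype gap in the decrement endpoint (affected 76 ± 14%, wild type
17 ± 11%, six 3-monthly visits, within-subject correlation 0.7)?

```r
sample_size(power_spec(mu_affected = 76, mu_wildtype = 17,
                       sd_affected = 14, sd_wildtype = 11,
                       improvement_fraction = 0.5))
#>   n_per_group achieved_power delta sd_between
#> 1           4          0.887 -29.5       10.9
```

Four animals per group reach 89% power for a 50% rescue — the decrement is
a high-power biomarker.

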