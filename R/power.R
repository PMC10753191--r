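#' Welch two-sample t-test
#'
#' Two-tailed unpaired t-test with the Welch degrees-of-freedom correction,
#' the group-comparison workhorse for the fibre-type and expression panels.
#' Degenerate input (zero variance in both groups, equal means) returns
#' `p = 1` by convention.
#'
#' @param a,b Numeric vectors (each n >= 2).
#' @return One-row tibble `t`, `df`, `p_value`, `mean_a`, `mean_b`, `n_a`,
#'   `n_b`.
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                            mean_a = mean(a), mean_b = mean(b),
                            n_a = length(a), n_b = length(b)))
    }
    abort("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b))
}

#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the p-values ascending and applies the Sidak exponent at each rank:
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforcing monotone
#' non-decreasing adjusted values by running maximum, returned in the input
#' order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @examples
#' holm_sidak(c(0.01, 0.04, 0.03))
#' @export
holm_sidak <- function(pvals) {
  stopifnot(all(is.finite(pvals)), all(pvals >= 0), all(pvals <= 1))
  m <- length(pvals)
  o <- order(pvals)
  adj <- 1 - (1 - pvals[o])^(m - seq_len(m) + 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

#' Power specification for a two-group repeated-measures design
#'
#' Describes the sample-size question asked of each candidate biomarker: how
#' many animals per genotype are needed to detect, at `target_power`, a
#' treatment that recovers a fraction `improvement_fraction` of the gap
#' between the affected and wild-type endpoint means. The treated group mean
#' is `mu_affected + f * (mu_wildtype - mu_affected)` and is compared against
#' the untreated affected group across `n_timepoints` equally correlated
#' repeated measures (compound symmetry, correlation `rho`), with pooled sd
#' `sqrt((sd_affected^2 + sd_wildtype^2) / 2)`.
#'
#' @param mu_affected,mu_wildtype Group endpoint means (endpoint units).
#' @param sd_affected,sd_wildtype Group endpoint sds.
#' @param improvement_fraction Fraction of the gap recovered, in (0, 1].
#' @param n_timepoints Repeated measurements per subject (default 6, the
#'   3-monthly visits from 3 to 18 months).
#' @param rho Within-subject correlation (default 0.7).
#' @param alpha Two-sided type-I error (default 0.05).
#' @param target_power Desired power (default 0.8).
#' @return Spec list of class `power_spec`.
#' @export
power_spec <- function(mu_affected, mu_wildtype, sd_affected, sd_wildtype,
                       improvement_fraction = 0.25, n_timepoints = 6,
                       rho = 0.7, alpha = 0.05, target_power = 0.8) {
  stopifnot(sd_affected >= 0, sd_wildtype >= 0,
            improvement_fraction > 0, improvement_fraction <= 1,
            rho >= 0, rho < 1, n_timepoints >= 1)
  structure(list(mu_affected = mu_affected, mu_wildtype = mu_wildtype,
                 sd_affected = sd_affected, sd_wildtype = sd_wildtype,
                 improvement_fraction = improvement_fraction,
                 n_timepoints = n_timepoints, rho = rho, alpha = alpha,
                 target_power = target_power),
            class = "power_spec")
}

power_effect <- function(spec) {
  delta <- spec$improvement_fraction * (spec$mu_wildtype - spec$mu_affected)
  sd_pooled <- sqrt((spec$sd_affected^2 + spec$sd_wildtype^2) / 2)
  # variance of a subject's time-averaged response under compound symmetry
  sd_between <- sd_pooled * sqrt((1 + (spec$n_timepoints - 1) * spec$rho) /
                                   spec$n_timepoints)
  list(delta = delta, sd_between = sd_between)
}

#' Power of the group main effect at a given per-group n
#'
#' Noncentral-F power for the between-group main effect of a 2-group x
#' T-timepoint repeated-measures design with compound symmetry: the group
#' effect is carried by the subject time-averages, whose variance is
#' `sd^2 (1 + (T-1) rho) / T`, giving `F(1, 2n - 2)` with noncentrality
#' `n delta^2 / (2 sigma_b^2)`.
#'
#' @param spec A [power_spec()].
#' @param n Per-group sample size, >= 2.
#' @return Power in `[0, 1]`.
#' @export
power_at_n <- function(spec, n) {
  stopifnot(n >= 2)
  eff <- power_effect(spec)
  if (eff$delta == 0) return(spec$alpha)
  ncp <- n * eff$delta^2 / (2 * eff$sd_between^2)
  df2 <- 2 * n - 2
  crit <- qf(1 - spec$alpha, 1, df2)
  1 - pf(crit, 1, df2, ncp = ncp)
}

#' Smallest per-group sample size achieving the target power
#'
#' Least integer `n >= 2` with `power_at_n(spec, n) >= target_power`
#' (minimality: the power at `n - 1` is below target, unless `n = 2`).
#'
#' @param spec A [power_spec()].
#' @param n_max Search ceiling (error if exceeded).
#' @return One-row tibble `n_per_group`, `achieved_power`, plus the effect
#'   size bookkeeping (`delta`, `sd_between`).
#' @export
sample_size <- function(spec, n_max = 10000) {
  eff <- power_effect(spec)
  if (eff$delta == 0) {
    abort("undetectable: affected and wild-type means are equal")
  }
  for (n in 2:n_max) {
    pw <- power_at_n(spec, n)
    if (pw >= spec$target_power) {
      return(tibble::tibble(n_per_group = n, achieved_power = pw,
                            delta = eff$delta, sd_between = eff$sd_between))
    }
  }
  abort("target power not reached within n_max")
}

#' Sample sizes for a table of biomarker candidates
#'
#' Vectorised driver mirroring a biomarker power table: one row per
#' candidate endpoint, expanded over the improvement fractions.
#'
#' @param candidates Tibble with columns `endpoint`, `mu_affected`,
#'   `mu_wildtype`, `sd_affected`, `sd_wildtype`.
#' @param improvement_fractions Fractions of the genotype gap to detect.
#' @param ... Passed to [power_spec()] (rho, n_timepoints, alpha,
#'   target_power).
#' @return Long tibble with `endpoint`, `improvement_fraction`,
#'   `n_per_group`, `achieved_power`.
#' @export
sample_size_table <- function(candidates,
                              improvement_fractions = c(1, 0.75, 0.5, 0.25),
                              ...) {
  tidyr::crossing(candidates, improvement_fraction = improvement_fractions) |>
    dplyr::rowwise() |>
    dplyr::mutate(res = list(sample_size(power_spec(
      mu_affected = .data$mu_affected, mu_wildtype = .data$mu_wildtype,
      sd_affected = .data$sd_affected, sd_wildtype = .data$sd_wildtype,
      improvement_fraction = .data$improvement_fraction, ...)))) |>
    dplyr::ungroup() |>
    tidyr::unnest("res") |>
    dplyr::select(-"delta", -"sd_between")
}
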