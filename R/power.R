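# Hypothesis-testing layer: the interaction statistic on observed counts,
# and analytic power for the interaction test and the regular single-site
# association test.

count_cols <- function() {
  c("n11_case", "n10_case", "n01_case", "n00_case",
    "n11_control", "n10_control", "n01_control", "n00_control")
}

plugin_beta_var <- function(counts) {
  # counts: data frame with the eight count columns, any number of rows
  nD <- counts$n11_case + counts$n10_case + counts$n01_case + counts$n00_case
  nd <- counts$n11_control + counts$n10_control + counts$n01_control +
    counts$n00_control
  pD <- cbind(counts$n11_case, counts$n10_case, counts$n01_case,
              counts$n00_case) / nD
  pd <- cbind(counts$n11_control, counts$n10_control, counts$n01_control,
              counts$n00_control) / nd
  det4 <- function(m) m[, 1] * m[, 4] - m[, 2] * m[, 3]
  brk <- function(m) {
    d <- det4(m)
    r1 <- m[, 1] + m[, 2]   # marginal of marker 1
    c1 <- m[, 1] + m[, 3]   # marginal of marker 2
    r1 * (1 - r1) * c1 * (1 - c1) + (1 - 2 * r1) * (1 - 2 * c1) * d - d^2
  }
  list(beta = det4(pD) - det4(pd),
       variance = brk(pD) / nD + brk(pd) / nd,
       n_case = nD, n_control = nd)
}

#' Chi-square test for marker-pair LD difference between cases and controls
#'
#' Given observed chromosome counts cross-classified by the alleles at the
#' two markers, computes the plug-in effect size
#' `beta_hat = beta_hat_case - beta_hat_control`, its plug-in variance, the
#' statistic `S = beta_hat^2 / Var(beta_hat)`, and a two-sided p-value from
#' the central chi-square distribution with 1 degree of freedom.
#'
#' @param counts A data frame with integer columns `n11_case`, `n10_case`,
#'   `n01_case`, `n00_case`, `n11_control`, `n10_control`, `n01_control`,
#'   `n00_control` (one row per table), e.g. from [sample_marker_tables()].
#' @param on_degenerate What to do when a table's plug-in variance is zero
#'   (a fixed marker in a stratum): `"error"` (default) or `"na"` to return
#'   `NA` for that row with `degenerate = TRUE`.
#' @return The input tibble with `beta_hat`, `variance_hat`, `statistic`,
#'   `p_value` and `degenerate` appended.
#' @examples
#' tab <- tibble::tibble(
#'   n11_case = 20, n10_case = 80, n01_case = 80, n00_case = 820,
#'   n11_control = 10, n10_control = 90, n01_control = 90, n00_control = 810
#' )
#' interaction_test(tab)
#' @export
interaction_test <- function(counts, on_degenerate = c("error", "na")) {
  on_degenerate <- rlang::arg_match(on_degenerate)
  missing <- setdiff(count_cols(), names(counts))
  if (length(missing) > 0) {
    abort(paste0("counts is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "epipower_error_invalid_parameter")
  }
  cc <- as.matrix(counts[count_cols()])
  if (any(cc < 0) || any(cc != round(cc))) {
    abort("counts must be nonnegative integers",
          class = "epipower_error_invalid_parameter")
  }
  pl <- plugin_beta_var(counts)
  if (any(pl$n_case == 0) || any(pl$n_control == 0)) {
    abort("both groups must be non-empty",
          class = "epipower_error_degenerate")
  }
  degen <- !is.finite(pl$variance) | pl$variance <= 0
  if (any(degen) && on_degenerate == "error") {
    abort(paste0("degenerate table: plug-in variance is zero in row ",
                 which(degen)[1]),
          class = "epipower_error_degenerate")
  }
  stat <- ifelse(degen, NA_real_, pl$beta^2 / pl$variance)
  out <- as_tibble(counts)
  out$beta_hat <- ifelse(degen, NA_real_, pl$beta)
  out$variance_hat <- ifelse(degen, NA_real_, pl$variance)
  out$statistic <- stat
  out$p_value <- pchisq(stat, df = 1, lower.tail = FALSE)
  out$degenerate <- degen
  out
}

power_from_ncp <- function(ncp, alpha) {
  crit <- qchisq(1 - alpha, df = 1)
  tibble(noncentrality = ncp, critical_value = crit,
         power = pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE),
         alpha = alpha)
}

#' Analytic power of the marker-pair interaction test
#'
#' Power of the 1-df chi-square test of the LD-difference effect size,
#' computed from the noncentral chi-square distribution with
#' noncentrality `E(beta_hat)^2 / Var(beta_hat)` and the upper-`alpha`
#' critical value of the central chi-square with 1 df. The denominator is
#' the variance under the alternative, matching the plug-in statistic.
#'
#' @inheritParams effect_size
#' @return The scenario tibble with `test = "interaction"`,
#'   `noncentrality`, `critical_value`, `power` and `alpha` appended
#'   (plus the [effect_size()] columns).
#' @examples
#' interaction_power(scenario(k = 2, r_x1 = 1.8, r_x2 = 1.8),
#'                   convention = "published")
#' @export
interaction_power <- function(data, convention = "consistent",
                              controls = c("mixture", "interaction"),
                              projection = c("conditional", "verbatim")) {
  es <- effect_size(data, convention = convention, controls = controls,
                    projection = projection, large_n = TRUE)
  pw <- power_from_ncp(es$expectation^2 / es$variance, es$alpha)
  pw$alpha <- NULL
  dplyr::bind_cols(es, tibble(test = "interaction"), pw)
}

#' Analytic power of the regular single-site association test
#'
#' Power of the two-sample allele-frequency chi-square test at marker M1:
#' the effect is the case-control difference of the M1 allele frequency
#' (marker marginals under the proper conditional projection), the
#' noncentrality is `effect^2 / (p1D (1 - p1D) / n_case +
#' p1d (1 - p1d) / n_control)`, and power comes from the noncentral
#' chi-square with 1 df as for the interaction test.
#'
#' The marginal allele frequencies are identical under both control
#' conventions, so this test has no `convention` argument.
#'
#' @inheritParams effect_size
#' @return The scenario tibble with `test = "single_site"`, `p1_case`,
#'   `p1_control`, `noncentrality`, `critical_value` and `power` appended.
#' @examples
#' single_site_power(scenario(f_x1 = 0.2, f_x2 = 0.2, p_m1 = 0.2,
#'                            p_m2 = 0.2, d1_prime = 0.5))
#' @export
single_site_power <- function(data) {
  validate_scenarios(data)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    p <- as.list(data[i, ])
    d1 <- dprime_to_d(p$d1_prime, p$p_m1, p$f_x1)
    cond <- marker_conditionals(p$p_m1, p$f_x1, d1)
    f1D <- case_marginal(p$f_x1, p$r_x1)
    f1d <- (p$f_x1 - p$prevalence * f1D) / (1 - p$prevalence)
    p1D <- cond[["x1"]] * f1D + cond[["x0"]] * (1 - f1D)
    p1d <- cond[["x1"]] * f1d + cond[["x0"]] * (1 - f1d)
    ncp <- (p1D - p1d)^2 /
      (p1D * (1 - p1D) / p$n_case + p1d * (1 - p1d) / p$n_control)
    dplyr::bind_cols(tibble(p1_case = p1D, p1_control = p1d),
                     power_from_ncp(ncp, p$alpha)["noncentrality"],
                     power_from_ncp(ncp, p$alpha)[c("critical_value",
                                                    "power")])
  })
  dplyr::bind_cols(data, tibble(test = "single_site"),
                   dplyr::bind_rows(rows))
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in (0, 1).
#' @param n_markers Number of hypotheses, at least 1.
#' @return `alpha / n_markers`; around `5e-8` for one million markers at
#'   `alpha = 0.05`.
#' @examples
#' bonferroni_threshold(0.05, 1e6)
#' @export
bonferroni_threshold <- function(alpha, n_markers) {
  if (any(!is.finite(n_markers) | n_markers < 1)) {
    abort("n_markers must be at least 1",
          class = "epipower_error_invalid_parameter")
  }
  if (any(!is.finite(alpha) | alpha <= 0 | alpha >= 1)) {
    abort("alpha must lie strictly in (0, 1)",
          class = "epipower_error_invalid_parameter")
  }
  alpha / n_markers
}

#' Number of two-locus interaction hypotheses among n markers
#'
#' The interaction scan tests every unordered marker pair, so the number
#' of hypotheses grows quadratically: `n (n - 1) / 2`.
#'
#' @param n_markers Number of markers, at least 2.
#' @return The number of marker pairs.
#' @examples
#' interaction_pair_count(1e6)
#' @export
interaction_pair_count <- function(n_markers) {
  if (any(!is.finite(n_markers) | n_markers < 2 |
            n_markers != round(n_markers))) {
    abort("n_markers must be an integer of at least 2",
          class = "epipower_error_invalid_parameter")
  }
  n_markers * (n_markers - 1) / 2
}
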