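# Effect size of the interaction signal: the difference between the
# marker-pair LD in cases and in controls.

ld_det <- function(v) v[["f11"]] * v[["f00"]] - v[["f10"]] * v[["f01"]]

# Large-sample variance of the plug-in LD determinant estimated from N
# multinomially sampled chromosomes (per-stratum bracket; divide by N).
var_bracket <- function(v) {
  p11 <- v[["f11"]]; p10 <- v[["f10"]]; p01 <- v[["f01"]]; p00 <- v[["f00"]]
  d <- p11 * p00 - p10 * p01
  (p11 + p10) * (1 - p11 - p10) * (p11 + p01) * (1 - p11 - p01) +
    (1 - 2 * p11 - 2 * p10) * (1 - 2 * p11 - 2 * p01) * d - d^2
}

resolve_convention <- function(convention, controls, projection) {
  if (!is.null(convention)) {
    convention <- rlang::arg_match0(convention, c("consistent", "published"))
    if (convention == "published") {
      list(controls = "interaction", projection = "verbatim")
    } else {
      list(controls = "mixture", projection = "conditional")
    }
  } else {
    list(controls = controls, projection = projection)
  }
}

# Marker cells for case and control strata of one scenario row.
marker_pair <- function(p, controls, projection) {
  list(
    case = project_marker(case_freqs_disease(p), p, projection),
    control = project_marker(
      control_freqs_disease(p, controls = controls), p, projection)
  )
}

#' Finite-sample covariance of the two estimated marker marginals
#'
#' Within one stratum of `n` multinomially sampled chromosomes, the
#' estimated allele frequencies at the two markers covary through the
#' joint cell: `Cov = (p11 - p1 * q1) / n`. This is the correction that
#' separates the finite-sample expectation of the LD estimator from its
#' large-sample limit.
#'
#' @param p11 Joint frequency of the "1/1" marker cell.
#' @param p1,q1 Marginal frequencies of the "1" allele at the two markers.
#' @param n Number of chromosomes in the stratum, at least 1.
#' @return `(p11 - p1 * q1) / n`.
#' @examples
#' covariance_marginals(0.0107079, 0.0731707, 0.0731707, 10000)
#' @export
covariance_marginals <- function(p11, p1, q1, n) {
  if (any(!is.finite(n) | n < 1)) {
    abort("n must be at least 1",
          class = "epipower_error_invalid_parameter")
  }
  if (any(p11 < 0 | p11 > 1 | p1 < 0 | p1 > 1 | q1 < 0 | q1 > 1)) {
    abort("proportions must lie in [0, 1]",
          class = "epipower_error_invalid_parameter")
  }
  (p11 - p1 * q1) / n
}

#' Expectation and variance of the interaction effect size
#'
#' For each scenario, computes the marker-pair LD in cases (`beta_case`)
#' and controls (`beta_control`), the expectation of the estimated effect
#' size `beta_hat = beta_hat_case - beta_hat_control`, and its sampling
#' variance `Var = Var_case + Var_control` under multinomial sampling of
#' `n_case` and `n_control` chromosomes.
#'
#' Each stratum's LD is the determinant `p11 p00 - p10 p01` of its marker
#' cells; for a normalized distribution this equals the covariance form
#' `p11 - p1 q1`. The large-sample expectation is the case-minus-control
#' determinant difference; with `large_n = FALSE` the finite-sample
#' covariance corrections ([covariance_marginals()]) are subtracted per
#' stratum. Per-stratum variances follow the classical large-sample
#' variance of the LD determinant estimator.
#'
#' @inheritParams haplotype_freqs
#' @param convention Shorthand that overrides `controls`/`projection` when
#'   non-`NULL`: `"consistent"` (mixture controls, conditional projection;
#'   the internally coherent model the simulator validates) or
#'   `"published"` (interaction controls, verbatim projection; reproduces
#'   the published closed-form tables). Default `"consistent"`.
#' @param large_n If `TRUE` (default), drop the finite-sample covariance
#'   corrections from the expectation.
#'
#' @return The scenario tibble with columns `beta_case`, `beta_control`,
#'   `cov_case`, `cov_control`, `expectation`, `variance_case`,
#'   `variance_control` and `variance` appended.
#'
#' @examples
#' effect_size(scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1))
#' effect_size(scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1),
#'             convention = "published")
#' @export
effect_size <- function(data, convention = "consistent",
                        controls = c("mixture", "interaction"),
                        projection = c("conditional", "verbatim"),
                        large_n = TRUE) {
  validate_scenarios(data)
  cv <- resolve_convention(convention, rlang::arg_match(controls),
                           rlang::arg_match(projection))
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    p <- as.list(data[i, ])
    mp <- marker_pair(p, cv$controls, cv$projection)
    bD <- ld_det(mp$case)
    bd <- ld_det(mp$control)
    covD <- (mp$case[["f11"]] -
               (mp$case[["f11"]] + mp$case[["f10"]]) *
               (mp$case[["f11"]] + mp$case[["f01"]])) / p$n_case
    covd <- (mp$control[["f11"]] -
               (mp$control[["f11"]] + mp$control[["f10"]]) *
               (mp$control[["f11"]] + mp$control[["f01"]])) / p$n_control
    vD <- var_bracket(mp$case) / p$n_case
    vd <- var_bracket(mp$control) / p$n_control
    if (cv$projection == "conditional" && (vD <= 0 || vd <= 0)) {
      abort("degenerate scenario: a marker cell distribution has zero variance",
            class = "epipower_error_degenerate")
    }
    tibble(
      beta_case = bD, beta_control = bd,
      cov_case = covD, cov_control = covd,
      expectation = if (large_n) bD - bd else (bD - covD) - (bd - covd),
      variance_case = vD, variance_control = vd,
      variance = vD + vd
    )
  })
  dplyr::bind_cols(data, dplyr::bind_rows(rows))
}
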