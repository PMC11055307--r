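#' Define a two-locus interaction scenario
#'
#' A scenario fixes every parameter of the haploid two-locus disease model:
#' population risk-allele frequencies at the two disease loci (`f_x1`,
#' `f_x2`) and at their linked markers (`p_m1`, `p_m2`), the per-allele
#' relative risks (`r_x1`, `r_x2`), the interaction coefficient `k`
#' (multiplicative excess of the double-risk haplotype among cases), the
#' disease prevalence `phi`, Lewontin's D' between each marker and its
#' disease locus (`d1_prime`, `d2_prime`), the numbers of case and control
#' chromosomes, and the significance level for testing.
#'
#' Validation is eager: a parameter set whose implied case haplotype
#' frequencies fall outside \[0, 1\] is rejected here with an error naming
#' the violated quantity, rather than propagating `NaN` downstream.
#' Control-stratum feasibility depends on the control convention and is
#' checked wherever control frequencies are derived (see
#' [haplotype_freqs()]): the exact `"mixture"` convention forbids stronger
#' case enrichment than the population can supply at the given prevalence,
#' while the published `"interaction"` convention tolerates it.
#'
#' @param f_x1,f_x2 Population frequencies of the risk alleles at disease
#'   loci X1 and X2, strictly in (0, 1).
#' @param p_m1,p_m2 Population frequencies of the tagging alleles at marker
#'   loci M1 and M2, strictly in (0, 1).
#' @param r_x1,r_x2 Relative risks of the X1 and X2 risk alleles (ratio of
#'   disease incidence in carriers to non-carriers), positive.
#' @param k Interaction coefficient: `f11D = (1 + k) * f1D * f2D` among
#'   case chromosomes. Must exceed -1 and keep `f11D` feasible.
#' @param prevalence Disease prevalence `phi`, strictly in (0, 1).
#' @param d1_prime,d2_prime Lewontin's D' between X1 and M1, and X2 and M2,
#'   in \[0, 1\] (only nonnegative association is modelled).
#' @param n_case,n_control Numbers of case and control chromosomes
#'   (haploid sampling units), at least 1.
#' @param alpha Significance level of the test, strictly in (0, 1).
#'
#' @return A one-row tibble with one column per parameter.
#'
#' @examples
#' scenario(k = 2, r_x1 = 1.8, r_x2 = 1.8)
#'
#' @seealso [scenario_grid()] for parameter sweeps, [effect_size()] and
#'   [interaction_power()] for the quantities computed from a scenario.
#' @export
scenario <- function(f_x1 = 0.05, f_x2 = 0.05,
                     p_m1 = 0.05, p_m2 = 0.05,
                     r_x1 = 2, r_x2 = 2,
                     k = 1, prevalence = 0.1,
                     d1_prime = 1, d2_prime = 1,
                     n_case = 10000, n_control = 10000,
                     alpha = 0.05) {
  out <- tibble(
    f_x1 = f_x1, f_x2 = f_x2, p_m1 = p_m1, p_m2 = p_m2,
    r_x1 = r_x1, r_x2 = r_x2, k = k, prevalence = prevalence,
    d1_prime = d1_prime, d2_prime = d2_prime,
    n_case = n_case, n_control = n_control, alpha = alpha
  )
  validate_scenarios(out)
  out
}

scenario_fields <- function() {
  c("f_x1", "f_x2", "p_m1", "p_m2", "r_x1", "r_x2", "k", "prevalence",
    "d1_prime", "d2_prime", "n_case", "n_control", "alpha")
}

# Checks ranges and model feasibility for every row; errors on first problem.
validate_scenarios <- function(data, call = rlang::caller_env()) {
  stopifnot(is.data.frame(data))
  missing <- setdiff(scenario_fields(), names(data))
  if (length(missing) > 0) {
    abort(paste0("scenario data is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "epipower_error_invalid_parameter", call = call)
  }
  chk <- function(ok, what) {
    if (!all(ok)) {
      abort(paste0("invalid parameter: ", what,
                   " (first bad row: ", which(!ok)[1], ")"),
            class = "epipower_error_invalid_parameter", call = call)
    }
  }
  inside <- function(x) is.finite(x) & x > 0 & x < 1
  chk(inside(data$f_x1), "f_x1 must lie strictly in (0, 1)")
  chk(inside(data$f_x2), "f_x2 must lie strictly in (0, 1)")
  chk(inside(data$p_m1), "p_m1 must lie strictly in (0, 1)")
  chk(inside(data$p_m2), "p_m2 must lie strictly in (0, 1)")
  chk(inside(data$prevalence), "prevalence must lie strictly in (0, 1)")
  chk(inside(data$alpha), "alpha must lie strictly in (0, 1)")
  chk(is.finite(data$r_x1) & data$r_x1 > 0, "r_x1 must be positive")
  chk(is.finite(data$r_x2) & data$r_x2 > 0, "r_x2 must be positive")
  chk(is.finite(data$k) & data$k > -1, "k must be greater than -1")
  chk(is.finite(data$d1_prime) & data$d1_prime >= 0 & data$d1_prime <= 1,
      "d1_prime must lie in [0, 1]")
  chk(is.finite(data$d2_prime) & data$d2_prime >= 0 & data$d2_prime <= 1,
      "d2_prime must lie in [0, 1]")
  chk(data$n_case >= 1 & data$n_case == round(data$n_case),
      "n_case must be a positive integer")
  chk(data$n_control >= 1 & data$n_control == round(data$n_control),
      "n_control must be a positive integer")

  # model feasibility, rowwise
  for (i in seq_len(nrow(data))) {
    p <- as.list(data[i, ])
    assert_feasible(p, row = i, call = call)
  }
  invisible(data)
}

# Feasibility of the case stratum (convention-independent). Control-stratum
# feasibility depends on the chosen control convention and is enforced at
# the point where control frequencies are computed: in particular the exact
# mixture convention is infeasible for strong interactions at rare alleles
# even where the published "interaction" convention is not.
assert_feasible <- function(p, row = 1L, call = rlang::caller_env()) {
  f1D <- case_marginal(p$f_x1, p$r_x1)
  f2D <- case_marginal(p$f_x2, p$r_x2)
  f11D <- (1 + p$k) * f1D * f2D
  bad <- function(what) {
    abort(paste0("infeasible scenario (row ", row, "): ", what),
          class = "epipower_error_infeasible", call = call)
  }
  if (f11D > min(f1D, f2D) + 1e-15) {
    bad(paste0("case double-risk haplotype frequency f11D = ",
               signif(f11D, 6), " exceeds min(f1D, f2D) = ",
               signif(min(f1D, f2D), 6),
               "; the (1 + k) inflation is too strong"))
  }
  if (1 - f1D - f2D + f11D < -1e-15) {
    bad("case haplotype frequency f00D is negative")
  }
  invisible(TRUE)
}
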