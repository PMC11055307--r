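# Core closed-form frequency algebra for the two-locus haploid model.
#
# Internally a two-locus haplotype distribution is a length-4 numeric
# vector in the order c(f11, f10, f01, f00), where the first index is the
# allele at locus 1 and the second the allele at locus 2.

#' Convert Lewontin's D' to the raw LD coefficient D
#'
#' For a pair of loci with allele frequencies `p_a` and `p_b` and a
#' nonnegative association between the two "1" alleles, the maximum
#' attainable LD is `Dmax = min(p_a * (1 - p_b), (1 - p_a) * p_b)` and
#' `D = d_prime * Dmax`. Negative association is not modelled: the tagging
#' allele of each marker is taken to tag the risk allele of its disease
#' locus.
#'
#' @param d_prime Lewontin's D', in \[0, 1\].
#' @param p_a,p_b Allele frequencies at the two loci, strictly in (0, 1).
#' @return The signed LD coefficient D (here always >= 0).
#' @examples
#' dprime_to_d(1, 0.05, 0.05)  # 0.0475
#' dprime_to_d(0.5, 0.2, 0.1)  # 0.04
#' @export
dprime_to_d <- function(d_prime, p_a, p_b) {
  if (any(!is.finite(d_prime) | d_prime < 0 | d_prime > 1)) {
    abort("d_prime must lie in [0, 1]",
          class = "epipower_error_invalid_parameter")
  }
  if (any(!is.finite(p_a) | p_a <= 0 | p_a >= 1) ||
      any(!is.finite(p_b) | p_b <= 0 | p_b >= 1)) {
    abort("allele frequencies must lie strictly in (0, 1)",
          class = "epipower_error_invalid_parameter")
  }
  d_prime * pmin(p_a * (1 - p_b), (1 - p_a) * p_b)
}

# Frequency of a risk allele among case chromosomes:
# f1D = R f / (R f + (1 - f)).
case_marginal <- function(f, r) r * f / (r * f + (1 - f))

hap4 <- function(f1, f2, f11) {
  c(f11 = f11, f10 = f1 - f11, f01 = f2 - f11, f00 = 1 - f1 - f2 + f11)
}

# Disease-locus haplotype frequencies among case chromosomes.
case_freqs_disease <- function(p) {
  f1D <- case_marginal(p$f_x1, p$r_x1)
  f2D <- case_marginal(p$f_x2, p$r_x2)
  hap4(f1D, f2D, (1 + p$k) * f1D * f2D)
}

# Disease-locus haplotype frequencies in the general population: the two
# disease loci are unlinked and independent.
population_freqs_disease <- function(p) {
  hap4(p$f_x1, p$f_x2, p$f_x1 * p$f_x2)
}

# Disease-locus haplotype frequencies among control chromosomes.
#
# Both conventions share the exact prevalence-mixture marginals
#   f1d = (f1 - phi * f1D) / (1 - phi),
# which is total probability over disease status. They differ in the
# control joint:
#   "mixture":     f11d = (f1*f2 - phi*f11D) / (1 - phi); the unique joint
#                  for which phi*case + (1-phi)*control reconstitutes the
#                  independent population cell-wise.
#   "interaction": f11d = (1 + k) * f1d * f2d; the interaction coefficient
#                  acts identically in controls (the convention behind the
#                  published figures; see the methods vignette).
control_freqs_disease <- function(p, controls = c("mixture", "interaction"),
                                  check = TRUE) {
  controls <- rlang::arg_match(controls)
  phi <- p$prevalence
  cs <- case_freqs_disease(p)
  if (controls == "mixture") {
    out <- (population_freqs_disease(p) - phi * cs) / (1 - phi)
  } else {
    f1d <- (p$f_x1 - phi * (cs[["f11"]] + cs[["f10"]])) / (1 - phi)
    f2d <- (p$f_x2 - phi * (cs[["f11"]] + cs[["f01"]])) / (1 - phi)
    out <- hap4(f1d, f2d, (1 + p$k) * f1d * f2d)
  }
  if (check && any(out < -1e-15 | out > 1 + 1e-15)) {
    lab <- names(out)[which.min(out)]
    abort(paste0("infeasible scenario: control haplotype frequency ", lab,
                 " = ", signif(min(out), 6), " falls outside [0, 1]",
                 " under the '", controls, "' control convention"),
          class = "epipower_error_infeasible")
  }
  out
}

# Conditional probabilities P(M = 1 | X = x) implied by (p, f, D) under the
# standard signed 2x2 decomposition: joint(M=1, X=1) = p f + D and
# joint(M=1, X=0) = p (1 - f) - D.
marker_conditionals <- function(p_m, f_x, d) {
  a1 <- (p_m * f_x + d) / f_x
  a0 <- (p_m * (1 - f_x) - d) / (1 - f_x)
  if (a1 < -1e-12 || a1 > 1 + 1e-12 || a0 < -1e-12 || a0 > 1 + 1e-12) {
    abort(paste0("invalid LD: conditional marker probability outside [0, 1]",
                 " (P(M|X=1) = ", signif(a1, 6),
                 ", P(M|X=0) = ", signif(a0, 6), ")"),
          class = "epipower_error_invalid_ld")
  }
  c(x1 = min(max(a1, 0), 1), x0 = min(max(a0, 0), 1))
}

# Project a disease-locus haplotype distribution onto the marker loci.
#
# "conditional" sums, over the four disease haplotypes, products of the
# proper conditional probabilities P(M1 | X1) P(M2 | X2); the result is a
# probability vector. "verbatim" instead evaluates the published four-term
# cell formulas literally, with "+D" in every numerator (including the
# M = 0 complements): the resulting cells are not a normalized
# distribution (they can sum to more than 1) and exist only to reproduce
# the published closed-form tables; they cannot parameterize a multinomial.
project_marker <- function(hd, p,
                           projection = c("conditional", "verbatim")) {
  projection <- rlang::arg_match(projection)
  d1 <- dprime_to_d(p$d1_prime, p$p_m1, p$f_x1)
  d2 <- dprime_to_d(p$d2_prime, p$p_m2, p$f_x2)
  if (projection == "conditional") {
    c1 <- marker_conditionals(p$p_m1, p$f_x1, d1)
    c2 <- marker_conditionals(p$p_m2, p$f_x2, d2)
    # weight of M = 1 given each disease haplotype, order f11 f10 f01 f00
    w1 <- c(c1[["x1"]], c1[["x1"]], c1[["x0"]], c1[["x0"]])
    w2 <- c(c2[["x1"]], c2[["x0"]], c2[["x1"]], c2[["x0"]])
    v1 <- 1 - w1
    v2 <- 1 - w2
  } else {
    # every numerator carries +D, exactly as displayed
    lit <- function(p_m, f_x, d) {
      list(m1 = c((p_m * f_x + d) / f_x, (p_m * f_x + d) / f_x,
                  (p_m * (1 - f_x) + d) / (1 - f_x),
                  (p_m * (1 - f_x) + d) / (1 - f_x)),
           m0 = c(((1 - p_m) * f_x + d) / f_x, ((1 - p_m) * f_x + d) / f_x,
                  ((1 - p_m) * (1 - f_x) + d) / (1 - f_x),
                  ((1 - p_m) * (1 - f_x) + d) / (1 - f_x)))
    }
    l1 <- lit(p$p_m1, p$f_x1, d1)
    l2raw <- lit(p$p_m2, p$f_x2, d2)
    # locus-2 weights follow the second index of the haplotype order
    reord <- c(1, 3, 2, 4)
    w1 <- l1$m1; v1 <- l1$m0
    w2 <- l2raw$m1[reord]; v2 <- l2raw$m0[reord]
  }
  c(f11 = sum(w1 * w2 * hd), f10 = sum(w1 * v2 * hd),
    f01 = sum(v1 * w2 * hd), f00 = sum(v1 * v2 * hd))
}

# Resolve the 4-cell frequency vector for one scenario row.
stratum_freqs <- function(p, stratum, loci = "disease",
                          controls = "mixture",
                          projection = "conditional") {
  hd <- switch(stratum,
    case = case_freqs_disease(p),
    control = control_freqs_disease(p, controls = controls),
    population = population_freqs_disease(p),
    abort(paste0("unknown stratum: ", stratum),
          class = "epipower_error_invalid_parameter")
  )
  if (identical(loci, "disease")) hd else project_marker(hd, p, projection)
}

#' Haplotype and marker-cell frequencies for each stratum
#'
#' Computes the two-locus frequency vector (`f11`, `f10`, `f01`, `f00`)
#' for the requested strata of each scenario, either at the disease loci
#' or projected onto the marker loci through the marker-disease LD.
#'
#' @param data A scenario tibble, as returned by [scenario()] or
#'   [scenario_grid()].
#' @param stratum Strata to return: any of `"case"`, `"control"`,
#'   `"population"`.
#' @param loci `"disease"` for the disease-locus haplotype frequencies or
#'   `"marker"` for the marker-cell frequencies.
#' @param controls Control-stratum convention: `"mixture"` (default;
#'   exact prevalence mixture against an independent population) or
#'   `"interaction"` (interaction coefficient applied in controls as well,
#'   the convention behind the published figures).
#' @param projection Marker projection: `"conditional"` (default; proper
#'   conditional probabilities, cells form a distribution) or `"verbatim"`
#'   (the published four-term formulas taken literally; cells are
#'   unnormalized and only meaningful inside the published closed-form
#'   pipeline).
#'
#' @return A tibble with one row per scenario and stratum: the scenario
#'   columns, `stratum`, `loci`, and `f11`, `f10`, `f01`, `f00`.
#'
#' @examples
#' haplotype_freqs(scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1),
#'                 stratum = c("case", "control"))
#' @export
haplotype_freqs <- function(data,
                            stratum = c("case", "control", "population"),
                            loci = c("disease", "marker"),
                            controls = c("mixture", "interaction"),
                            projection = c("conditional", "verbatim")) {
  validate_scenarios(data)
  stratum <- match.arg(stratum, several.ok = TRUE)
  loci <- rlang::arg_match(loci)
  controls <- rlang::arg_match(controls)
  projection <- rlang::arg_match(projection)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    p <- as.list(data[i, ])
    purrr::map(stratum, function(s) {
      fr <- stratum_freqs(p, s, loci = loci, controls = controls,
                          projection = projection)
      dplyr::bind_cols(data[i, ],
                       tibble(stratum = s, loci = loci),
                       as_tibble(as.list(fr)))
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}
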