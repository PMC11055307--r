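---
title: "Power analysis for LD-based detection of gene-gene interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power analysis for LD-based detection of gene-gene interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipower)
library(dplyr)
```

## The model

Statistical epistasis between two unlinked disease loci X1 and X2 can be
expressed, on the haplotype (single-chromosome) scale, as *extra linkage
disequilibrium between the two loci among affected individuals*. If the
two loci are independent in the general population, any LD between them
within cases must come from a non-additive joint effect on disease risk.
`epipower` is a design-stage calculator for the case-control test of that
signal at linked marker loci.

The model is haploid throughout: a "sample of N chromosomes" means N
phased haplotypes, and all frequencies are chromosome frequencies. The
parameters of one scenario are:

| parameter | meaning | default |
|---|---|---|
| `f_x1`, `f_x2` | population risk-allele frequencies at X1, X2 | 0.05 |
| `p_m1`, `p_m2` | allele frequencies at markers M1, M2 | 0.05 |
| `r_x1`, `r_x2` | per-allele relative risks (incidence ratio carriers : non-carriers) | 2 |
| `k` | interaction coefficient | 1 |
| `prevalence` | disease prevalence `phi` | 0.1 |
| `d1_prime`, `d2_prime` | Lewontin's D' of each marker with its disease locus | 1 |
| `n_case`, `n_control` | chromosomes per group | 10000 |
| `alpha` | significance level | 0.05 |

The defaults are the baseline configuration of the reference analysis the
figure presets mirror: rare risk alleles (0.05), perfectly tagging
markers, 10% prevalence and 10,000 chromosomes per group. Realistic
relative risks for single common alleles are of the order 1.1–2, which is
why the default sits at 2 and the presets sweep 1–3.

Among case chromosomes the risk-allele frequency is the incidence-ratio
enrichment

$$f_{1*D} = \frac{R_{1} f_{1*}}{R_{1} f_{1*} + (1 - f_{1*})},$$

and the interaction coefficient K defines the case joint frequency
multiplicatively,

$$f_{11D} = (1 + K)\, f_{1*D} f_{*1D},$$

so K is exactly the relative excess of the double-risk haplotype over
independence within cases; `haplotype_freqs()` inverts this identity to
K within 1e-10 for any feasible scenario. K = 0 means no interaction.

The tested quantity is the effect size

$$\beta = \beta_D - \beta_d, \qquad
  \beta_s = p_{11s} p_{00s} - p_{10s} p_{01s},$$

the difference between the marker-pair LD in cases (D) and controls (d),
estimated by plugging in observed cell proportions. Its sampling variance
under multinomial sampling of each group is the classical large-sample
variance of the LD determinant estimator, summed over the two independent
groups. The test statistic is $S = \hat\beta^2 / \widehat{Var}(\hat\beta)$,
central $\chi^2_1$ under the null, and analytic power uses the noncentral
$\chi^2_1$ with noncentrality $E(\hat\beta)^2 / Var(\hat\beta)$, with the
variance evaluated under the alternative (matching the plug-in
statistic). Testing is two-sided throughout.

For comparison, `single_site_power()` implements the regular marker
association test at M1: a two-sample allele-frequency chi-square whose
noncentrality is the squared case-control frequency difference over the
sum of its binomial variances. Its effect depends only on the marker
*marginals*, which are identical under both control conventions below, so
it takes no convention argument.

## Two conventions: `consistent` and `published`

The enrichment formula above pins down the case stratum, but two further
ingredients are under-determined and had to be fixed by design:

**The control stratum.** Total probability over disease status forces the
control *marginals* to be the exact prevalence mixture
$f_{1*d} = (f_{1*} - \phi f_{1*D}) / (1 - \phi)$. The control *joint* is
not forced. Two choices are implemented behind
`controls = c("mixture", "interaction")`:

* `"mixture"` derives the joint the same way,
  $f_{11d} = (f_{1*}f_{*1} - \phi f_{11D})/(1-\phi)$ — the unique joint
  for which prevalence-weighting cases and controls reconstitutes an
  independent population cell-by-cell. It is the internally coherent
  choice and the package default.
* `"interaction"` applies the interaction coefficient in controls too,
  $f_{11d} = (1 + K) f_{1*d} f_{*1d}$. This is the convention behind the
  published reference figures: with it (and the verbatim projection
  below) every printed effect size, variance and power is reproduced to
  its printed precision, which is how the convention was identified.

The two differ materially. Under `"mixture"`, controls carry *negative*
LD (the population is independent, cases are positively associated, so
controls must compensate), which roughly doubles the effect size; under
`"interaction"` both strata are positively associated and only the
frequency enrichment differentiates them. The mixture convention also has
a harder feasibility edge: $\phi (1+K) f_{1*D} f_{*1D} \le f_{1*}f_{*1}$,
violated already at the baseline frequencies for K = 2 with R = 2, a
configuration the reference figures do use. Scenario construction
therefore validates only the case stratum eagerly; each control
convention enforces its own bounds when control frequencies are derived,
with an error naming the violated cell.

**The marker projection.** Disease-locus frequencies are projected onto
the markers through the marker–disease LD $D_i$ (from
`dprime_to_d()`, $D = D' \cdot \min(p(1-f), (1-p)f)$; only nonnegative
association is modelled, the tagging allele tags the risk allele).
`projection = "conditional"` uses the proper conditional probabilities of
the signed 2x2 decomposition, $P(M{=}1\mid X{=}1) = (pf + D)/f$ and
$P(M{=}1\mid X{=}0) = (p(1-f) - D)/(1-f)$; the projected cells form a
probability distribution, and with $D' = 1$ and $p = f$ the markers
coincide with the disease loci exactly. `projection = "verbatim"`
instead evaluates the reference analysis's four-term cell formulas
literally, with "+D" in *every* numerator including the M = 0
complements. Those cells are **not** a distribution (they can sum to well
over 1), the determinant and covariance forms of their LD no longer
agree, and the projected power is not even monotone in $D'$ near 1 — but
they are what the published numbers were computed from, and only they
reproduce those numbers.

The shorthand `convention = "consistent"` (mixture + conditional,
default) or `"published"` (interaction + verbatim) sets both at once.
Use `"consistent"` for design work — it is the variant whose every
analytic quantity the Monte Carlo simulator verifies — and
`"published"` to reproduce the reference tables and figures. The figure
presets (`preset_grid("fig1a")` … `"fig6d"`) carry the published
convention by default for that reason.

```{r conventions}
sc <- scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1)
bind_rows(
  consistent = effect_size(sc)[, c("expectation", "variance")],
  published = effect_size(sc, convention = "published")[, c("expectation",
                                                            "variance")],
  .id = "convention"
)
```

## The simulator and what passing tests mean

`sample_marker_tables()` draws case and control tables from independent
multinomials over the four marker cells — necessarily under the
`conditional` projection, since the verbatim cells cannot parameterize a
multinomial. A single master seed is split deterministically into one
sub-stream per scenario and stratum, so enlarging the control group never
perturbs the case draws and every result is exactly reproducible from
`(parameters, replicates, seed)`.

`empirical_power()` and `empirical_beta_moments()` are the oracle for the
analytic layer: across randomized feasible scenarios, analytic
$E(\hat\beta)$ and $Var(\hat\beta)$ match the Monte Carlo moments within
3 Monte Carlo standard errors, the null statistic is central
$\chi^2_1$ (Kolmogorov–Smirnov), the type-I error is nominal, and
analytic power matches empirical rejection rates. The test suite uses
20,000 replicates for moment checks and 5,000 for power and calibration
at 10,000 chromosomes per group — the scale at which the large-sample
variance formula and the noncentral-chi-square approximation are
accurate; at a few hundred chromosomes per group the plug-in statistic
is visibly anti-conservative and only the finite-sample expectation
(`large_n = FALSE`, which subtracts the `covariance_marginals()` terms)
remains exact.

What the generator emulates is the model's own sampling process: phased
haplotypes, known phase, multinomial counts. It does not emulate diploid
genotypes (no Hardy–Weinberg pairing of haplotypes into individuals, no
nine-genotype penetrance models), phase uncertainty, population
stratification, genotyping error or ascertainment. Passing tests
therefore validate the calculator against its own assumptions, not the
behaviour of the test on real genotype data.

## Numerical choices

* Closed-form frequency identities are asserted to 1e-12 absolute
  (normalization, mixture conservation, determinant/covariance identity)
  and K-recovery to 1e-10; these are pure arithmetic, so tolerances are
  near machine precision.
* Feasibility slack is 1e-15, so scenarios on the boundary
  (e.g. $f_{11D} = \min(f_{1*D}, f_{*1D})$ exactly) are accepted.
* Degenerate observed tables (a marker fixed in both strata, plug-in
  variance zero) raise a classed error from `interaction_test()`; the
  simulator counts them as non-rejections and reports the count, warning
  if they exceed 1% of replicates.
* Grid evaluation never aborts on an infeasible grid point: the row is
  flagged with the violated bound and the rest of the grid is computed.

## Presets and known limitations

The presets encode the reference figure scenarios: `fig1a`/`fig1b`
(effect size against K and R), `fig2` (variance against sample size for
`f_x1` in 0.05/0.1/0.15), `fig3`/`fig4` (power against R, K and sample
size), `fig5a`–`d` and `fig6a`–`d` (power of both tests against
$D_1'$ or K for three `f_x1` values at the four significance tiers
5e-2, 5e-4, 5e-6, 5e-8). Sweep granularity is evenly spaced over the
stated endpoints where the source states none.

Known limitations, all inherent to the scope:

* Two loci only; no higher-order interactions.
* Haploid analysis; diploid nine-genotype disease models are out of
  scope (dominant or recessive coding reduces to this model when phase
  is unambiguous).
* Nonnegative D' only.
* The `fig2` preset reproduces the published variance exactly at
  `f_x1 = 0.05`; at 0.1 and 0.15 the reference values correspond to
  holding the *raw* LD value D at its 0.05-frequency maximum rather than
  re-normalizing D' at the new frequency, so the preset (which uses D' as
  specified) deviates from them by a few percent there.
* The `fig6` interaction-coefficient sweep at `f_x1 = 0.3` leaves the
  haploid feasible region near K = 1.17 ($f_{11D}$ would exceed a case
  marginal); those grid points are reported as infeasible although the
  published curves extend across them.
* At genome-wide significance (5e-8) the interaction test's power is
  below 0.01 almost everywhere on the `fig5d` grid, but not literally
  everywhere: the published convention still yields up to 0.059 at
  `f_x1 = 0.2` with strong marker LD. "Essentially powerless" is the
  accurate summary; a uniform bound below 0.01 is not.
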