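# epipower

Power analysis for detecting **statistical epistasis** (gene–gene
interaction) in case-control genetic association studies, under the model
in which interaction between two unlinked disease loci appears as *extra
linkage disequilibrium (LD) between them among affected chromosomes*.

Researchers running GWAS-scale interaction scans almost never find
replicable epistasis. This toolkit quantifies why, at the design stage:
for a scenario defined by allele frequencies, per-allele relative risks
R, an interaction coefficient K, disease prevalence, marker–disease LD
(D′) and sample sizes, it computes in closed form

- the case/control/population two-locus haplotype frequencies and their
  projection onto marker loci,
- the expectation and sampling variance of the effect size
  β̂ = β̂_D − β̂_d, the difference between the marker-pair LD in cases
  (β_D = p11 p00 − p10 p01) and in controls,
- the power of the 1-df chi-square interaction test
  S = β̂² / Var(β̂) via the noncentral chi-square with noncentrality
  E(β̂)²/Var(β̂),
- the power of the regular single-site marker association test for
  comparison, and Bonferroni thresholds for quadratic numbers of marker
  pairs,

plus a seeded multinomial Monte Carlo simulator that validates every
analytic quantity, figure-preset scenario grids, a YAML configuration
loader, ggplot2 `autoplot()` methods and a thin command-line front end
(`inst/cli/epipower.R`).

Two model conventions are provided (see the methods vignette,
`vignettes/ld-epistasis-power.Rmd`): the internally `"consistent"`
default (exact prevalence-mixture controls, proper conditional marker
projection — what the simulator verifies) and the `"published"`
convention (interaction coefficient applied in both strata, verbatim
four-term marker-cell formulas) that reproduces the reference study's
printed effect sizes, variances and powers to their printed precision.

## Worked example

A strong-interaction scenario: K = 2, R = 1.8 at both loci, risk-allele
and marker frequencies 0.05, perfect marker LD, prevalence 0.1, 10,000
chromosomes per group, alpha = 0.05.

```r
library(epipower)
library(dplyr)

sc <- scenario(k = 2, r_x1 = 1.8, r_x2 = 1.8)

interaction_power(sc, convention = "published") |>
  select(k, r_x1, n_case, alpha, expectation, variance, noncentrality, power)
#> # A tibble: 1 × 8
#>       k  r_x1 n_case alpha expectation   variance noncentrality power
#>   <dbl> <dbl>  <dbl> <dbl>       <dbl>      <dbl>         <dbl> <dbl>
#> 1     2   1.8  10000  0.05     0.00706 0.00000589          8.45 0.828
```

Even with an interaction coefficient of 2 — a 3-fold excess of the
double-risk haplotype among cases — the interaction test reaches only
power 0.83 at a *nominal* 0.05 level with 10,000 chromosomes per group.
The regular single-site test at marker M1 in the same scenario is far
stronger (the case-control marker frequency difference 0.087 vs 0.046
drives power to 1):

```r
single_site_power(sc) |> select(p1_case, p1_control, power)
#> # A tibble: 1 × 3
#>   p1_case p1_control power
#>     <dbl>      <dbl> <dbl>
#> 1  0.0865     0.0459     1
```

At a genome-wide threshold the contrast is stark: tightening `alpha`
to `bonferroni_threshold(0.05, 1e6) = 5e-8` collapses interaction power
to below 0.06 everywhere on the preset grids while single-site power
survives — the package's quantitative account of "missing epistasis".

The simulator cross-checks any analytic number; at the null it shows the
test keeps its size:

```r
sim <- empirical_power(scenario(r_x1 = 1, r_x2 = 1, k = 0),
                       replicates = 1000, seed = 1)
tidy(sim) |> select(test, replicates, rejection_rate, rejection_se)
#> # A tibble: 1 × 4
#>   test        replicates rejection_rate rejection_se
#>   <chr>            <dbl>          <dbl>        <dbl>
#> 1 interaction       1000          0.046      0.00662
```

Figure-style sweeps come from presets:

```r
run_grid(preset_grid("fig5a")) |> ggplot2::autoplot()
```

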