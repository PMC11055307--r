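# Shared fixtures for the test suite. All fixtures are built in code.

# The recurring baseline: frequency 0.05 at every locus, complete LD,
# prevalence 0.1, 10000 chromosomes per group, alpha 0.05.
baseline_scenario <- function(...) scenario(...)

# A reproducible set of randomized feasible scenarios for property-style
# sweeps. Frequencies and risks are drawn over realistic ranges and any
# draw that fails feasibility is rejected and redrawn.
random_scenarios <- function(n, seed, n_case = 5000, n_control = 5000) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 1
  while (i <= n) {
    cand <- try(scenario(
      f_x1 = runif(1, 0.05, 0.4), f_x2 = runif(1, 0.05, 0.4),
      p_m1 = runif(1, 0.05, 0.4), p_m2 = runif(1, 0.05, 0.4),
      r_x1 = runif(1, 1, 2.5), r_x2 = runif(1, 1, 2.5),
      k = runif(1, -0.5, 1.5), prevalence = runif(1, 0.05, 0.2),
      d1_prime = runif(1, 0.2, 1), d2_prime = runif(1, 0.2, 1),
      n_case = n_case, n_control = n_control
    ), silent = TRUE)
    if (!inherits(cand, "try-error")) {
      ok <- !inherits(try(haplotype_freqs(cand, stratum = "control"),
                          silent = TRUE), "try-error")
      if (ok) {
        out[[i]] <- cand
        i <- i + 1
      }
    }
  }
  dplyr::bind_rows(out)
}

# Direct scalar transcription of the closed-form case marginal, used as an
# independent check of vectorized code paths.
oracle_case_marginal <- function(f, r) r * f / (r * f + 1 - f)
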