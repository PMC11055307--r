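test_that("dprime_to_d applies the Lewontin normalization", {
  expect_equal(dprime_to_d(1.0, 0.05, 0.05), 0.0475)
  expect_equal(dprime_to_d(0.0, 0.2, 0.3), 0)
  # Dmax = min(0.18, 0.08) = 0.08, halved
  expect_equal(dprime_to_d(0.5, 0.2, 0.1), 0.04)
  expect_error(dprime_to_d(1.2, 0.2, 0.1), class = "epipower_error_invalid_parameter")
  expect_error(dprime_to_d(0.5, 0, 0.1), class = "epipower_error_invalid_parameter")
})

test_that("case haplotype frequencies follow the relative-risk enrichment", {
  sc <- scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1)
  hf <- haplotype_freqs(sc, stratum = "case", loci = "disease")
  # marginal: R f / (R f + 1 - f) = 0.075 / 1.025
  expect_equal(hf$f11 + hf$f10, 0.075 / 1.025, tolerance = 1e-12)
  # joint: (1 + K) times the product of the case marginals
  expect_equal(hf$f11, 2 * (0.075 / 1.025)^2, tolerance = 1e-12)
  expect_equal(hf$f11, 0.0107079, tolerance = 1e-5)

  # K = 0 removes the extra LD entirely
  hf0 <- haplotype_freqs(scenario(r_x1 = 1.5, r_x2 = 1.5, k = 0),
                         stratum = "case", loci = "disease")
  expect_equal(hf0$f11, (hf0$f11 + hf0$f10) * (hf0$f11 + hf0$f01),
               tolerance = 1e-14)
})

test_that("mixture controls invert the prevalence mixture exactly", {
  sc <- scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1)
  ctl <- haplotype_freqs(sc, stratum = "control", loci = "disease")
  expect_equal(ctl$f11 + ctl$f10, (0.05 - 0.1 * 0.075 / 1.025) / 0.9,
               tolerance = 1e-12)
  expect_equal(ctl$f11 + ctl$f10, 0.0474255, tolerance = 1e-5)

  # defining property: phi * case + (1 - phi) * control = population
  cs <- haplotype_freqs(sc, stratum = "case", loci = "disease")
  pop <- haplotype_freqs(sc, stratum = "population", loci = "disease")
  for (cell in c("f11", "f10", "f01", "f00")) {
    expect_equal(0.1 * cs[[cell]] + 0.9 * ctl[[cell]], pop[[cell]],
                 tolerance = 1e-12)
  }

  # no association with disease: controls equal the population products
  null_ctl <- haplotype_freqs(scenario(r_x1 = 1, r_x2 = 1, k = 0),
                              stratum = "control", loci = "disease")
  expect_equal(null_ctl$f11, 0.05 * 0.05, tolerance = 1e-14)
  expect_equal(null_ctl$f10, 0.05 * 0.95, tolerance = 1e-14)
})

test_that("marker projection collapses and factorizes in the limiting cases", {
  # complete LD with matching frequencies: markers coincide with the
  # disease loci
  sc <- scenario(r_x1 = 1.5, r_x2 = 1.5, k = 1)
  mk <- haplotype_freqs(sc, stratum = "case", loci = "marker")
  dis <- haplotype_freqs(sc, stratum = "case", loci = "disease")
  expect_equal(unlist(mk[c("f11", "f10", "f01", "f00")]),
               unlist(dis[c("f11", "f10", "f01", "f00")]),
               tolerance = 1e-12)
  expect_equal(mk$f11, 0.0107079, tolerance = 1e-5)
  expect_equal(mk$f10, 0.0624628, tolerance = 1e-5)
  expect_equal(mk$f00, 0.8643664, tolerance = 1e-5)

  # D' = 0: markers independent of disease status and of each other
  sc0 <- scenario(d1_prime = 0, d2_prime = 0, r_x1 = 2, r_x2 = 2, k = 1)
  for (s in c("case", "control")) {
    mk0 <- haplotype_freqs(sc0, stratum = s, loci = "marker")
    expect_equal(mk0$f11, 0.05 * 0.05, tolerance = 1e-12)
  }
})

test_that("frequency vectors normalize and satisfy the 2x2 LD identity", {
  grid <- random_scenarios(12, seed = 42)
  for (s in c("case", "control", "population")) {
    for (l in c("disease", "marker")) {
      hf <- haplotype_freqs(grid, stratum = s, loci = l)
      cells <- as.matrix(hf[, c("f11", "f10", "f01", "f00")])
      expect_true(all(cells >= -1e-12 & cells <= 1 + 1e-12))
      expect_equal(rowSums(cells), rep(1, nrow(cells)), tolerance = 1e-12)
      # determinant form == covariance form of the LD
      det_form <- cells[, 1] * cells[, 4] - cells[, 2] * cells[, 3]
      cov_form <- cells[, 1] -
        (cells[, 1] + cells[, 2]) * (cells[, 1] + cells[, 3])
      expect_equal(det_form, cov_form, tolerance = 1e-12)
    }
  }
})

test_that("interaction coefficient is recovered from case frequencies", {
  grid <- random_scenarios(12, seed = 7)
  hf <- haplotype_freqs(grid, stratum = "case", loci = "disease")
  k_back <- hf$f11 / ((hf$f11 + hf$f10) * (hf$f11 + hf$f01)) - 1
  expect_equal(k_back, grid$k, tolerance = 1e-10)
})

test_that("case marginal increases with relative risk", {
  rs <- seq(1, 4, by = 0.25)
  marg <- vapply(rs, function(r) {
    hf <- haplotype_freqs(scenario(r_x1 = r), stratum = "case",
                          loci = "disease")
    hf$f11 + hf$f10
  }, numeric(1))
  expect_true(all(diff(marg) > 0))
  expect_equal(marg, oracle_case_marginal(0.05, rs), tolerance = 1e-12)
})

test_that("infeasible parameter sets are rejected eagerly with a named bound", {
  # (1 + k) inflation beyond the smaller case marginal
  expect_error(scenario(f_x1 = 0.4, f_x2 = 0.4, r_x1 = 2.5, r_x2 = 2.5,
                        k = 1.5),
               "f11D", class = "epipower_error_infeasible")
  # case enrichment exceeding the population supply: the exact mixture
  # control stratum does not exist, and says so when derived
  strong <- scenario(f_x1 = 0.1, f_x2 = 0.1, r_x1 = 3, r_x2 = 3, k = 2,
                     prevalence = 0.4)
  expect_error(haplotype_freqs(strong, stratum = "control"),
               class = "epipower_error_infeasible")
  # ... while the interaction convention remains feasible there
  expect_silent(haplotype_freqs(strong, stratum = "control",
                                controls = "interaction"))
  expect_error(scenario(alpha = 0), class = "epipower_error_invalid_parameter")
  expect_error(scenario(n_case = 0), class = "epipower_error_invalid_parameter")
})

test_that("published control convention applies K in both strata", {
  sc <- scenario(r_x1 = 2, r_x2 = 2, k = 1)
  ctl <- haplotype_freqs(sc, stratum = "control", loci = "disease",
                         controls = "interaction")
  f1d <- ctl$f11 + ctl$f10
  f2d <- ctl$f11 + ctl$f01
  expect_equal(ctl$f11, 2 * f1d * f2d, tolerance = 1e-14)
  # marginals agree with the mixture convention
  mix <- haplotype_freqs(sc, stratum = "control", loci = "disease")
  expect_equal(f1d, mix$f11 + mix$f10, tolerance = 1e-14)
})
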