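test_that("scenario_grid expands sweeps in order and echoes parameters", {
  g <- scenario_grid(scenario(), list(r_x = c(1.5, 2), k = c(0, 1, 2)))
  expect_equal(nrow(g), 6)
  # first sweep varies slowest
  expect_equal(g$r_x1, rep(c(1.5, 2), each = 3))
  expect_equal(g$k, rep(c(0, 1, 2), times = 2))
  expect_equal(g$r_x1, g$r_x2)
  expect_true(all(g$feasible))

  # empty sweep list: single-row grid of the base itself
  single <- scenario_grid(scenario(k = 0.3), list())
  expect_equal(nrow(single), 1)
  expect_equal(single$k, 0.3)

  expect_error(scenario_grid(scenario(), list(bogus = 1:3)),
               "bogus", class = "epipower_error_invalid_parameter")
})

test_that("infeasible grid points are flagged per row, not fatal", {
  g <- scenario_grid(scenario(f_x1 = 0.4, f_x2 = 0.4, r_x1 = 2.5,
                              r_x2 = 2.5, k = 0),
                     list(k = c(0, 0.5, 1.5)))
  expect_equal(g$feasible, c(TRUE, TRUE, FALSE))
  res <- run_grid(g, outputs = "expectation")
  expect_equal(is.na(res$value), c(FALSE, FALSE, TRUE))
  expect_match(res$infeasible_reason[3], "f11D")
})

test_that("run_grid returns one long row per grid point and quantity", {
  g <- scenario_grid(scenario(), list(k = c(0.5, 1)),
                     outputs = c("expectation", "power_interaction"))
  res <- run_grid(g)
  expect_equal(nrow(res), 4)
  expect_setequal(unique(res$quantity), c("expectation",
                                          "power_interaction"))
  # analytic outputs are byte-stable across runs
  expect_identical(res$value, run_grid(g)$value)
})

test_that("figure presets encode the stated scenario parameters", {
  f1 <- preset_grid("fig1a")
  expect_true(all(f1$f_x1 == 0.05 & f1$p_m2 == 0.05))
  expect_true(all(f1$d1_prime == 1 & f1$d2_prime == 1))
  expect_true(all(f1$prevalence == 0.1))
  expect_setequal(unique(f1$r_x1), c(1.5, 2, 2.5))
  expect_equal(range(f1$k), c(0, 2))

  f5d <- preset_grid("fig5d")
  expect_true(all(f5d$alpha == 5e-8))
  expect_true(all(f5d$f_x2 == 0.2 & f5d$p_m1 == 0.2 & f5d$p_m2 == 0.2))
  expect_true(all(f5d$d2_prime == 1))
  expect_setequal(unique(f5d$f_x1), c(0.1, 0.2, 0.3))
  expect_equal(sort(unique(f5d$d1_prime)), seq(0.1, 1, by = 0.1))
  expect_equal(attr(f5d, "convention"), "published")

  # the published fig1a numbers drop out of the preset at (K = 1, r = 1.5)
  res <- run_grid(preset_grid("fig1a"))
  row <- dplyr::filter(res, r_x1 == 1.5, k == 1)
  expect_equal(row$value, 2.04e-3, tolerance = 0.005)
})

test_that("configuration files round-trip and validate their schema", {
  g <- scenario_grid(scenario(f_x1 = 0.1), list(k = c(0.5, 1)),
                     outputs = "variance")
  path <- tempfile(fileext = ".yaml")
  save_scenario_config(g, path)
  g2 <- load_scenario_config(path)
  expect_equal(as.data.frame(g2), as.data.frame(g))
  expect_equal(attr(g2, "outputs"), "variance")

  # minimal config: defaults filled in
  minimal <- tempfile(fileext = ".yaml")
  writeLines("sweeps:\n  k: [0.5, 1.0]\n", minimal)
  gm <- load_scenario_config(minimal)
  expect_equal(nrow(gm), 2)
  expect_true(all(gm$f_x1 == 0.05 & gm$n_case == 10000 & gm$alpha == 0.05))

  # schema errors list every invalid field
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("base:", "  nope: 1", "sweeps:", "  wrong: [1, 2]",
               "outputs: [bogus]"), bad)
  err <- tryCatch(load_scenario_config(bad), error = identity)
  expect_s3_class(err, "epipower_error_invalid_parameter")
  expect_match(conditionMessage(err), "nope")
  expect_match(conditionMessage(err), "wrong")
  expect_match(conditionMessage(err), "bogus")

  # preset reference in a config
  pre <- tempfile(fileext = ".yaml")
  writeLines("preset: fig2", pre)
  expect_equal(attr(load_scenario_config(pre), "preset"), "fig2")
})

test_that("grid TSV export carries the annotated header", {
  res <- run_grid(scenario_grid(scenario(), list(k = c(0.5, 1))),
                  outputs = "expectation")
  path <- tempfile(fileext = ".tsv")
  write_grid_tsv(res, path)
  lines <- readLines(path)
  expect_match(lines[1], "^# epipower")
  body <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(body), 2)
})

test_that("autoplot draws power curves from a grid result", {
  res <- run_grid(scenario_grid(scenario(), list(r_x = c(1.5, 2),
                                                 k = c(0, 1, 2))))
  p <- ggplot2::autoplot(res)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})

test_that("every analytic preset evaluates end to end quickly", {
  for (nm in setdiff(preset_names(), c("fig5b", "fig5c", "fig6b",
                                       "fig6c"))) {
    res <- run_grid(preset_grid(nm))
    expect_true(all(is.finite(res$value[res$feasible])), info = nm)
  }
})
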