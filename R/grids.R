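# Scenario grids, figure presets, configuration files and the long-format
# results table.

# Sweep names may be single scenario fields or linked pairs that move both
# loci (or both group sizes) together.
linked_sweeps <- function() {
  list(r_x = c("r_x1", "r_x2"), f_x = c("f_x1", "f_x2"),
       p_m = c("p_m1", "p_m2"), d_prime = c("d1_prime", "d2_prime"),
       n = c("n_case", "n_control"))
}

resolve_sweep_fields <- function(nm) {
  if (nm %in% scenario_fields()) return(nm)
  lk <- linked_sweeps()
  if (nm %in% names(lk)) return(lk[[nm]])
  abort(paste0("unknown sweep parameter: '", nm, "'; must be one of ",
               paste(c(scenario_fields(), names(lk)), collapse = ", ")),
        class = "epipower_error_invalid_parameter")
}

#' Build a grid of scenarios from a base scenario and parameter sweeps
#'
#' The grid is the Cartesian product of the sweeps applied to the base
#' scenario, ordered with the first sweep varying slowest. Sweep names are
#' scenario fields, or one of the linked pseudo-fields `r_x`, `f_x`,
#' `p_m`, `d_prime`, `n`, which set both members of the corresponding pair
#' at once. Infeasible grid points are kept and flagged in the `feasible`
#' column rather than rejected, so a sweep may legitimately cross the edge
#' of the feasible region.
#'
#' @param base A one-row scenario tibble, e.g. from [scenario()].
#' @param sweeps Named list of value vectors, e.g.
#'   `list(k = seq(0, 2, 0.5), r_x = c(1.5, 2, 2.5))`.
#' @param outputs Character vector of quantities for [run_grid()]; any of
#'   `"expectation"`, `"variance"`, `"power_interaction"`,
#'   `"power_single_site"`, `"empirical_power"`.
#' @return A tibble of scenarios (class `epi_grid`) with `feasible` and
#'   `infeasible_reason` columns; the base, sweeps and outputs are kept as
#'   attributes so the grid can be serialized with
#'   [save_scenario_config()].
#' @examples
#' scenario_grid(scenario(), list(k = c(0.5, 1, 2)))
#' @export
scenario_grid <- function(base = scenario(), sweeps = list(),
                          outputs = "power_interaction") {
  stopifnot(is.data.frame(base), nrow(base) == 1)
  outputs <- match.arg(outputs, grid_outputs(), several.ok = TRUE)
  if (length(sweeps) > 0 &&
      (is.null(names(sweeps)) || any(names(sweeps) == ""))) {
    abort("every sweep must be named",
          class = "epipower_error_invalid_parameter")
  }
  vals <- lapply(sweeps, identity)
  grid <- if (length(vals) == 0) {
    tibble(.row = 1L)
  } else {
    g <- rev(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE))
    as_tibble(g)
  }
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    p <- as.list(base)
    for (nm in names(sweeps)) {
      for (fld in resolve_sweep_fields(nm)) p[[fld]] <- grid[[nm]][i]
    }
    as_tibble(p[scenario_fields()])
  })
  out <- dplyr::bind_rows(rows)
  feas <- purrr::map(seq_len(nrow(out)), function(i) {
    err <- tryCatch({
      assert_feasible(as.list(out[i, ]))
      NA_character_
    }, error = function(e) conditionMessage(e))
    tibble(feasible = is.na(err), infeasible_reason = err)
  })
  out <- dplyr::bind_cols(out, dplyr::bind_rows(feas))
  structure(out, class = c("epi_grid", class(out)),
            base = base, sweeps = sweeps, outputs = outputs)
}

grid_outputs <- function() {
  c("expectation", "variance", "power_interaction", "power_single_site",
    "empirical_power")
}

#' Preset scenario grids mirroring the published figures
#'
#' Each preset encodes the parameter statements of one published results
#' panel: effect-size curves over the interaction coefficient and relative
#' risk (`fig1a`, `fig1b`), variance against sample size (`fig2`),
#' power against relative risk, interaction coefficient and sample size
#' (`fig3a`, `fig3b`, `fig4a`, `fig4b`), and the marker-LD /
#' significance-tier grids comparing the interaction test with the
#' single-site test (`fig5a`-`fig5d`, `fig6a`-`fig6d`). Where a panel's
#' sweep range is not stated numerically, the sweep covers the stated
#' endpoints with evenly spaced points. Presets carry
#' `convention = "published"` so that [run_grid()] reproduces the figure
#' values by default.
#'
#' @param name One of the names returned by `preset_names()`.
#' @return A scenario grid as from [scenario_grid()].
#' @examples
#' preset_grid("fig1a")
#' preset_names()
#' @export
preset_grid <- function(name) {
  name <- rlang::arg_match0(name, preset_names())
  fig1_base <- scenario()  # f = 0.05 at all loci, D' = 1, phi = 0.1,
                           # N = 10000, alpha = 0.05
  fig5_base <- scenario(f_x2 = 0.2, p_m1 = 0.2, p_m2 = 0.2, f_x1 = 0.2,
                        r_x1 = 2, r_x2 = 2, k = 1, d2_prime = 1)
  tiers <- c(a = 5e-2, b = 5e-4, c = 5e-6, d = 5e-8)
  g <- switch(name,
    fig1a = scenario_grid(fig1_base,
      list(r_x = c(1.5, 2, 2.5), k = seq(0, 2, by = 0.1)),
      outputs = "expectation"),
    fig1b = scenario_grid(fig1_base,
      list(k = c(0.5, 1, 2), r_x = seq(1, 3, by = 0.1)),
      outputs = "expectation"),
    fig2 = scenario_grid(scenario(k = 1, r_x1 = 2, r_x2 = 2),
      list(f_x1 = c(0.05, 0.1, 0.15), n = seq(500, 10000, by = 500)),
      outputs = "variance"),
    fig3a = scenario_grid(fig1_base,
      list(k = c(0.5, 1, 2), r_x = seq(1, 2, by = 0.05)),
      outputs = "power_interaction"),
    fig3b = scenario_grid(scenario(k = 1),
      list(n = c(1000, 5000, 10000), r_x = seq(1, 3, by = 0.1)),
      outputs = "power_interaction"),
    fig4a = scenario_grid(fig1_base,
      list(r_x = c(1.2, 2, 2.5), k = seq(0, 2, by = 0.1)),
      outputs = "power_interaction"),
    fig4b = scenario_grid(scenario(r_x1 = 2, r_x2 = 2),
      list(n = c(1000, 5000, 10000), k = seq(0, 2, by = 0.1)),
      outputs = "power_interaction"),
    {
      fam <- substr(name, 1, 4)
      tier <- tiers[[substr(name, 5, 5)]]
      if (fam == "fig5") {
        scenario_grid(
          dplyr::mutate(fig5_base, alpha = tier),
          list(f_x1 = c(0.1, 0.2, 0.3), d1_prime = seq(0.1, 1, by = 0.1)),
          outputs = c("power_interaction", "power_single_site"))
      } else {
        scenario_grid(
          dplyr::mutate(fig5_base, alpha = tier, d1_prime = 0.5),
          list(f_x1 = c(0.1, 0.2, 0.3), k = seq(0, 2, by = 0.1)),
          outputs = c("power_interaction", "power_single_site"))
      }
    }
  )
  attr(g, "preset") <- name
  attr(g, "convention") <- "published"
  g
}

#' @rdname preset_grid
#' @export
preset_names <- function() {
  c("fig1a", "fig1b", "fig2", "fig3a", "fig3b", "fig4a", "fig4b",
    paste0("fig5", letters[1:4]), paste0("fig6", letters[1:4]))
}

#' Evaluate requested quantities over a scenario grid
#'
#' Produces a long-format results table: one row per feasible grid point
#' per requested quantity, with all resolved parameters echoed. Infeasible
#' grid points are reported with `NA` values and their reason, never
#' dropped silently and never fatal.
#'
#' @param grid A grid from [scenario_grid()] or [preset_grid()].
#' @param outputs Quantities to compute; defaults to the grid's own
#'   `outputs` attribute.
#' @param convention Passed to [effect_size()]/[interaction_power()];
#'   defaults to the grid's `convention` attribute (presets use
#'   `"published"`), otherwise `"consistent"`.
#' @param seed,replicates Used only when `outputs` includes
#'   `"empirical_power"`.
#' @return A tibble (class `epi_grid_result`) with the scenario columns
#'   plus `quantity` and `value`.
#' @examples
#' run_grid(scenario_grid(scenario(), list(k = c(0.5, 1))),
#'          outputs = "expectation")
#' @export
run_grid <- function(grid, outputs = NULL, convention = NULL,
                     seed = 1, replicates = 1000) {
  outputs <- outputs %||% attr(grid, "outputs") %||% "power_interaction"
  outputs <- match.arg(outputs, grid_outputs(), several.ok = TRUE)
  convention <- convention %||% attr(grid, "convention") %||% "consistent"
  if (!"feasible" %in% names(grid)) {
    grid$feasible <- TRUE
    grid$infeasible_reason <- NA_character_
  }
  eval_row <- function(q, row, i) {
    if (q == "expectation") {
      effect_size(row, convention = convention)$expectation
    } else if (q == "variance") {
      effect_size(row, convention = convention)$variance
    } else if (q == "power_interaction") {
      interaction_power(row, convention = convention)$power
    } else if (q == "power_single_site") {
      single_site_power(row)$power
    } else {
      empirical_power(row, replicates = replicates,
                      seed = seed + i)$rejection_rate
    }
  }
  pieces <- purrr::map(outputs, function(q) {
    res <- grid[, c(scenario_fields(), "feasible", "infeasible_reason")]
    res$quantity <- q
    res$value <- NA_real_
    for (i in which(res$feasible)) {
      v <- tryCatch(eval_row(q, grid[i, scenario_fields()], i),
                    error = function(e) conditionMessage(e))
      if (is.character(v)) {
        # infeasible under the chosen convention: flag, do not fail
        res$feasible[i] <- FALSE
        res$infeasible_reason[i] <- v
      } else {
        res$value[i] <- v
      }
    }
    res
  })
  out <- dplyr::bind_rows(pieces)
  structure(out, class = c("epi_grid_result", class(out)),
            sweeps = attr(grid, "sweeps"),
            preset = attr(grid, "preset"),
            convention = convention, seed = seed)
}

config_defaults <- function() as.list(scenario())

#' Read or write a scenario-grid configuration file
#'
#' The configuration is YAML with optional keys `preset` (a
#' [preset_grid()] name), `base` (scenario fields; omitted fields take the
#' baseline defaults: frequency 0.05 at all loci, complete LD, prevalence
#' 0.1, 10000 chromosomes per group, alpha 0.05), `sweeps` (named value
#' lists) and `outputs`. A `preset` key overrides `base`/`sweeps`.
#'
#' @param path File path.
#' @return `load_scenario_config()` returns a validated scenario grid;
#'   `save_scenario_config()` writes `grid`'s configuration and returns
#'   `path` invisibly.
#' @examples
#' path <- tempfile(fileext = ".yaml")
#' save_scenario_config(scenario_grid(scenario(), list(k = c(0.5, 1))), path)
#' load_scenario_config(path)
#' @export
load_scenario_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "epipower_error_invalid_parameter")
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) return(preset_grid(cfg$preset))
  base_in <- cfg$base %||% list()
  sweeps <- cfg$sweeps %||% list()
  outputs <- unlist(cfg$outputs) %||% "power_interaction"
  problems <- character(0)
  bad_base <- setdiff(names(base_in), scenario_fields())
  if (length(bad_base) > 0) {
    problems <- c(problems, paste0("unknown base field(s): ",
                                   paste(bad_base, collapse = ", ")))
  }
  bad_sweep <- setdiff(names(sweeps),
                       c(scenario_fields(), names(linked_sweeps())))
  if (length(bad_sweep) > 0) {
    problems <- c(problems, paste0("unknown sweep field(s): ",
                                   paste(bad_sweep, collapse = ", ")))
  }
  bad_out <- setdiff(outputs, grid_outputs())
  if (length(bad_out) > 0) {
    problems <- c(problems, paste0("unknown output(s): ",
                                   paste(bad_out, collapse = ", ")))
  }
  if (length(problems) > 0) {
    abort(paste0("invalid configuration:\n- ",
                 paste(problems, collapse = "\n- ")),
          class = "epipower_error_invalid_parameter")
  }
  base <- as_tibble(modifyList(config_defaults(), base_in))
  validate_scenarios(base)
  g <- scenario_grid(base, lapply(sweeps, unlist), outputs = outputs)
  if (!is.null(cfg$convention)) attr(g, "convention") <- cfg$convention
  g
}

#' @rdname load_scenario_config
#' @param grid A grid from [scenario_grid()] or [preset_grid()].
#' @export
save_scenario_config <- function(grid, path) {
  cfg <- if (!is.null(attr(grid, "preset"))) {
    list(preset = attr(grid, "preset"))
  } else {
    list(base = as.list(attr(grid, "base")),
         sweeps = lapply(attr(grid, "sweeps"), as.vector),
         outputs = as.list(attr(grid, "outputs")))
  }
  if (!is.null(attr(grid, "convention"))) {
    cfg$convention <- attr(grid, "convention")
  }
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write a grid results table as annotated TSV
#'
#' Writes the long-format results with a commented header block recording
#' the package version, preset name (if any), convention and seed.
#'
#' @param results A results table from [run_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_tsv <- function(results, path) {
  hdr <- c(
    paste0("# epipower ", as.character(utils::packageVersion("epipower"))),
    paste0("# preset: ", attr(results, "preset") %||% "(custom)"),
    paste0("# convention: ", attr(results, "convention") %||% "consistent"),
    paste0("# seed: ", attr(results, "seed") %||% "NA")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(results), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
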