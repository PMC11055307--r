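# Monte Carlo engine: multinomial sampling of case/control marker tables
# and empirical estimates of power, type-I error and the moments of the
# effect-size estimator.

# Deterministic per-scenario, per-stratum sub-seeds from one master seed.
# Case and control strata get independent streams, so changing n_control
# never perturbs the case draws.
stream_seeds <- function(seed, n_scenarios) {
  if (!is.finite(seed) || seed != round(seed)) {
    abort("seed must be an integer",
          class = "epipower_error_invalid_parameter")
  }
  set.seed(seed)
  matrix(sample.int(.Machine$integer.max, 2 * n_scenarios),
         ncol = 2, dimnames = list(NULL, c("case", "control")))
}

draw_counts <- function(sub_seed, replicates, n, probs) {
  set.seed(sub_seed)
  # multinomial over the four marker cells, order f11 f10 f01 f00
  t(rmultinom(replicates, size = n, prob = probs))
}

#' Simulate case/control marker count tables
#'
#' Draws `replicates` independent tables per scenario: case cells from a
#' multinomial with `n_case` chromosomes and the case marker-cell
#' probabilities, control cells independently from their own multinomial.
#' Sampling always uses the proper conditional marker projection (the
#' verbatim published cells are not a distribution and cannot be sampled
#' from).
#'
#' @inheritParams haplotype_freqs
#' @param replicates Number of tables per scenario.
#' @param seed Master integer seed; case and control strata of each
#'   scenario use separate sub-streams derived from it.
#' @return A tibble with `scenario`, `replicate` and the eight count
#'   columns `n11_case` ... `n00_control`.
#' @examples
#' sample_marker_tables(scenario(n_case = 200, n_control = 200),
#'                      replicates = 3, seed = 1)
#' @export
sample_marker_tables <- function(data, replicates = 1, seed = 1,
                                 controls = c("mixture", "interaction")) {
  validate_scenarios(data)
  controls <- rlang::arg_match(controls)
  if (replicates < 1) {
    abort("replicates must be at least 1",
          class = "epipower_error_invalid_parameter")
  }
  seeds <- stream_seeds(seed, nrow(data))
  purrr::map(seq_len(nrow(data)), function(i) {
    p <- as.list(data[i, ])
    pc <- stratum_freqs(p, "case", loci = "marker", controls = controls)
    pd <- stratum_freqs(p, "control", loci = "marker", controls = controls)
    cs <- draw_counts(seeds[i, "case"], replicates, p$n_case, pc)
    ct <- draw_counts(seeds[i, "control"], replicates, p$n_control, pd)
    tibble(
      scenario = i, replicate = seq_len(replicates),
      n11_case = cs[, 1], n10_case = cs[, 2],
      n01_case = cs[, 3], n00_case = cs[, 4],
      n11_control = ct[, 1], n10_control = ct[, 2],
      n01_control = ct[, 3], n00_control = ct[, 4]
    )
  }) |> dplyr::bind_rows()
}

single_site_stat <- function(counts) {
  nD <- counts$n11_case + counts$n10_case + counts$n01_case + counts$n00_case
  nd <- counts$n11_control + counts$n10_control + counts$n01_control +
    counts$n00_control
  p1D <- (counts$n11_case + counts$n10_case) / nD
  p1d <- (counts$n11_control + counts$n10_control) / nd
  v <- p1D * (1 - p1D) / nD + p1d * (1 - p1d) / nd
  ifelse(v > 0, (p1D - p1d)^2 / v, NA_real_)
}

new_epi_simulation <- function(results, replicates, seed, test) {
  structure(results,
            class = c("epi_simulation", class(results)),
            replicates = replicates, seed = seed, test = test)
}

#' Empirical power (or type-I error) by Monte Carlo simulation
#'
#' Samples `replicates` tables per scenario, applies the chosen test at
#' each scenario's `alpha`, and reports the rejection rate with its
#' binomial standard error. Degenerate tables (zero plug-in variance) are
#' counted as non-rejections and reported; if they exceed 1% of the
#' replicates a warning is attached to the result.
#'
#' @inheritParams sample_marker_tables
#' @param test `"interaction"` for the LD-difference statistic or
#'   `"single_site"` for the allele-frequency chi-square at M1.
#' @param detail_file Optional path: if given, per-replicate
#'   `(beta_hat, statistic, reject)` triples are written there as TSV.
#' @return A tibble (class `epi_simulation`) with the scenario columns
#'   plus `test`, `replicates`, `n_degenerate`, `rejection_rate`,
#'   `rejection_se` and `seed`. [tidy()] and [glance()] methods are
#'   available.
#' @examples
#' empirical_power(scenario(n_case = 500, n_control = 500),
#'                 replicates = 200, seed = 7)
#' @export
empirical_power <- function(data, replicates = 5000, seed = 1,
                            test = c("interaction", "single_site"),
                            controls = c("mixture", "interaction"),
                            detail_file = NULL) {
  test <- rlang::arg_match(test)
  if (replicates < 100) {
    abort("replicates must be at least 100",
          class = "epipower_error_invalid_parameter")
  }
  tables <- sample_marker_tables(data, replicates = replicates, seed = seed,
                                 controls = controls)
  detail <- NULL
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    tab <- tables[tables$scenario == i, ]
    if (test == "interaction") {
      res <- interaction_test(tab, on_degenerate = "na")
      stat <- res$statistic
      beta <- res$beta_hat
    } else {
      stat <- single_site_stat(tab)
      beta <- NULL
    }
    alpha <- data$alpha[i]
    crit <- qchisq(1 - alpha, df = 1)
    reject <- !is.na(stat) & stat > crit
    n_deg <- sum(is.na(stat))
    if (n_deg > 0.01 * replicates) {
      warn(paste0("scenario ", i, ": ", n_deg, " of ", replicates,
                  " replicates produced degenerate tables"))
    }
    if (!is.null(detail_file)) {
      detail <<- dplyr::bind_rows(detail, tibble(
        scenario = i, replicate = seq_len(replicates),
        beta_hat = if (is.null(beta)) NA_real_ else beta,
        statistic = stat, reject = reject))
    }
    rate <- mean(reject)
    tibble(test = test, replicates = replicates, n_degenerate = n_deg,
           rejection_rate = rate,
           rejection_se = sqrt(rate * (1 - rate) / replicates),
           seed = seed)
  })
  if (!is.null(detail_file)) {
    utils::write.table(detail, detail_file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  new_epi_simulation(dplyr::bind_cols(data, dplyr::bind_rows(rows)),
                     replicates, seed, test)
}

#' Empirical moments of the effect-size estimator
#'
#' Samples tables and reports the Monte Carlo mean and variance of the
#' plug-in effect size `beta_hat`, with their Monte Carlo standard errors
#' (`beta_mean_se = sd / sqrt(R)`; `beta_var_se = var * sqrt(2 / (R - 1))`,
#' exact under approximate normality of `beta_hat`).
#'
#' @inheritParams empirical_power
#' @return A tibble (class `epi_simulation`) with the scenario columns
#'   plus `replicates`, `beta_mean`, `beta_mean_se`, `beta_var`,
#'   `beta_var_se` and `seed`.
#' @examples
#' empirical_beta_moments(scenario(n_case = 500, n_control = 500),
#'                        replicates = 1000, seed = 7)
#' @export
empirical_beta_moments <- function(data, replicates = 20000, seed = 1,
                                   controls = c("mixture", "interaction")) {
  if (replicates < 1000) {
    abort("replicates must be at least 1000",
          class = "epipower_error_invalid_parameter")
  }
  tables <- sample_marker_tables(data, replicates = replicates, seed = seed,
                                 controls = controls)
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    tab <- tables[tables$scenario == i, ]
    pl <- plugin_beta_var(tab)
    b <- pl$beta
    tibble(replicates = replicates,
           beta_mean = mean(b),
           beta_mean_se = stats::sd(b) / sqrt(replicates),
           beta_var = var(b),
           beta_var_se = var(b) * sqrt(2 / (replicates - 1)),
           seed = seed)
  })
  new_epi_simulation(dplyr::bind_cols(data, dplyr::bind_rows(rows)),
                     replicates, seed, "moments")
}

#' @method tidy epi_simulation
#' @export
tidy.epi_simulation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "epi_simulation")
  as_tibble(out)
}

#' @method glance epi_simulation
#' @export
glance.epi_simulation <- function(x, ...) {
  tibble(
    n_scenarios = nrow(x),
    replicates = attr(x, "replicates"),
    seed = attr(x, "seed"),
    test = attr(x, "test"),
    mean_rejection_rate = if ("rejection_rate" %in% names(x)) {
      mean(x$rejection_rate)
    } else {
      NA_real_
    }
  )
}
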