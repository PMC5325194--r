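#' Replicate cohort simulations with savings summaries
#'
#' The central entry point: runs `r` independent paired cohorts (replicate
#' `j` uses seed `base_seed + j - 1`), evaluates every scenario on each
#' cohort, and summarises per-scenario cohort totals and savings fractions
#' as mean +/- SEM across replicates (SEM = sample SD with `n - 1`
#' denominator divided by `sqrt(r)`).
#'
#' Savings are computed *within* each replicate against the reference
#' scenario (the initial-only policy if one is present, else the first
#' scenario) and then summarised across replicates, matching how a small
#' number of repetitions is typically reported.
#'
#' @param n Patients per cohort.
#' @param scenarios Named list of [titration_policy()] objects; defaults to
#'   [default_scenarios()] (I = no titration, II = 24 h, III = 3 min).
#' @param dists A [cohort_distributions()] object.
#' @param r Number of replicates (>= 2, so the SEM is defined).
#' @param base_seed Integer; replicate `j` is seeded with `base_seed + j - 1`.
#' @return An object of class `titration_study`; see Details.
#'
#' @details The returned object contains `totals` (an `r` x scenario matrix
#' of cohort totals in liters), `savings` (an `r` x scenario matrix of
#' per-replicate savings fractions vs the reference), their `mean_totals`,
#' `sem_totals`, `mean_savings`, `sem_savings` summaries, the `reference`
#' scenario label, the per-replicate `cohorts`, and the run parameters
#' (`n`, `r`, `base_seed`, `dists`, `scenarios`). Methods: `print`,
#' `summary`, `plot` (cumulative usage by patient, one line per scenario),
#' `as.data.frame` (one row per scenario, the results-table layout).
#'
#' @examples
#' study <- run_replicates(n = 100, r = 3, base_seed = 1)
#' study
#' as.data.frame(study)
#' @export
run_replicates <- function(n, scenarios = default_scenarios(),
                           dists = cohort_distributions(), r = 3,
                           base_seed = 1) {
  if (length(r) != 1 || r < 2) {
    stop("'r' must be >= 2 (the SEM is undefined for a single replicate)",
         call. = FALSE)
  }
  r <- as.integer(r)
  scenarios <- as_scenario_list(scenarios)
  seeds <- as.integer(base_seed) + seq_len(r) - 1L
  cohorts <- lapply(seeds, function(s) run_cohort(n, scenarios, dists, seed = s))

  totals <- do.call(rbind, lapply(cohorts, `[[`, "totals"))
  rownames(totals) <- paste0("replicate", seq_len(r))

  kinds <- vapply(scenarios, `[[`, character(1), "kind")
  ref <- if (any(kinds == "initial-only")) {
    names(scenarios)[which(kinds == "initial-only")[1]]
  } else {
    names(scenarios)[1]
  }
  savings <- apply(totals, 2, function(col) savings_fraction(totals[, ref], col))
  if (is.null(dim(savings))) savings <- matrix(savings, nrow = r,
                                               dimnames = dimnames(totals))

  sem <- function(x) stats::sd(x) / sqrt(length(x))
  structure(
    list(
      n = n, r = r, base_seed = base_seed, seeds = seeds,
      dists = dists, scenarios = scenarios, reference = ref,
      totals = totals,
      savings = savings,
      mean_totals = colMeans(totals),
      sem_totals = apply(totals, 2, sem),
      mean_savings = colMeans(savings),
      sem_savings = apply(savings, 2, sem),
      cohorts = cohorts
    ),
    class = "titration_study"
  )
}

#' @export
print.titration_study <- function(x, ...) {
  cat(sprintf(
    "Titration study: %d patients x %d replicates (base seed %d), reference scenario %s\n",
    x$n, x$r, as.integer(x$base_seed), x$reference))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.titration_study <- function(object, ...) {
  x <- object
  cat(sprintf("Paired titration simulation: N = %d patients, R = %d replicates\n",
              x$n, x$r))
  cat(sprintf("Replicate seeds: %s\n", paste(x$seeds, collapse = ", ")))
  df <- as.data.frame(x)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  Scenario %-3s total %6.0f +/- %.0f kL",
                df$scenario[i], df$mean_total_liters[i] / 1000,
                df$sem_total_liters[i] / 1000))
    if (df$scenario[i] != x$reference) {
      cat(sprintf(";  savings %.1f%% +/- %.1f%% (%.0f kL saved, %.0f h at 1 L/min)",
                  100 * df$mean_savings_fraction[i],
                  100 * df$sem_savings_fraction[i],
                  df$saved_liters_vs_reference[i] / 1000,
                  df$equivalent_hours_at_1lpm[i]))
    } else {
      cat("  (reference)")
    }
    cat("\n")
  }
  invisible(df)
}

#' @export
as.data.frame.titration_study <- function(x, ...) {
  labs <- names(x$scenarios)
  saved <- x$mean_totals[x$reference] - x$mean_totals
  data.frame(
    scenario = labs,
    interval_minutes = vapply(x$scenarios, `[[`, numeric(1), "interval_minutes"),
    mean_total_liters = unname(x$mean_totals),
    sem_total_liters = unname(x$sem_totals),
    mean_savings_fraction = unname(x$mean_savings),
    sem_savings_fraction = unname(x$sem_savings),
    saved_liters_vs_reference = unname(saved),
    equivalent_hours_at_1lpm = unname(liters_to_hours_at_flow(saved, 1)),
    row.names = NULL
  )
}

#' Plot cumulative oxygen usage by patient
#'
#' Draws the cumulative cohort consumption against patient index (sampling
#' order) for each scenario of one replicate -- the visual analogue of the
#' study's cumulative-usage figure.
#'
#' @param x A `titration_study` object.
#' @param replicate Which replicate's cohort to draw (default 1).
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.titration_study <- function(x, replicate = 1, ...) {
  cum <- x$cohorts[[replicate]]$cumulative
  m <- do.call(cbind, cum) / 1000
  graphics::matplot(seq_len(nrow(m)), m, type = "l", lty = 1, lwd = 2,
                    col = seq_len(ncol(m)),
                    xlab = "Patient index (sampling order)",
                    ylab = "Cumulative oxygen used (kL)",
                    main = sprintf("Cumulative usage, replicate %d (N = %d)",
                                   replicate, x$n), ...)
  graphics::legend("topleft", legend = colnames(x$totals), lty = 1, lwd = 2,
                   col = seq_len(ncol(m)), bty = "n",
                   title = "Scenario")
  invisible(x)
}
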