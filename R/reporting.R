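#' Run configuration for the reporting commands
#'
#' Bundles everything a simulation run needs: seed, cohort size, replicate
#' count, scenario list, distribution overrides and output directory. The
#' seed and full configuration are embedded in every output file so a run
#' can be reproduced from its artifacts alone.
#'
#' @param seed Integer base seed (required; recorded in all outputs).
#' @param n_patients Patients per cohort (>= 1).
#' @param n_replicates Replicates (>= 2 for SEM reporting).
#' @param scenarios Either a named list of [titration_policy()] objects or a
#'   character/numeric vector of intervals where `"none"` (or `"D"`) means
#'   initial-only and a number is an interval in minutes, e.g.
#'   `c("none", "1440", "3")`. Default labels are I, II, III, ...
#' @param config Optional path to a YAML/JSON file of distribution
#'   overrides (see [read_cohort_config()]). Ignored when `dists` is given.
#' @param dists Optional [cohort_distributions()] object.
#' @param out_dir Directory for output files (created if missing).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_patients = 100, n_replicates = 3,
                       scenarios = c("none", "1440", "3"),
                       config = NULL, dists = NULL, out_dir = ".") {
  if (n_patients < 1) stop("'n_patients' must be >= 1", call. = FALSE)
  if (n_replicates < 2) {
    stop("'n_replicates' must be >= 2 for SEM reporting", call. = FALSE)
  }
  if (is.null(dists)) {
    dists <- if (is.null(config)) cohort_distributions() else read_cohort_config(config)
  }
  structure(
    list(
      seed = as.integer(seed),
      n_patients = as.integer(n_patients),
      n_replicates = as.integer(n_replicates),
      scenarios = parse_scenarios(scenarios),
      dists = dists,
      out_dir = out_dir
    ),
    class = "run_config"
  )
}

#' Parse a scenario specification
#'
#' Turns `c("none", "1440", "3")`-style vectors into labelled
#' [titration_policy()] objects (`"none"`/`"D"` = initial-only, `"0"` =
#' continuous, a number = interval in minutes). Lists of policies pass
#' through [as_scenario_list()] validation unchanged.
#'
#' @param scenarios Character/numeric vector or list of policies.
#' @return Named list of `titration_policy` objects.
#' @export
parse_scenarios <- function(scenarios) {
  if (is.list(scenarios)) return(as_scenario_list(scenarios))
  if (length(scenarios) == 0) stop("'scenarios' must be non-empty", call. = FALSE)
  labels <- if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    as.character(utils::as.roman(seq_along(scenarios)))
  } else {
    names(scenarios)
  }
  pol <- lapply(seq_along(scenarios), function(i) {
    s <- tolower(as.character(scenarios[[i]]))
    if (s %in% c("none", "d", "initial-only", "na")) {
      titration_policy(NULL, label = labels[i])
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse scenario spec: ", s, call. = FALSE)
      titration_policy(v, label = labels[i])
    }
  })
  as_scenario_list(pol)
}

config_record <- function(config) {
  list(
    seed = config$seed,
    n_patients = config$n_patients,
    n_replicates = config$n_replicates,
    scenarios = lapply(config$scenarios, function(p) {
      list(label = p$label, kind = p$kind,
           interval_minutes = p$interval_minutes)
    }),
    distributions = unclass(config$dists),
    package_version = as.character(utils::packageVersion("oxytitrate"))
  )
}

#' Simulate and write result files
#'
#' Runs the replicate study described by a [run_config()] and writes three
#' artifacts to `out_dir`: `results.csv` (one row per scenario: mean total,
#' SEM, savings mean/SEM, liters saved vs reference and the 1 L/min-hour
#' equivalent), `cumulative.csv` (cumulative cohort usage by patient index,
#' per scenario and replicate) and `summary.json` (the results table plus
#' the seed, full configuration and per-replicate totals). Values are
#' rounded only at serialisation.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `study` and the three file
#'   paths.
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- run_replicates(
    n = config$n_patients, scenarios = config$scenarios,
    dists = config$dists, r = config$n_replicates,
    base_seed = config$seed
  )

  results <- cbind(seed = config$seed, as.data.frame(study))
  results_path <- file.path(config$out_dir, "results.csv")
  utils::write.csv(results, results_path, row.names = FALSE, quote = FALSE)

  cum <- do.call(rbind, lapply(seq_len(study$r), function(j) {
    co <- study$cohorts[[j]]
    do.call(rbind, lapply(names(co$cumulative), function(lab) {
      data.frame(
        replicate = j,
        patient_index = seq_len(co$n),
        scenario_label = lab,
        cumulative_liters = co$cumulative[[lab]]
      )
    }))
  }))
  cumulative_path <- file.path(config$out_dir, "cumulative.csv")
  utils::write.csv(cum, cumulative_path, row.names = FALSE, quote = FALSE)

  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(
    list(
      config = config_record(config),
      replicate_totals_liters = as.data.frame(study$totals),
      results = as.data.frame(study)
    ),
    summary_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )

  message(sprintf("seed %d: %d patients x %d replicates -> %s",
                  config$seed, config$n_patients, config$n_replicates,
                  config$out_dir))
  invisible(list(study = study, results_csv = results_path,
                 cumulative_csv = cumulative_path, summary_json = summary_path))
}

#' Write the exact-expectation oracle report
#'
#' For each configured scenario, computes the enumeration oracle
#' ([expected_patient_consumption()]) and the predicted replicate SEM for
#' the configured `(n_patients, n_replicates)`, and writes a single JSON
#' report.
#'
#' @param config A [run_config()].
#' @param out_file Output JSON path; defaults to `expectation.json` in the
#'   config's `out_dir`.
#' @return Invisibly, the report list.
#' @export
cmd_expect <- function(config,
                       out_file = file.path(config$out_dir, "expectation.json")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(dirname(out_file), showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(config$scenarios, function(p) {
    e <- expected_patient_consumption(config$dists, p)
    list(
      label = p$label, kind = p$kind, interval_minutes = p$interval_minutes,
      expected_volume_liters = e$expected_volume,
      variance_liters2 = e$variance,
      expected_savings_vs_initial_only = e$expected_savings,
      predicted_replicate_sem_liters = sqrt(
        config$n_patients * e$variance / config$n_replicates)
    )
  })
  out <- list(config = config_record(config), scenarios = reports)
  jsonlite::write_json(out, out_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
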