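#' Sample a synthetic patient cohort
#'
#' Draws `n` independent patients from the cohort distributions. Starting
#' flow, duration and profile are mutually independent; draws are consumed
#' from the generator in a fixed documented order (all `v0`, then all
#' durations, then all profiles) so that a cohort is fully reproducible
#' from its seed.
#'
#' @param n Number of patients (>= 1).
#' @param dists A [cohort_distributions()] object.
#' @param seed Optional integer seed. When supplied, sampling runs under a
#'   local RNG state (the caller's `.Random.seed` is restored afterwards).
#' @return A data frame with columns `id`, `v0` (L/min), `duration_days`,
#'   `profile` (`"A"`/`"B"`).
#'
#' @examples
#' head(sample_cohort(5, cohort_distributions(), seed = 1))
#' @export
sample_cohort <- function(n, dists = cohort_distributions(), seed = NULL) {
  if (length(n) != 1 || n < 1) stop("'n' must be a single integer >= 1", call. = FALSE)
  n <- as.integer(n)
  with_local_seed(seed, {
    data.frame(
      id = seq_len(n),
      v0 = draw_from(dists$v0_support, n, dists$v0_probs),
      duration_days = draw_from(dists$duration_support, n, dists$duration_probs),
      profile = draw_from(c("A", "B"), n, dists$profile_probs),
      stringsAsFactors = FALSE
    )
  })
}

# Index-based draw so length-1 supports are not misread as 1:x by sample().
draw_from <- function(support, n, probs) {
  support[sample.int(length(support), n, replace = TRUE, prob = probs)]
}

# Evaluate code under set.seed(seed) without clobbering the caller's RNG
# stream; a NULL seed uses (and advances) the current stream.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Run one paired multi-scenario cohort
#'
#' Samples a single cohort of `n` patients and evaluates **every** scenario
#' on that same cohort (common random numbers), so that scenario differences
#' reflect the titration policy alone and not sampling noise. Scenario
#' evaluation consumes no randomness.
#'
#' @param n Number of patients.
#' @param scenarios A named list of [titration_policy()] objects (labels
#'   must be unique); defaults to [default_scenarios()].
#' @param dists A [cohort_distributions()] object.
#' @param seed Integer seed for cohort sampling (recorded in the result).
#' @return An object of class `titration_cohort`: a list with `seed`, `n`,
#'   `patients` (the sampled cohort), `totals` (named vector of per-scenario
#'   cohort totals, liters), `records` (long data frame `patient_id`,
#'   `scenario`, `interval_minutes`, `volume_liters`) and `cumulative`
#'   (per-scenario cumulative-by-patient series, liters, in sampling order).
#'
#' @examples
#' res <- run_cohort(100, seed = 1)
#' res$totals / 1000  # cohort totals in kL for scenarios I, II, III
#' @export
run_cohort <- function(n, scenarios = default_scenarios(),
                       dists = cohort_distributions(), seed = NULL) {
  scenarios <- as_scenario_list(scenarios)
  patients <- sample_cohort(n, dists, seed)
  vols <- lapply(scenarios, function(p) consumed_volume(patients, p, dists$k))
  records <- do.call(rbind, lapply(names(scenarios), function(lab) {
    data.frame(
      patient_id = patients$id,
      scenario = lab,
      interval_minutes = scenarios[[lab]]$interval_minutes,
      volume_liters = vols[[lab]],
      stringsAsFactors = FALSE
    )
  }))
  structure(
    list(
      seed = seed,
      n = n,
      dists = dists,
      scenarios = scenarios,
      patients = patients,
      totals = vapply(vols, sum, numeric(1)),
      records = records,
      cumulative = lapply(vols, cumsum)
    ),
    class = "titration_cohort"
  )
}

#' @export
print.titration_cohort <- function(x, ...) {
  cat("Paired titration cohort: ", x$n, " patients",
      if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed), "\n", sep = "")
  tot <- data.frame(
    scenario = names(x$totals),
    total_kL = round(x$totals / 1000, 1)
  )
  print(tot, row.names = FALSE)
  invisible(x)
}

#' Oxygen savings fraction
#'
#' The fraction of oxygen saved by a titration policy relative to the
#' no-titration reference: `1 - total_policy / total_ref`. With the default
#' non-increasing profiles this lies in `[0, 1)`; a policy total exceeding
#' the reference signals an increasing profile, which the model does not
#' support, and raises an error.
#'
#' @param total_ref Reference (no-titration) cohort total, liters; > 0.
#' @param total_policy Cohort total under the titration policy, liters.
#' @return Savings as a fraction in `[0, 1)`.
#' @examples
#' savings_fraction(374000, 344000)  # 0.0802
#' @export
savings_fraction <- function(total_ref, total_policy) {
  if (any(total_ref <= 0)) stop("'total_ref' must be positive", call. = FALSE)
  if (any(total_policy > total_ref * (1 + 1e-12))) {
    stop("'total_policy' exceeds 'total_ref': profiles that increase oxygen need are not supported",
         call. = FALSE)
  }
  pmax(1 - total_policy / total_ref, 0)
}

#' Convert an oxygen volume to hours of delivery at a standard flow
#'
#' Expresses a saved (or used) volume as the equivalent duration of therapy
#' at a standard flow rate, e.g. 30 kL at 1 L/min is 500 hours.
#'
#' @param volume Volume in liters.
#' @param flow Flow rate in L/min; must be positive.
#' @return Hours of delivery.
#' @examples
#' liters_to_hours_at_flow(30000, 1)  # 500
#' @export
liters_to_hours_at_flow <- function(volume, flow = 1) {
  if (any(flow <= 0)) stop("'flow' must be positive", call. = FALSE)
  volume / flow / 60
}

#' Export a sampled cohort as CSV
#'
#' Writes the cohort table with columns `id`, `v0_lpm`, `duration_days`,
#' `profile`.
#'
#' @param patients Cohort data frame from [sample_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(patients, path) {
  patients <- as_patient_frame(patients)
  out <- data.frame(
    id = patients$id,
    v0_lpm = patients$v0,
    duration_days = patients$duration_days,
    profile = patients$profile
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
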