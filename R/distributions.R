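#' Cohort sampling distributions
#'
#' Constructs (and validates) the discrete sampling laws that define a
#' synthetic cohort of hypoxemic-pneumonia patients on oxygen therapy:
#' the starting flow rate `v0`, the treatment duration `D`, the weaning
#' profile (A or B), and the weaning rate `k`.
#'
#' The defaults encode the study conditions: `v0` is uniform on
#' \{0.5, 1.0, 2.0\} L/min (WHO starting rates for infants and children),
#' duration is 1--5 days with probabilities \{0.32, 0.27, 0.18, 0.12, 0.11\}
#' (derived from clinical duration-of-therapy data), the two weaning
#' profiles are equiprobable, and `k = 0.125` L/min/day.
#'
#' The invariant `k * 3 < min(v0_support)` guarantees that every profile
#' stays strictly positive over the 5-day horizon (the longest declining
#' span in either profile is 3 days).
#'
#' @param v0_support Numeric vector of possible starting flow rates (L/min).
#' @param v0_probs Probabilities for `v0_support`; must sum to 1.
#' @param duration_support Integer vector of possible treatment durations
#'   (days), each >= 1.
#' @param duration_probs Probabilities for `duration_support`; must sum to 1.
#' @param profile_probs Length-2 probabilities for profiles A and B.
#' @param k Weaning rate in L/min per day; must satisfy
#'   `3 * k < min(v0_support)`.
#'
#' @return An object of class `cohort_distributions`: a list with the six
#'   fields above.
#'
#' @examples
#' d <- cohort_distributions()
#' d$k                      # 0.125 L/min/day
#' sum(d$duration_probs)    # 1
#'
#' @seealso [read_cohort_config()] to build one from a YAML/JSON file,
#'   [sample_cohort()] to draw patients from it.
#' @export
cohort_distributions <- function(v0_support = c(0.5, 1.0, 2.0),
                                 v0_probs = rep(1 / 3, 3),
                                 duration_support = 1:5,
                                 duration_probs = c(0.32, 0.27, 0.18, 0.12, 0.11),
                                 profile_probs = c(0.5, 0.5),
                                 k = 0.125) {
  d <- structure(
    list(
      v0_support = as.numeric(v0_support),
      v0_probs = as.numeric(v0_probs),
      duration_support = as.integer(duration_support),
      duration_probs = as.numeric(duration_probs),
      profile_probs = as.numeric(profile_probs),
      k = as.numeric(k)
    ),
    class = "cohort_distributions"
  )
  validate_cohort_distributions(d)
}

validate_cohort_distributions <- function(d) {
  check_probs <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0)) {
      stop(sprintf("'%s' must be non-negative and finite", what), call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-12) {
      stop(sprintf("'%s' must sum to 1 (got %.15g)", what, sum(p)), call. = FALSE)
    }
  }
  if (length(d$v0_support) != length(d$v0_probs)) {
    stop("'v0_support' and 'v0_probs' must have equal length", call. = FALSE)
  }
  if (length(d$duration_support) != length(d$duration_probs)) {
    stop("'duration_support' and 'duration_probs' must have equal length",
         call. = FALSE)
  }
  if (length(d$profile_probs) != 2) {
    stop("'profile_probs' must have length 2 (profiles A and B)", call. = FALSE)
  }
  check_probs(d$v0_probs, "v0_probs")
  check_probs(d$duration_probs, "duration_probs")
  check_probs(d$profile_probs, "profile_probs")
  if (any(d$v0_support <= 0)) {
    stop("'v0_support' flow rates must be positive", call. = FALSE)
  }
  if (any(d$duration_support < 1)) {
    stop("'duration_support' values must be integers >= 1", call. = FALSE)
  }
  if (!is.finite(d$k) || d$k < 0) {
    stop("'k' must be a non-negative weaning rate (L/min/day)", call. = FALSE)
  }
  # longest declining span in either profile is 3 days
  if (d$k * 3 >= min(d$v0_support)) {
    stop(sprintf(
      "weaning over 3 days (3*k = %.4g L/min) must stay below the smallest starting flow (%.4g L/min) so flows remain positive",
      d$k * 3, min(d$v0_support)
    ), call. = FALSE)
  }
  d
}

#' @export
print.cohort_distributions <- function(x, ...) {
  cat("Cohort sampling distributions\n")
  cat("  starting flow v0 (L/min): ",
      paste(sprintf("%g (p=%.3g)", x$v0_support, x$v0_probs), collapse = ", "),
      "\n", sep = "")
  cat("  duration D (days):        ",
      paste(sprintf("%d (p=%.3g)", x$duration_support, x$duration_probs),
            collapse = ", "), "\n", sep = "")
  cat("  profile A/B probs:        ",
      paste(sprintf("%.3g", x$profile_probs), collapse = ", "), "\n", sep = "")
  cat("  weaning rate k:           ", x$k, " L/min/day\n", sep = "")
  invisible(x)
}

#' Read cohort distributions from a config file
#'
#' Reads a small key--value configuration file (YAML or JSON) overriding any
#' subset of the default cohort distributions. Recognised keys:
#' `v0_support`, `v0_probs`, `duration_support`, `duration_probs`,
#' `profile_probs`, `k`. Unknown keys raise an error listing the offenders;
#' omitted keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [cohort_distributions()] object.
#'
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines("k: 0", cfg)
#' read_cohort_config(cfg)$k   # 0: weaning disabled
#'
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  allowed <- c("v0_support", "v0_probs", "duration_support",
               "duration_probs", "profile_probs", "k")
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) {
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(cohort_distributions, raw)
}
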