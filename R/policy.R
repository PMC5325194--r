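#' Titration policy
#'
#' A titration policy says how often a patient's delivered flow is re-set to
#' the profile value. Three kinds are supported:
#'
#' * **initial-only** (`interval_minutes = NULL`): the starting flow `v0` is
#'   held for the entire treatment -- no routine titration. This is the
#'   study reference scenario.
#' * **periodic** (`interval_minutes > 0`): a zero-order hold -- at each
#'   titration instant (starting at t = 0) the flow is re-set to the profile
#'   value and held constant until the next instant.
#' * **continuous** (`interval_minutes = 0`): the idealised limit of the
#'   interval going to zero; consumption is the exact integral of the
#'   profile.
#'
#' @param interval_minutes `NULL` for initial-only, `0` for the continuous
#'   limit, or a positive number of minutes between titrations.
#' @param label Optional scenario label (e.g. `"I"`, `"II"`, `"III"`);
#'   defaults to a description of the policy.
#' @return An object of class `titration_policy` with fields `kind`,
#'   `interval_minutes` (NA unless periodic) and `label`.
#'
#' @examples
#' titration_policy()          # initial-only (no routine titration)
#' titration_policy(1440)      # once daily
#' titration_policy(3)         # every 3 minutes (automated system)
#' @export
titration_policy <- function(interval_minutes = NULL, label = NULL) {
  if (is.null(interval_minutes)) {
    kind <- "initial-only"
    interval <- NA_real_
  } else {
    interval <- as.numeric(interval_minutes)
    if (length(interval) != 1 || !is.finite(interval) || interval < 0) {
      stop("'interval_minutes' must be a single non-negative number or NULL",
           call. = FALSE)
    }
    kind <- if (interval == 0) "continuous" else "periodic"
    if (kind == "continuous") interval <- NA_real_
  }
  if (is.null(label)) {
    label <- switch(kind,
      "initial-only" = "initial-only",
      "continuous" = "continuous",
      "periodic" = sprintf("every %g min", interval)
    )
  }
  structure(
    list(kind = kind, interval_minutes = interval, label = label),
    class = "titration_policy"
  )
}

#' @export
print.titration_policy <- function(x, ...) {
  cat("Titration policy [", x$label, "]: ", x$kind, sep = "")
  if (x$kind == "periodic") cat(" (interval ", x$interval_minutes, " min)", sep = "")
  cat("\n")
  invisible(x)
}

#' Default study scenarios
#'
#' The three titration scenarios evaluated by the study: Scenario I holds
#' the starting rate for the full treatment (the reference), Scenario II
#' titrates every 24 hours (once-daily manual titration), Scenario III
#' every 3 minutes (automated closed-loop titration).
#'
#' @return Named list of three [titration_policy()] objects labelled
#'   `I`, `II`, `III`.
#' @examples
#' default_scenarios()
#' @export
default_scenarios <- function() {
  list(
    I = titration_policy(NULL, label = "I"),
    II = titration_policy(1440, label = "II"),
    III = titration_policy(3, label = "III")
  )
}

# Coerce a user-supplied scenario spec (policy list, possibly unlabelled)
# into a validated named list of titration_policy objects.
as_scenario_list <- function(scenarios) {
  if (inherits(scenarios, "titration_policy")) scenarios <- list(scenarios)
  if (!is.list(scenarios) || length(scenarios) == 0) {
    stop("'scenarios' must be a non-empty list of titration policies",
         call. = FALSE)
  }
  scenarios <- lapply(scenarios, function(s) {
    if (!inherits(s, "titration_policy")) {
      stop("each scenario must be a 'titration_policy' object", call. = FALSE)
    }
    s
  })
  labels <- vapply(scenarios, `[[`, character(1), "label")
  if (anyDuplicated(labels)) {
    stop("scenario labels must be unique within a run", call. = FALSE)
  }
  names(scenarios) <- labels
  scenarios
}
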