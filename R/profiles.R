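#' Oxygen-need profile flow rate at time t
#'
#' Evaluates the piecewise-linear weaning profiles that describe a patient's
#' oxygen flow-rate need over the course of therapy. Both profiles start at
#' `v0` and decline at the weaning rate `k` over part of the 5-day horizon:
#'
#' * **Profile A** declines immediately: `v0 - k*t` for `0 <= t < 3`, then
#'   plateaus at `v0 - 3k` for `t >= 3`.
#' * **Profile B** holds `v0` for the first day, declines as `v0 - k*(t - 1)`
#'   for `1 <= t < 3`, then plateaus at `v0 - 2k` for `t >= 3`.
#'
#' Equivalently, `flow = v0 - k * w(t)` with weaned amount
#' `w_A(t) = min(t, 3)` and `w_B(t) = min(max(t - 1, 0), 2)`. Flows are
#' continuous, non-increasing, and strictly positive whenever
#' `3k < v0` (guaranteed by the [cohort_distributions()] invariant).
#'
#' Arguments are recycled to a common length, so the function is vectorised
#' over patients as well as over time.
#'
#' @param profile_id Character vector of profile labels, `"A"` or `"B"`.
#' @param v0 Starting flow rate(s), L/min.
#' @param k Weaning rate, L/min per day.
#' @param t Time(s) since start of therapy, in days; must be >= 0.
#' @return Flow rate(s) in L/min.
#'
#' @examples
#' flow_at("A", v0 = 1, k = 0.125, t = 0:4)  # 1.000 0.875 0.750 0.625 0.625
#' flow_at("B", v0 = 2, k = 0.125, t = 0.5)  # 2: profile B holds v0 on day 1
#' @export
flow_at <- function(profile_id, v0, k, t) {
  if (any(t < 0)) {
    stop("'t' must be non-negative (days since start of therapy)",
         call. = FALSE)
  }
  n <- max(length(profile_id), length(v0), length(t))
  profile_id <- rep_len(as.character(profile_id), n)
  v0 <- rep_len(v0, n)
  t <- rep_len(t, n)
  if (!all(profile_id %in% c("A", "B"))) {
    stop("'profile_id' must be \"A\" or \"B\"", call. = FALSE)
  }
  v0 - k * weaned_amount(profile_id, t)
}

# Cumulative weaned flow w(t) in L/min such that flow = v0 - k * w(t).
weaned_amount <- function(profile_id, t) {
  ifelse(profile_id == "A", pmin(t, 3), pmin(pmax(t - 1, 0), 2))
}

# Integral of w(t) over [0, t] in L/min * day; closed form of the piecewise
# ramps, used by continuous_consumption().
weaned_amount_integral <- function(profile_id, t) {
  a <- ifelse(t <= 3, t^2 / 2, 4.5 + 3 * (t - 3))
  tb <- pmin(pmax(t - 1, 0), 2)
  b <- tb^2 / 2 + 2 * pmax(t - 3, 0)
  ifelse(profile_id == "A", a, b)
}
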