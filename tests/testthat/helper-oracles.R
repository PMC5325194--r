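# Independent reference implementations used as oracles. These are written
# directly from the piecewise profile definitions as scalar functions and
# plain loops, deliberately sharing no code with the package internals.

ref_flow <- function(profile, v0, k, t) {
  if (profile == "A") {
    if (t < 3) v0 - k * t else v0 - 3 * k
  } else {
    if (t < 1) v0 else if (t < 3) v0 - k * (t - 1) else v0 - 2 * k
  }
}

# exact integral of the profile over [0, D] days via adaptive quadrature
ref_continuous <- function(profile, v0, D, k) {
  f <- Vectorize(function(t) ref_flow(profile, v0, k, t))
  # integrate each day separately so the kinks at t = 1, 3 are respected
  pieces <- vapply(seq_len(D), function(d) {
    stats::integrate(f, d - 1, d, rel.tol = 1e-12)$value
  }, numeric(1))
  1440 * sum(pieces)
}

# zero-order-hold sum as an explicit loop over titration steps
ref_zoh <- function(profile, v0, D, k, dt_min) {
  total_min <- D * 1440
  t <- 0
  vol <- 0
  while (t < total_min) {
    len <- min(dt_min, total_min - t)
    vol <- vol + ref_flow(profile, v0, k, t / 1440) * len
    t <- t + dt_min
  }
  vol
}

# full default parameter grid (30 combinations) with joint probabilities
default_grid <- function() {
  g <- expand.grid(v0 = c(0.5, 1.0, 2.0), D = 1:5, profile = c("A", "B"),
                   stringsAsFactors = FALSE)
  pD <- c(0.32, 0.27, 0.18, 0.12, 0.11)
  g$prob <- (1 / 3) * pD[g$D] * 0.5
  g
}

# exact expectation of an arbitrary per-patient volume function over the grid
ref_expectation <- function(volume_fn) {
  g <- default_grid()
  vols <- mapply(volume_fn, g$profile, g$v0, g$D)
  c(mean = sum(g$prob * vols), second = sum(g$prob * vols^2))
}
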