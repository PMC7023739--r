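# Shared fixtures: point-mass distribution sets and per-woman service
# matrices for deterministic schedule checks.

TABLE_MEANS <- c(check_in = 0.457, connect_ctg = 3.410, ctg_scan = 26.250,
                 disconnect_ctg = 3.410, consultation = 22.325,
                 check_out = 1.589)
ZERO_CONTENTION_LOS <- sum(TABLE_MEANS)  # 57.441

point_dist <- function(value, activity = "fixed") {
  fit_bounded_service_distribution(list(
    activity = activity, min = value, median = value, mean = value,
    max = value, sd = 0, kurtosis = 0, skewness = 0
  ))
}

# point-mass distribution set at the elicited activity means, check count
# fixed at `checks`
point_mass_dists <- function(checks = 2) {
  out <- lapply(names(TABLE_MEANS), function(k) point_dist(TABLE_MEANS[[k]], k))
  names(out) <- names(TABLE_MEANS)
  out$n_ctg_checks <- point_dist(checks, "n_ctg_checks")
  out
}

# per-woman service matrix: the activity means plus distinct small offsets,
# so no two task completions ever coincide
jittered_services <- function(n, scale = 0.011) {
  base <- matrix(rep(TABLE_MEANS, each = n), nrow = n)
  base + matrix(seq_len(n * 6), nrow = n) * scale
}

ample_config <- function(arrivals, ...) {
  clinic_config(arrivals = arrivals, midwives = arrivals,
                doctors = arrivals, ctg_machines = arrivals,
                reception_staff = arrivals, ...)
}

fitted_dists <- fit_service_distributions()
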