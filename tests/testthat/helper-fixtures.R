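# shared helpers: independent detection oracle and random-series generator

# brute-force HA detection over all measurement pairs (s, t) with
# t - s <= window and t <= horizon, plus the ratio-to-admission rule;
# intentionally naive and independent of the package implementation
oracle_detect <- function(hours, value, ratio = 1.5, rise = 26.5,
                          window = 48, horizon = 168) {
  v0 <- value[1]
  onset <- Inf
  for (j in seq_along(hours)) {
    if (hours[j] > horizon) next
    fired <- value[j] / v0 >= ratio
    if (!fired) {
      for (k in seq_along(hours)) {
        if (hours[k] <= hours[j] && hours[k] >= hours[j] - window &&
            value[j] - value[k] >= rise) {
          fired <- TRUE
          break
        }
      }
    }
    if (fired) onset <- min(onset, hours[j])
  }
  if (is.finite(onset)) onset else NA_real_
}

random_series <- function() {
  n <- sample(2:12, 1)
  hours <- c(0, sort(runif(n - 1, 0.5, 240)))
  value <- runif(n, 40, if (runif(1) < 0.5) 150 else 400)
  data.frame(hours = hours, scr_umol_l = value)
}

small_config <- function(seed = 11, ...) {
  sim_config(n_patients_per_cell = 300, seed = seed, ...)
}
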