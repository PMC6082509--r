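#' Configuration for the two-site, two-period cohort simulator
#'
#' Defaults encode the study conditions the package is designed around: two
#' acute medical units (an intervention and a control site) observed over a
#' pre and a post period, roughly 7,000-8,000 admissions per site-period
#' cell, community-acquired AKI prevalence near 8.3%, hospital-acquired AKI
#' incidence near 8.3% (intervention site) and 6.5% (control site) of at-risk
#' admissions, in-hospital mortality near 25% given HA-AKI, and a
#' configurable multiplicative odds effect applied only in the
#' intervention-site post period to HA-AKI incidence and to death given
#' HA-AKI.
#'
#' @param n_patients_per_cell Patients per site-period cell (each site draws
#'   `2 * n_patients_per_cell` patients whose admissions are split across
#'   periods, so expected admissions per cell is
#'   `n_patients_per_cell * mean_admissions_per_patient`).
#' @param mean_admissions_per_patient Mean admissions per patient (>= 1);
#'   counts are `1 + Poisson(mean - 1)`, so values above 1 create the
#'   patient-level clustering the clustered models account for.
#' @param ca_aki_prev Probability an eligible admission presents with CA-AKI.
#' @param ha_aki_base_rate Named vector `c(intervention =, control =)` of
#'   baseline HA-AKI probabilities among eligible non-CA admissions.
#' @param intervention_or_ha,intervention_or_mort Multiplicative odds effects
#'   (> 0) applied in the intervention-site post period to HA-AKI incidence
#'   and to in-hospital death given HA-AKI. Defaults are the unadjusted
#'   post/pre odds-ratio contrasts implied by the study tables
#'   (0.928/1.019 and 0.731/1.104).
#' @param mort_given_ha,mort_given_ca,mort_background In-hospital death
#'   probabilities given HA-AKI, given CA-AKI, and otherwise.
#' @param icu_given_ha,icu_background ICU escalation probabilities.
#' @param baseline_scr_missing_prob Probability a patient has no retrievable
#'   pre-admission creatinine history.
#' @param comorbidity_prevs Named probabilities for the six comorbidity flags.
#' @param age_mean_sd Length-2 numeric: mean and SD of age in years.
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters (days);
#'   defaults give mean ~11 days with a heavy right tail.
#' @param exclusion_frac Fraction of admissions planted to violate one
#'   inclusion rule (spread equally over the five exclusion reasons) so that
#'   cohort filtering is exercised.
#' @param stage_probs Length-3 probabilities of planted HA-AKI severity
#'   falling in the stage 1/2/3 ratio bands.
#' @param seed Integer seed; identical config and seed give identical cohorts.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_patients_per_cell = 6500,
                       mean_admissions_per_patient = 1.15,
                       ca_aki_prev = 0.083,
                       ha_aki_base_rate = c(intervention = 0.083, control = 0.065),
                       intervention_or_ha = 0.91,
                       intervention_or_mort = 0.66,
                       mort_given_ha = 0.25,
                       mort_given_ca = 0.21,
                       mort_background = 0.065,
                       icu_given_ha = 0.075,
                       icu_background = 0.02,
                       baseline_scr_missing_prob = 0.2,
                       comorbidity_prevs = c(ckd = 0.47, diabetes = 0.23,
                                             heart_failure = 0.24,
                                             liver_disease = 0.025,
                                             hypertension = 0.58,
                                             vascular_disease = 0.09),
                       age_mean_sd = c(74.5, 17),
                       los_meanlog = 1.96, los_sdlog = 0.94,
                       exclusion_frac = 0.04,
                       stage_probs = c(0.78, 0.15, 0.07),
                       seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$ca_aki_prev, cfg$ha_aki_base_rate, cfg$mort_given_ha,
             cfg$mort_given_ca, cfg$mort_background, cfg$icu_given_ha,
             cfg$icu_background, cfg$baseline_scr_missing_prob,
             cfg$comorbidity_prevs, cfg$exclusion_frac, cfg$stage_probs)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$intervention_or_ha <= 0 || cfg$intervention_or_mort <= 0) {
    stop("odds-effect parameters must be positive", call. = FALSE)
  }
  if (cfg$mean_admissions_per_patient < 1) {
    stop("mean_admissions_per_patient must be >= 1", call. = FALSE)
  }
  if (!all(c("intervention", "control") %in% names(cfg$ha_aki_base_rate))) {
    stop("ha_aki_base_rate needs named entries 'intervention' and 'control'",
         call. = FALSE)
  }
  cfg$n_patients_per_cell <- as.integer(cfg$n_patients_per_cell)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

.period_starts <- c(pre = "2014-06-01", post = "2015-06-01")
.period_days <- 304  # ten months

# flat noise band around the admission value: +/-12 umol/l can neither reach
# a 26.5 rise within any window nor a 1.5 ratio for values above 24 umol/l,
# so unplanted series can never trigger detection
.noise_band <- 12

#' Generate a synthetic two-site, two-period admission cohort
#'
#' Draws patients (with stable age, comorbidities and true baseline
#' creatinine), gives each one or more admissions split across the pre and
#' post periods, and plants community- and hospital-acquired AKI
#' trajectories so that creatinine-based ascertainment
#' ([classify_cohort()]) recovers exactly the planted events. A configured
#' fraction of admissions violates one inclusion rule each. All randomness
#' flows from `config$seed`; the caller's RNG state is restored on exit.
#'
#' Serum creatinine is sampled at admission and then roughly daily
#' (24 +/- 5 h jitter) up to eight days or discharge; unplanted values stay
#' within a +/-12 micromol/l band of the admission value, planted HA-AKI
#' trajectories stay flat until onset then rise to
#' `admission value * severity ratio` and plateau.
#'
#' @param config A [sim_config()].
#' @return Object of class `aki_cohort`: list with `admissions` (one row per
#'   admission, including planted ground-truth columns `planted_category`,
#'   `planted_onset_hours`, `planted_stage`), `scr` (long creatinine table:
#'   `admission_id`, `hours`, `scr_umol_l`), `baseline_history`
#'   (`admission_id`, `days_before`, `scr_umol_l`) and `config`.
#' @examples
#' coh <- generate_cohort(sim_config(n_patients_per_cell = 50, seed = 7))
#' nrow(coh$admissions)
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  parts <- lapply(c("intervention", "control"), .generate_site, config = config)
  adm <- data.table::rbindlist(lapply(parts, `[[`, "admissions"))
  scr <- data.table::rbindlist(lapply(parts, `[[`, "scr"))
  hist <- data.table::rbindlist(lapply(parts, `[[`, "baseline_history"))
  structure(list(admissions = adm, scr = scr, baseline_history = hist,
                 config = config),
            class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat("Synthetic admission cohort:", nrow(x$admissions), "admissions,",
      length(unique(x$admissions$patient_id)), "patients,",
      nrow(x$scr), "creatinine measurements\n")
  print(x$admissions[, table(site, period)])
  invisible(x)
}

.generate_site <- function(site, config) {
  n_pat <- 2L * config$n_patients_per_cell
  empty <- list(
    admissions = data.table::data.table(),
    scr = data.table::data.table(),
    baseline_history = data.table::data.table()
  )
  if (n_pat == 0L) return(empty)

  # ---- patient level ----------------------------------------------------
  n_adm_per_pat <- 1L + rpois(n_pat, config$mean_admissions_per_patient - 1)
  age_p <- pmin(pmax(rnorm(n_pat, config$age_mean_sd[1], config$age_mean_sd[2]),
                     18), 105)
  com <- vapply(config$comorbidity_prevs,
                function(p) runif(n_pat) < p,
                logical(n_pat))
  if (n_pat == 1L) com <- matrix(com, nrow = 1,
                                 dimnames = list(NULL, names(config$comorbidity_prevs)))
  base_scr_p <- pmin(pmax(rlnorm(n_pat, log(75), 0.28), 40), 250)
  base_missing_p <- runif(n_pat) < config$baseline_scr_missing_prob

  # ---- admission level --------------------------------------------------
  pat_idx <- rep(seq_len(n_pat), n_adm_per_pat)
  n_adm <- length(pat_idx)
  d <- data.table::data.table(
    patient_id = sprintf("%s_p%05d", substr(site, 1, 3), pat_idx),
    site = site,
    period = sample(c("pre", "post"), n_adm, replace = TRUE),
    age = age_p[pat_idx]
  )
  for (nm in colnames(com)) d[[nm]] <- com[pat_idx, nm]
  d$admission_id <- sprintf("%s_a%06d", substr(site, 1, 3), seq_len(n_adm))
  d$news <- pmin(rpois(n_adm, 1.8), 12L)
  d$resp_rate_ge20 <- runif(n_adm) < 0.23
  d$avpu_below_alert <- runif(n_adm) < 0.012
  d$specialty <- "medical"
  d$direct_ed_to_icu <- FALSE

  # planted exclusions (one reason each)
  reasons <- c("under18", "non_medical", "no_overnight", "single_scr",
               "direct_ed_icu")
  excl <- runif(n_adm) < config$exclusion_frac
  d$planted_exclusion <- ifelse(excl, sample(reasons, n_adm, replace = TRUE),
                                NA_character_)
  d$age[which(d$planted_exclusion == "under18")] <-
    runif(sum(d$planted_exclusion == "under18", na.rm = TRUE), 5, 17.5)
  d$specialty[which(d$planted_exclusion == "non_medical")] <- "non_medical"
  d$direct_ed_to_icu[which(d$planted_exclusion == "direct_ed_icu")] <- TRUE
  eligible <- is.na(d$planted_exclusion)

  # ---- event planting ---------------------------------------------------
  is_post_int <- d$site == "intervention" & d$period == "post"
  ca <- eligible & runif(n_adm) < config$ca_aki_prev
  p_ha <- plogis(qlogis(config$ha_aki_base_rate[[site]]) +
                   log(config$intervention_or_ha) * is_post_int)
  ha <- eligible & !ca & runif(n_adm) < p_ha

  p_die <- ifelse(ha, plogis(qlogis(config$mort_given_ha) +
                               log(config$intervention_or_mort) * is_post_int),
                  ifelse(ca, config$mort_given_ca, config$mort_background))
  died <- runif(n_adm) < p_die
  icu <- runif(n_adm) < ifelse(ha, config$icu_given_ha, config$icu_background)

  # ---- stay timing ------------------------------------------------------
  los <- rlnorm(n_adm, config$los_meanlog, config$los_sdlog)  # days
  los[eligible] <- pmax(los[eligible], 1.5)
  los[ha] <- pmax(los[ha], 2.5)
  no_night <- which(d$planted_exclusion == "no_overnight")
  los[no_night] <- runif(length(no_night), 0.05, 0.3)

  start <- as.POSIXct(.period_starts[d$period], tz = "UTC")
  adm_time <- start + runif(n_adm, 0, .period_days) * 86400
  # same-day discharges must not cross midnight
  adm_time[no_night] <- as.POSIXct(
    format(adm_time[no_night], "%Y-%m-%d"), tz = "UTC") + 8 * 3600

  onset <- rep(NA_real_, n_adm)
  onset[ha] <- runif(sum(ha), 12, pmin(168, los[ha] * 24 - 12))
  severity <- rep(NA_real_, n_adm)
  band <- sample.int(3L, sum(ha), replace = TRUE,
                     prob = config$stage_probs)
  severity[ha] <- c(1.5, 2, 3)[band] + runif(sum(ha), 0, c(0.5, 1, 1)[band])

  death_time <- rep(as.POSIXct(NA, tz = "UTC"), n_adm)
  if (any(died)) {
    lo <- ifelse(ha[died], onset[died] / 24 + 0.25, 0.2)
    at <- runif(sum(died), lo, pmax(los[died], lo + 0.2))
    death_time[died] <- adm_time[died] + at * 86400
  }
  discharge <- adm_time + los * 86400
  discharge[died] <- death_time[died]
  icu_time <- rep(as.POSIXct(NA, tz = "UTC"), n_adm)
  icu_time[icu] <- adm_time[icu] + runif(sum(icu), 0.1, pmax(los[icu] * 0.8, 0.2)) * 86400

  d$admission_time <- adm_time
  d$discharge_time <- discharge
  d$death_in_hospital <- died
  d$death_time <- death_time
  d$icu_escalation <- icu
  d$icu_time <- icu_time
  d$planted_category <- ifelse(ca, "CA", ifelse(ha, "HA", "none"))
  d$planted_category[!eligible] <- "none"
  d$planted_onset_hours <- onset
  stage_truth <- rep(0L, n_adm)
  stage_truth[ha] <- band            # severity drawn inside the stage band
  stage_truth[ca] <- NA_integer_     # CA stage depends on the derived baseline
  d$planted_stage <- stage_truth

  # ---- creatinine -------------------------------------------------------
  base_missing <- base_missing_p[pat_idx]
  base_true <- base_scr_p[pat_idx]
  v0 <- base_true * runif(n_adm, 0.85, 1.3)          # no AKI at admission
  v0[ca] <- ifelse(base_missing[ca],
                   runif(sum(ca), 360, 480),          # absolute-level CA
                   base_true[ca] * runif(sum(ca), 1.6, 3.2))

  series_end <- pmin(los * 24, 192)
  scr <- .make_series(d$admission_id, v0, series_end, onset, severity,
                      d$planted_category,
                      single = !is.na(d$planted_exclusion) &
                        d$planted_exclusion == "single_scr")

  # CA stage ground truth needs the derived baseline; filled by tests via
  # classify_cohort, so left NA above.

  # ---- baseline history -------------------------------------------------
  has_hist <- !base_missing
  idx <- which(has_hist)
  n_h <- sample(1:3, length(idx), replace = TRUE)
  hist <- data.table::data.table(
    admission_id = rep(d$admission_id[idx], n_h),
    days_before = runif(sum(n_h), 1, 300),
    scr_umol_l = rep(base_true[idx], n_h) * runif(sum(n_h), 0.95, 1.05)
  )

  data.table::setcolorder(d, c("admission_id", "patient_id", "site", "period"))
  list(admissions = d, scr = scr, baseline_history = hist)
}

# build the long creatinine table for all admissions at once
.make_series <- function(admission_id, v0, end_hours, onset, severity,
                         category, single) {
  n <- length(admission_id)
  n_days <- pmax(ceiling(end_hours / 24) - 1L, 1L)
  n_days[single] <- 0L
  reg_id <- rep(seq_len(n), n_days)
  reg_t <- 24 * unlist(lapply(n_days, seq_len), use.names = FALSE) +
    runif(length(reg_id), -5, 5)
  keep <- reg_t < rep(end_hours, n_days)[seq_along(reg_id)] &
    reg_t > 0
  # guarantee >= 2 measurements for multi-sample admissions: always keep the
  # first post-admission draw, clamped inside the stay
  first_of_adm <- !duplicated(reg_id)
  reg_t[first_of_adm] <- pmin(reg_t[first_of_adm],
                              rep(end_hours, n_days)[first_of_adm] - 0.5)
  keep <- keep | first_of_adm
  reg_id <- reg_id[keep]
  reg_t <- reg_t[keep]

  val <- v0[reg_id] + runif(length(reg_id), -.noise_band, .noise_band)
  cat_r <- category[reg_id]
  # CA admissions drift back toward baseline, never above admission value
  is_ca <- cat_r == "CA"
  val[is_ca] <- v0[reg_id[is_ca]] * runif(sum(is_ca), 0.75, 1)
  # HA: flat band before onset (already), plateau at peak after onset
  is_ha <- cat_r == "HA"
  after <- is_ha & reg_t > onset[reg_id]
  peak <- v0 * severity
  val[after] <- peak[reg_id[after]] * runif(sum(after), 0.93, 1)

  dt <- data.table::data.table(id = reg_id, hours = reg_t, scr_umol_l = val)
  ha_idx <- which(category == "HA")
  dt <- rbind(
    data.table::data.table(id = seq_len(n), hours = 0, scr_umol_l = v0),
    dt,
    data.table::data.table(id = ha_idx, hours = onset[ha_idx],
                           scr_umol_l = peak[ha_idx])
  )
  dt[, admission_id := admission_id[id]]
  data.table::setorder(dt, id, hours)
  dt[, id := NULL]
  data.table::setcolorder(dt, c("admission_id", "hours", "scr_umol_l"))
  dt[]
}

#' Plant a hospital-acquired AKI trajectory into a creatinine series
#'
#' Deterministically rewrites a series so that detection ([detect_ha()])
#' triggers exactly at `onset_hours` with the maximum stage implied by
#' `severity_ratio`: values before onset are clamped into a +/-12 micromol/l
#' band around the admission value (which can never trigger), a measurement
#' with value `admission * severity_ratio` is inserted at onset, and later
#' values plateau just below the peak.
#'
#' @param series Data frame with `hours`, `scr_umol_l` (first row = admission).
#' @param onset_hours Requested onset, hours; must be positive and within the
#'   seven-day horizon.
#' @param severity_ratio Peak-to-admission creatinine ratio (>= 1.5).
#' @param th [aki_thresholds()].
#' @return The modified series (same columns, sorted, strictly increasing
#'   times).
#' @examples
#' s <- data.frame(hours = c(0, 24, 72), scr_umol_l = c(80, 82, 78))
#' planted <- plant_ha_aki_trajectory(s, onset_hours = 48, severity_ratio = 2)
#' detect_ha(planted)  # 48
#' @export
plant_ha_aki_trajectory <- function(series, onset_hours, severity_ratio,
                                    th = aki_thresholds()) {
  .check_series(series)
  if (onset_hours <= 0 || onset_hours > th$horizon) {
    stop("onset must lie in (0, ", th$horizon, "] hours", call. = FALSE)
  }
  if (severity_ratio < th$ratio_threshold) {
    stop("severity_ratio must be at least ", th$ratio_threshold, call. = FALSE)
  }
  t <- series$hours
  v0 <- series$scr_umol_l[1]
  peak <- v0 * severity_ratio
  val <- pmin(pmax(series$scr_umol_l, v0 - .noise_band), v0 + .noise_band)
  val[1] <- v0
  val[t > onset_hours] <- peak * 0.97
  out <- data.frame(hours = c(t[abs(t - onset_hours) > 1e-9], onset_hours),
                    scr_umol_l = c(val[abs(t - onset_hours) > 1e-9], peak))
  out <- out[order(out$hours), , drop = FALSE]
  rownames(out) <- NULL
  out
}
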