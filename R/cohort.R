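#' Apply study inclusion and exclusion rules
#'
#' An admission enters the analysis set when the patient is at least 18
#' years old, admitted under a medical specialty, stays at least one night
#' (discharge on a later calendar day than admission), has at least two
#' serum creatinine measurements, and was not moved directly from the
#' emergency department to intensive care. Excluded admissions carry exactly
#' one reason — the first matching in the order the exclusion criteria are
#' applied: direct ED-to-ICU transfer, age under 18, non-medical specialty,
#' no overnight stay, single creatinine.
#'
#' @param admissions Data frame of admissions (needs `admission_id`, `age`,
#'   `specialty`, `direct_ed_to_icu`, `admission_time`, `discharge_time`).
#' @param scr Long creatinine table (`admission_id`, `hours`, `scr_umol_l`)
#'   used to count measurements per admission.
#' @return List with `rows` (the admissions plus logical `included` and
#'   `exclusion_reason`) and `tally` (named counts: total, per-reason,
#'   analysed) for flow-diagram style accounting.
#' @export
apply_inclusion <- function(admissions, scr) {
  adm <- data.table::as.data.table(admissions)
  counts <- data.table::as.data.table(scr)[, .(n_scr = .N), by = admission_id]
  adm <- counts[adm, on = "admission_id"]
  adm[is.na(n_scr), n_scr := 0L]

  overnight <- as.Date(adm$discharge_time, tz = "UTC") >
    as.Date(adm$admission_time, tz = "UTC")
  reason <- rep(NA_character_, nrow(adm))
  reason[!overnight] <- "no_overnight"
  reason[adm$n_scr < 2] <- "single_scr"
  reason[adm$specialty != "medical"] <- "non_medical"
  reason[adm$age < 18] <- "under18"
  reason[adm$direct_ed_to_icu] <- "direct_ed_icu"

  adm[, exclusion_reason := reason]
  adm[, included := is.na(reason)]
  tally <- c(total = nrow(adm),
             table(factor(reason, levels = c("direct_ed_icu", "under18",
                                             "non_medical", "no_overnight",
                                             "single_scr"))),
             analysed = sum(adm$included))
  list(rows = adm[], tally = tally)
}

#' Build the analysis-ready cohort table
#'
#' Runs the whole per-admission derivation: inclusion filtering, AKI
#' ascertainment, risk-score and alert-state assignment, and outcome
#' derivation (in-hospital death, death within seven days of admission, ICU
#' escalation, length of stay in days — to death or discharge). One row per
#' admission; excluded admissions keep their exclusion reason and `NA`
#' analysis fields.
#'
#' @param cohort An `aki_cohort` from [generate_cohort()] or assembled from
#'   user data (list with `admissions`, `scr`, `baseline_history`).
#' @param th [aki_thresholds()].
#' @param weights [aps_weights()] table.
#' @param cutoff At-risk cut-off for the AMBER flag (default 5).
#' @return List with `rows` (a `data.table`, one row per admission, class
#'   `cohort_rows`) and `tally` (exclusion accounting).
#' @export
build_cohort <- function(cohort, th = aki_thresholds(),
                         weights = aps_weights(), cutoff = 5L) {
  inc <- apply_inclusion(cohort$admissions, cohort$scr)
  rows <- inc$rows

  cls <- classify_cohort(cohort, th)
  rows <- cls[rows, on = "admission_id"]
  rows[included == FALSE,
       c("category", "onset_hours", "max_stage", "peak_rise_umol_l") :=
         list(NA_character_, NA_real_, NA_integer_, NA_real_)]

  rows[, aps_score := compute_aps(rows, weights)]
  st <- assign_state(rows$aps_score,
                     ifelse(is.na(rows$category), "none", rows$category),
                     cutoff)
  rows[, alert_state := st$state]
  rows[, alert_reason := st$reason]

  if (any(rows$death_in_hospital & is.na(rows$death_time))) {
    stop("death flagged without a death time", call. = FALSE)
  }
  end_time <- data.table::fifelse(rows$death_in_hospital, rows$death_time,
                                  rows$discharge_time)
  rows[, length_of_stay := as.numeric(difftime(end_time, admission_time,
                                               units = "days"))]
  rows[, died_in_hospital := death_in_hospital]
  rows[, died_by_day7 := death_in_hospital &
         death_time <= admission_time + 7 * 86400]
  rows[, stage3 := !is.na(max_stage) & max_stage == 3L]
  data.table::setattr(rows, "class",
                      c("cohort_rows", class(rows)))
  list(rows = rows[], tally = inc$tally)
}

#' Restrict to patients with a single admission
#'
#' Keeps the rows of patients whose `patient_id` occurs exactly once within
#' its site across both periods (sites are analysed separately, so cross-site
#' identity is not linked).
#'
#' @param rows Cohort rows (any data frame with `patient_id` and `site`).
#' @return Subset with the same columns.
#' @export
single_admission_subset <- function(rows) {
  d <- data.table::as.data.table(rows)
  if (nrow(d) == 0) return(d)
  d[, .n_adm := .N, by = .(site, patient_id)]
  out <- d[.n_adm == 1L]
  out[, .n_adm := NULL]
  out[]
}
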