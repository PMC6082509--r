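#' Summary counts of the two-site before-after evaluation
#'
#' The admission-level cell counts of the two-site, two-period AKI alerting
#' evaluation the package's simulator emulates: total admissions, CA-AKI
#' cases, incident HA-AKI cases (denominator: admissions without CA-AKI) and,
#' among HA-AKI cases, in-hospital deaths, deaths within seven days of
#' admission, progression to stage 3 and ICU escalation, per site-period
#' cell. AMBER (at-risk flag) group sizes and CA/AMBER death counts are also
#' carried; for those, only whole percentages are published, so the counts
#' are reconstructed at that printed precision and should not be used for
#' exact checks.
#'
#' @return Data frame with one row per site-period cell.
#' @export
study_summary_counts <- function() {
  data.frame(
    site = rep(c("intervention", "control"), each = 2),
    period = rep(c("pre", "post"), 2),
    n_admissions = c(7532L, 8636L, 6749L, 7378L),
    n_ca = c(670L, 755L, 491L, 586L),
    n_at_risk = c(6862L, 7881L, 6258L, 6792L),  # admissions minus CA-AKI
    n_ha = c(568L, 609L, 410L, 453L),
    ha_died = c(156L, 132L, 94L, 112L),
    ha_died7 = c(92L, 64L, 37L, 57L),
    ha_stage3 = c(47L, 40L, 17L, 25L),
    ha_icu = c(42L, 42L, 29L, 48L),
    n_amber = c(2057L, 2351L, 1810L, 1851L),
    amber_died = c(288L, 259L, 181L, 185L),     # from whole-percent mortality
    ca_died = c(154L, 174L, 93L, 100L),         # from whole-percent mortality
    stringsAsFactors = FALSE
  )
}

#' Expand the summary counts into an admission-level table
#'
#' Builds one row per admission, reproducing every published margin of
#' [study_summary_counts()] exactly: within each cell the non-CA block is
#' laid out with the HA-AKI cases first (deaths by day seven nested inside
#' in-hospital deaths; stage-3 and ICU flags assigned from the top of the
#' block), the AMBER flag covers the first `n_amber` non-CA admissions (so
#' every HA case is inside the AMBER group), and extra AMBER deaths beyond
#' those among HA cases are placed among AMBER non-HA admissions. Patient
#' identifiers are unique — the expansion carries no within-patient
#' clustering — and no covariates are attached: the joint layout beyond the
#' published margins is a synthetic convention.
#'
#' @return `data.table` with columns `admission_id`, `patient_id`, `site`,
#'   `period`, `ca`, `ha`, `died`, `died7`, `stage3`, `icu`, `amber`.
#' @examples
#' rows <- study_summary_cohort()
#' nrow(rows)  # 30295
#' @export
study_summary_cohort <- function() {
  cells <- study_summary_counts()
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cc <- cells[i, ]
    n <- cc$n_admissions
    n_ca <- cc$n_ca
    n_ar <- cc$n_at_risk
    stopifnot(n_ca + n_ar == n)
    ca <- c(rep(TRUE, n_ca), rep(FALSE, n_ar))
    # non-CA block layout: [1..n_ha] = HA cases
    ha <- c(rep(FALSE, n_ca), rep(TRUE, cc$n_ha), rep(FALSE, n_ar - cc$n_ha))
    flag_block <- function(n_flag, block_start, block_len) {
      f <- rep(FALSE, n)
      if (n_flag > 0) f[block_start + seq_len(n_flag) - 1L] <- TRUE
      f
    }
    ha_start <- n_ca + 1L
    died7 <- flag_block(cc$ha_died7, ha_start, cc$n_ha)
    died <- flag_block(cc$ha_died, ha_start, cc$n_ha)
    stage3 <- flag_block(cc$ha_stage3, ha_start, cc$n_ha)
    icu <- flag_block(cc$ha_icu, ha_start, cc$n_ha)
    amber <- flag_block(cc$n_amber, ha_start, n_ar)
    # AMBER deaths beyond the HA block sit in AMBER non-HA admissions
    extra_amber <- cc$amber_died - cc$ha_died
    if (extra_amber > 0) {
      died[ha_start + cc$n_ha + seq_len(extra_amber) - 1L] <- TRUE
    }
    # CA deaths at the top of the CA block
    if (cc$ca_died > 0) died[seq_len(cc$ca_died)] <- TRUE
    out[[i]] <- data.table::data.table(
      site = cc$site, period = cc$period,
      ca = ca, ha = ha, died = died, died7 = died7,
      stage3 = stage3, icu = icu, amber = amber
    )
  }
  d <- data.table::rbindlist(out)
  d[, admission_id := sprintf("ref_a%05d", .I)]
  d[, patient_id := sprintf("ref_p%05d", .I)]
  data.table::setcolorder(d, c("admission_id", "patient_id", "site", "period"))
  d[]
}
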