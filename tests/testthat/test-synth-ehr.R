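test_that("configuration is validated", {
  expect_error(sim_config(ca_aki_prev = 1.2), "probabilities")
  expect_error(sim_config(intervention_or_ha = 0), "positive")
  expect_error(sim_config(mean_admissions_per_patient = 0.5), ">= 1")
  expect_error(sim_config(ha_aki_base_rate = c(a = 0.1, b = 0.1)), "named")
})

test_that("zero patients give an empty cohort", {
  coh <- generate_cohort(sim_config(n_patients_per_cell = 0))
  expect_equal(nrow(coh$admissions), 0)
  expect_equal(nrow(coh$scr), 0)
})

test_that("identical config and seed give identical cohorts; RNG state is restored", {
  cfg <- small_config()
  set.seed(99)
  a <- generate_cohort(cfg)
  after_a <- runif(1)
  set.seed(99)
  b <- generate_cohort(cfg)
  after_b <- runif(1)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$scr, b$scr)
  expect_identical(a$baseline_history, b$baseline_history)
  expect_identical(after_a, after_b)  # caller's stream untouched
  # a different seed changes the draw
  expect_false(identical(
    generate_cohort(small_config(seed = 12))$admissions$age,
    a$admissions$age))
})

test_that("patient-level clustering exists whenever mean admissions exceed one", {
  coh <- generate_cohort(small_config(mean_admissions_per_patient = 1.3))
  expect_gt(sum(duplicated(coh$admissions$patient_id)), 0)
  one <- generate_cohort(small_config(mean_admissions_per_patient = 1))
  expect_equal(sum(duplicated(one$admissions$patient_id)), 0)
})

test_that("admission records satisfy their structural invariants", {
  coh <- generate_cohort(small_config())
  adm <- coh$admissions
  expect_true(all(adm$discharge_time >= adm$admission_time))
  died <- adm$death_in_hospital
  expect_true(all(adm$death_time[died] >= adm$admission_time[died]))
  expect_true(all(adm$death_time[died] <= adm$discharge_time[died]))
  expect_true(all(is.na(adm$death_time[!died])))
  ord <- coh$scr[, .(ok = !is.unsorted(hours, strictly = TRUE) &&
                       all(hours >= 0)), by = admission_id]
  expect_true(all(ord$ok))
  expect_true(all(coh$scr$scr_umol_l > 0))
  expect_true(all(adm$age >= 0))
})

test_that("planted AKI is recovered exactly by ascertainment on included admissions", {
  coh <- generate_cohort(sim_config(n_patients_per_cell = 1500, seed = 5))
  cls <- classify_cohort(coh)
  inc <- apply_inclusion(coh$admissions, coh$scr)
  adm <- merge(coh$admissions, cls, by = "admission_id")
  adm <- adm[adm$admission_id %in% inc$rows$admission_id[inc$rows$included], ]
  expect_identical(adm$category, adm$planted_category)
  ha <- adm[adm$planted_category == "HA", ]
  expect_equal(ha$onset_hours, ha$planted_onset_hours, tolerance = 1e-9)
  expect_identical(ha$max_stage, as.integer(ha$planted_stage))
})

test_that("planted event rates match configured probabilities within 3 binomial SE", {
  cfg <- sim_config(n_patients_per_cell = 4500, intervention_or_ha = 1,
                    seed = 21)
  coh <- generate_cohort(cfg)
  adm <- coh$admissions
  eligible <- is.na(adm$planted_exclusion)
  for (s in c("intervention", "control")) {
    for (p in c("pre", "post")) {
      cell <- adm[eligible & adm$site == s & adm$period == p, ]
      # CA prevalence
      n <- nrow(cell)
      p_ca <- cfg$ca_aki_prev
      expect_lt(abs(mean(cell$planted_category == "CA") - p_ca),
                3 * sqrt(p_ca * (1 - p_ca) / n))
      # HA rate among non-CA
      ar <- cell[cell$planted_category != "CA", ]
      p_ha <- cfg$ha_aki_base_rate[[s]]
      expect_lt(abs(mean(ar$planted_category == "HA") - p_ha),
                3 * sqrt(p_ha * (1 - p_ha) / nrow(ar)))
      # mortality given HA (pre-truncation by inclusion)
      ha <- cell[cell$planted_category == "HA", ]
      p_m <- cfg$mort_given_ha
      expect_lt(abs(mean(ha$death_in_hospital) - p_m),
                3 * sqrt(p_m * (1 - p_m) / nrow(ha)))
    }
  }
})

test_that("trajectory planting triggers detection at the requested onset and stage", {
  flat <- data.frame(hours = c(0, 24, 60, 96), scr_umol_l = rep(80, 4))
  expect_true(is.na(detect_ha(flat)))  # unplanted never triggers

  p1 <- plant_ha_aki_trajectory(flat, onset_hours = 48, severity_ratio = 1.5)
  expect_equal(detect_ha(p1), 48)
  expect_equal(aki_stage(max(p1$scr_umol_l), 80, TRUE), 1L)

  p3 <- plant_ha_aki_trajectory(flat, onset_hours = 48, severity_ratio = 3)
  expect_equal(aki_stage(max(p3$scr_umol_l), 80, TRUE), 3L)

  # requested onset beyond the horizon is rejected
  expect_error(plant_ha_aki_trajectory(flat, 200, 2), "horizon|168")
  expect_error(plant_ha_aki_trajectory(flat, 48, 1.2), "at least")

  # wild pre-existing values are clamped so nothing fires before onset
  wild <- data.frame(hours = c(0, 20, 40, 80), scr_umol_l = c(80, 300, 50, 80))
  p <- plant_ha_aki_trajectory(wild, onset_hours = 60, severity_ratio = 2)
  expect_equal(detect_ha(p), 60)
})

test_that("planted exclusions cover every reason", {
  coh <- generate_cohort(sim_config(n_patients_per_cell = 1500, seed = 8))
  tally <- apply_inclusion(coh$admissions, coh$scr)$tally
  for (r in c("direct_ed_icu", "under18", "non_medical", "no_overnight",
              "single_scr")) {
    expect_gt(tally[[r]], 0)
  }
})
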