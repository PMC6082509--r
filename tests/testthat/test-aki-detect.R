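test_that("baseline derivation prefers the lowest recent value, then the older median", {
  expect_equal(derive_baseline(
    data.frame(days_before = c(2, 5), scr_umol_l = c(90, 80))), 80)
  expect_equal(derive_baseline(
    data.frame(days_before = c(30, 90, 200), scr_umol_l = c(70, 90, 110))), 90)
  # even count in the long lookback: mean of the two central values
  expect_equal(derive_baseline(
    data.frame(days_before = c(30, 90, 200, 300),
               scr_umol_l = c(70, 90, 110, 130))), 100)
  # a single recent value beats any number of older ones
  expect_equal(derive_baseline(
    data.frame(days_before = c(6, 30, 60), scr_umol_l = c(95, 60, 62))), 95)
  expect_true(is.na(derive_baseline(NULL)))
  expect_true(is.na(derive_baseline(
    data.frame(days_before = numeric(), scr_umol_l = numeric()))))
  # values beyond a year are ignored entirely
  expect_true(is.na(derive_baseline(
    data.frame(days_before = 400, scr_umol_l = 80))))
  expect_error(derive_baseline(
    data.frame(days_before = -1, scr_umol_l = 80)), "non-negative")
})

test_that("community-acquired AKI rules are boundary-inclusive", {
  expect_true(classify_ca(120, 80))    # ratio exactly 1.5
  expect_false(classify_ca(140, 100))  # ratio 1.4
  expect_true(classify_ca(360, NA))    # absolute level without baseline
  expect_true(classify_ca(354, NA))    # boundary of the absolute rule
  expect_false(classify_ca(353, NA))
  expect_error(classify_ca(-5, 80), "positive")
})

test_that("hospital-acquired detection applies ratio, rolling-rise and horizon rules", {
  expect_equal(detect_ha(
    data.frame(hours = c(0, 36), scr_umol_l = c(80, 122))), 36)
  expect_equal(detect_ha(
    data.frame(hours = c(0, 20, 47), scr_umol_l = c(80, 84, 111))), 47)
  # ratio rule fires only after the 7-day horizon: no detection
  expect_true(is.na(detect_ha(
    data.frame(hours = c(0, 100, 180), scr_umol_l = c(80, 100, 140)))))
  # rise measured against the window minimum, not the admission value
  expect_equal(detect_ha(
    data.frame(hours = c(0, 60, 100), scr_umol_l = c(100, 80, 107))), 100)
  # exact 26.5 rise triggers
  expect_equal(detect_ha(
    data.frame(hours = c(0, 30), scr_umol_l = c(80, 106.5))), 30)
  # 48h window is inclusive; a rise over a longer gap does not count
  expect_true(is.na(detect_ha(
    data.frame(hours = c(0, 100), scr_umol_l = c(80, 107)))))
  expect_error(detect_ha(data.frame(hours = 0, scr_umol_l = 80)),
               "at least two")
})

test_that("staging follows the ratio bands", {
  expect_equal(aki_stage(240, 80, TRUE), 3L)  # x3
  expect_equal(aki_stage(170, 80, TRUE), 2L)  # 2.125
  expect_equal(aki_stage(130, 80, TRUE), 1L)  # fired but below x2
  expect_equal(aki_stage(160, 80, TRUE), 2L)  # boundary x2
  expect_equal(aki_stage(130, 80, FALSE), 0L)
})

test_that("classification gives CA precedence and handles the null case", {
  mk <- function(hours, v, hist = NULL) {
    list(scr = data.frame(hours = hours, scr_umol_l = v),
         baseline_history = hist)
  }
  ca <- classify_admission(mk(c(0, 24), c(120, 121),
                              data.frame(days_before = 3, scr_umol_l = 80)))
  expect_equal(ca$category, "CA")
  expect_equal(ca$onset_hours, 0)

  ha <- classify_admission(mk(c(0, 30), c(85, 130),
                              data.frame(days_before = 3, scr_umol_l = 80)))
  expect_equal(ha$category, "HA")
  expect_equal(ha$onset_hours, 30)

  none <- classify_admission(mk(c(0, 24, 48), c(80, 80, 80)))
  expect_equal(none$category, "none")
  expect_equal(none$max_stage, 0L)
  expect_equal(none$peak_rise_umol_l, 0)

  # CA detected through the absolute level without baseline is staged 3
  abs_ca <- classify_admission(mk(c(0, 24), c(400, 380)))
  expect_equal(abs_ca$category, "CA")
  expect_equal(abs_ca$max_stage, 3L)
})

test_that("no admission is both CA and HA, and category none means stage 0", {
  set.seed(401)
  for (i in 1:200) {
    s <- random_series()
    hist <- if (runif(1) < 0.5) {
      data.frame(days_before = runif(2, 1, 300), scr_umol_l = runif(2, 50, 150))
    }
    cls <- classify_admission(list(scr = s, baseline_history = hist))
    expect_true(cls$category %in% c("none", "CA", "HA"))
    expect_identical(cls$category == "none", cls$max_stage == 0L)
    if (cls$category == "CA") expect_equal(cls$onset_hours, 0)
    if (cls$category == "HA") {
      expect_gt(cls$onset_hours, 0)
      expect_lte(cls$onset_hours, 168)
    }
  }
})

test_that("detection matches the brute-force pairwise oracle", {
  set.seed(402)
  for (i in 1:1000) {
    s <- random_series()
    expect_identical(detect_ha(s), oracle_detect(s$hours, s$scr_umol_l))
  }
})

test_that("scaling a series up never delays onset; raising one value never delays past it", {
  set.seed(403)
  for (i in 1:300) {
    s <- random_series()
    o1 <- detect_ha(s)
    s2 <- s
    s2$scr_umol_l <- s2$scr_umol_l * runif(1, 1, 1.6)
    o2 <- detect_ha(s2)
    expect_lte(ifelse(is.na(o2), Inf, o2), ifelse(is.na(o1), Inf, o1))

    # raising one post-admission value: triggers at that time only get easier
    j <- sample(2:nrow(s), 1)
    s3 <- s
    s3$scr_umol_l[j] <- s3$scr_umol_l[j] + runif(1, 0, 100)
    o3 <- detect_ha(s3)
    if (!is.na(o1) && o1 == s$hours[j]) {
      expect_lte(o3, s$hours[j])
    }
    # ratio-rule detections survive any pointwise increase
    v0 <- s$scr_umol_l[1]
    if (any(s$scr_umol_l / v0 >= 1.5 & s$hours <= 168)) {
      s4 <- s
      s4$scr_umol_l[-1] <- s4$scr_umol_l[-1] + runif(nrow(s) - 1, 0, 50)
      expect_false(is.na(detect_ha(s4)))
    }
  }
})

test_that("vectorised cohort classification agrees with the per-record path", {
  set.seed(404)
  recs <- lapply(1:300, function(i) {
    s <- random_series()
    k <- sample(1:3, 1)
    hist <- if (runif(1) < 0.6) {
      data.frame(days_before = runif(k, 1, 400),
                 scr_umol_l = runif(k, 50, 200))
    }
    list(scr = s, baseline_history = hist)
  })
  ids <- sprintf("a%03d", seq_along(recs))
  scr <- data.table::rbindlist(lapply(seq_along(recs), function(i) {
    cbind(admission_id = ids[i], recs[[i]]$scr)
  }))
  hist <- data.table::rbindlist(lapply(seq_along(recs), function(i) {
    h <- recs[[i]]$baseline_history
    if (is.null(h)) NULL else cbind(admission_id = ids[i], h)
  }))
  fast <- classify_cohort(list(scr = scr, baseline_history = hist))
  for (i in seq_along(recs)) {
    slow <- classify_admission(recs[[i]])
    row <- fast[fast$admission_id == ids[i], ]
    expect_equal(row$category, slow$category, info = ids[i])
    expect_equal(row$onset_hours, slow$onset_hours, info = ids[i])
    expect_equal(row$max_stage, slow$max_stage, info = ids[i])
    expect_equal(row$peak_rise_umol_l, slow$peak_rise_umol_l, info = ids[i])
  }
})
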