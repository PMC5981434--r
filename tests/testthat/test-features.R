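test_that("registry has 110 features with the documented category counts", {
  reg <- feature_registry()
  expect_equal(nrow(reg), 110)
  expect_false(anyDuplicated(reg$name) > 0)
  counts <- table(reg$category)
  expect_equal(unname(counts[c("night_std", "night_mean", "night_min", "night_max",
                               "night_median", "night_p5", "night_p25",
                               "night_p75", "night_p95")]),
               c(6, 6, 4, 5, 5, 5, 5, 5, 5), ignore_attr = TRUE)
  expect_equal(unname(counts[c("quarter_std", "quarter_mean", "quarter_max",
                               "quarter_min", "quarter_median", "quarter_p5",
                               "quarter_p25", "quarter_p75", "quarter_p95")]),
               c(5, 5, 5, 4, 5, 5, 5, 5, 5), ignore_attr = TRUE)
  expect_equal(unname(counts["correlation"]), 14, ignore_attr = TRUE)
  expect_equal(unname(counts["hrv"]), 6, ignore_attr = TRUE)
  # EDA minimum excluded everywhere; (hr, ibi) correlation excluded
  expect_false("min_eda" %in% reg$name)
  expect_false("qdiff_min_eda" %in% reg$name)
  expect_false("corr_hr_ibi_interp" %in% reg$name)
})

test_that("extraction returns 110 finite features, deterministically", {
  night <- tiny_night()
  fv <- extract_night_features(night)
  expect_length(fv$values, 110)
  expect_true(all(is.finite(fv$values)))
  expect_identical(names(fv$values), feature_registry()$name)
  expect_identical(fv$values, extract_night_features(night)$values)
})

test_that("constant channels zero out spreads and quarter differences", {
  night <- as_night(constant_block())
  v <- extract_night_features(night)$values
  reg <- feature_registry()
  expect_true(all(v[reg$name[reg$category == "night_std"]] == 0))
  expect_true(all(v[startsWith(reg$name, "qdiff")] == 0))
  expect_true(all(v[reg$category == "correlation"] == 0))  # zero variance rule
})

test_that("quarter differences recover the closed-form ramp value", {
  # linear ramp 36 -> 37: first-quarter mean is 36 + 1/8, last is 36 + 7/8
  n <- 4096
  blk <- constant_block(n)
  blk$temp <- seq(36, 37, length.out = n)
  qd <- compute_quarter_diffs(blk)
  expect_equal(unname(qd["qdiff_mean_temp"]), 0.75, tolerance = 1e-3)
  expect_length(qd, 44)
  expect_error(compute_quarter_diffs(constant_block(3)), "at least 4")
})

test_that("translation: shifting a channel moves location stats, not spread", {
  night <- tiny_night()
  v0 <- extract_night_features(night)$values
  shifted <- night
  shifted$block$temp <- shifted$block$temp + 2.5
  v1 <- extract_night_features(shifted)$values
  for (f in c("mean_temp", "median_temp", "p5_temp", "p95_temp", "min_temp", "max_temp")) {
    expect_equal(unname(v1[f] - v0[f]), 2.5, tolerance = 1e-9)
  }
  same <- c("std_temp", "qdiff_std_temp", "qdiff_mean_temp",
            grep("^corr_.*temp", names(v0), value = TRUE))
  expect_equal(v1[same], v0[same], tolerance = 1e-9)
})

test_that("signal correlations: count, duplicated column, independence", {
  blk <- constant_block(10000)
  set.seed(9)
  for (col in c("acc_mag", "bvp", "temp", "hr", "eda", "ibi_interp")) {
    blk[[col]] <- rnorm(10000)
  }
  cc <- compute_signal_correlations(blk)
  expect_length(cc, 14)
  expect_true(all(abs(cc) < 0.1))
  blk$eda <- blk$temp
  expect_equal(unname(compute_signal_correlations(blk)["corr_temp_eda"]), 1)
  expect_error(compute_signal_correlations(constant_block(1)), "at least 2")
})

test_that("HRV features match hand computation on worked examples", {
  h <- compute_hrv_features(c(0.80, 0.85, 0.80))
  expect_equal(unname(h["hrv_rmssd"]), 0.05)
  expect_equal(unname(h["hrv_sdiff_mean"]), 0)
  expect_equal(unname(h["hrv_nn50"]), 0)
  expect_equal(unname(h["hrv_n_beats"]), 3)

  expect_equal(unname(compute_hrv_features(c(0.80, 0.86, 0.80))["hrv_nn50"]), 2)

  const <- compute_hrv_features(rep(0.8, 50))
  expect_equal(unname(const["hrv_rmssd"]), 0)
  expect_equal(unname(const["hrv_sdiff_sd"]), 0)

  expect_warning(short <- compute_hrv_features(c(0.8, 0.9)), "fewer than 3")
  expect_equal(unname(short["hrv_n_beats"]), 2)
  expect_equal(unname(short["hrv_rmssd"]), 0)
})

test_that("total power tracks interval variability", {
  set.seed(4)
  lo <- compute_hrv_features(rnorm(500, 0.8, 0.005))[["hrv_total_power"]]
  hi <- compute_hrv_features(rnorm(500, 0.8, 0.05))[["hrv_total_power"]]
  expect_gt(hi, lo * 10)
})

test_that("feature tables carry metadata plus the registry columns", {
  ft <- tiny_subject_features()
  expect_equal(ncol(ft), 113)
  expect_identical(names(ft)[1:3], c("subject_id", "night_id", "label"))
  expect_identical(names(ft)[-(1:3)], feature_registry()$name)
  expect_true(all(ft$label %in% c("pre_migraine", "non_migraine")))
})
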