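test_that("fully rested days qualify from the lookback boundary onward", {
  log <- flat_log()
  expect_equal(qualifying_minutes(log), 15:1439)
  expect_length(qualifying_minutes(log), 1425L)
})

test_that("an activity bout disqualifies its lookback shadow", {
  log <- flat_log(active = 100:110)
  expect_equal(qualifying_minutes(log), setdiff(15:1439, 100:125))
  all_active <- flat_log(active = 0:1439)
  expect_length(qualifying_minutes(all_active), 0L)
})

test_that("unknown step data never certifies rest", {
  log <- flat_log()
  log$steps <- log$steps[log$steps$time != 50L, ]   # minute 50 unknown
  expect_equal(qualifying_minutes(log), setdiff(15:1439, 50:65))
})

test_that("qualifying minutes match a brute-force re-derivation on random logs", {
  set.seed(2024)
  for (i in 1:25) {
    log <- random_log(sprintf("Q%02d", i))
    expect_identical(qualifying_minutes(log), brute_force_qualifying(log),
                     info = paste("log", i))
  }
})

test_that("adding activity never enlarges the qualifying set", {
  set.seed(88)
  log <- flat_log(active = c(300:320, 700:705))
  base <- qualifying_minutes(log)
  for (i in 1:15) {
    m <- sample(0:1439, 1)
    perturbed <- log
    perturbed$steps$steps[perturbed$steps$time == m] <- 50L
    expect_true(all(qualifying_minutes(perturbed) %in% base))
  }
})

test_that("daily rHR is the median with the even-count mean convention", {
  params <- rest_params(min_rest_minutes_per_day = 3L)
  odd <- flat_log(hr = c(60, 62, 64), hr_minutes = c(100, 200, 300))
  expect_equal(daily_rhr(odd, params)$rhr, 62)
  even <- flat_log(hr = c(60, 62, 64, 66), hr_minutes = c(100, 200, 300, 400))
  expect_equal(daily_rhr(even, params)$rhr, 63)
})

test_that("days with too few resting minutes are marked missing", {
  log <- flat_log(hr = 70, hr_minutes = seq(100, 1000, by = 100))  # 10 samples
  d <- daily_rhr(log, rest_params(min_rest_minutes_per_day = 30L))
  expect_true(is.na(d$rhr))
  expect_equal(d$n_rest_minutes, 10L)
})

test_that("daily medians match the brute-force oracle on random logs", {
  set.seed(515)
  params <- rest_params(min_rest_minutes_per_day = 5L)
  for (i in 1:25) {
    log <- random_log(sprintf("M%02d", i))
    expect_identical(daily_rhr(log, params)$rhr,
                     brute_force_daily_median(log, params))
  }
})

test_that("visit-level rHR averages the pre-visit window, excluding the visit day", {
  daily <- tibble::tibble(
    subject_id = "V1",
    date = as.Date("2024-03-01") + 0:5,
    rhr = c(70, 72, 74, 76, 78, 99),   # last row is the visit day itself
    n_rest_minutes = 100L
  )
  v <- visit_wd_rhr(daily, "2024-03-06")
  expect_equal(v$wd_rhr, 74)
  expect_equal(v$n_days_used, 5L)
  # perturbing the visit day's own value leaves the output unchanged
  daily$rhr[6] <- 150
  expect_equal(visit_wd_rhr(daily, "2024-03-06")$wd_rhr, 74)
})

test_that("too few valid days yields a missing visit value", {
  daily <- tibble::tibble(subject_id = "V1",
                          date = as.Date("2024-03-04") + 0:1,
                          rhr = c(70, 72), n_rest_minutes = 100L)
  v <- visit_wd_rhr(daily, "2024-03-06", rest_params(min_valid_days_per_visit = 3L))
  expect_true(is.na(v$wd_rhr))
  expect_equal(v$n_days_used, 2L)
  # visit before all data
  early <- visit_wd_rhr(daily, "2024-01-01")
  expect_true(is.na(early$wd_rhr))
  expect_equal(early$n_days_used, 0L)
})

test_that("noise-free extraction recovers the true resting HR exactly", {
  cfg <- quiet_config(n_thyrotoxic = 2L, n_control = 1L, seed = 21L,
                      subject_sd = 3)   # subject heterogeneity, no noise
  study <- generate_study(cfg)
  ex <- extract_all(study$logs, study$visits)
  merged <- merge(ex$visits, study$truth, by = c("subject_id", "visit_index"))
  expect_equal(merged$wd_rhr, merged$true_rest_hr_bpm, tolerance = 1e-12)
})

test_that("visits without any logs get missing values and a warning", {
  cfg <- generator_config(n_thyrotoxic = 1L, n_control = 1L, seed = 4L)
  study <- generate_study(cfg)
  expect_warning(ex <- extract_all(list(), study$visits), "no device logs")
  expect_true(all(is.na(ex$visits$wd_rhr)))
})
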