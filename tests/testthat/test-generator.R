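test_that("sample_cohort produces the configured group sizes, deterministically", {
  cfg <- generator_config(seed = 11L)
  set.seed(cfg$seed)
  cohort <- sample_cohort(cfg)
  expect_equal(nrow(cohort), 38L)
  expect_equal(sum(cohort$group == "thyrotoxic"), 28L)
  set.seed(cfg$seed)
  expect_identical(cohort, sample_cohort(cfg))

  empty <- generator_config(n_thyrotoxic = 0L, n_control = 0L)
  expect_equal(nrow(sample_cohort(empty)), 0L)
})

test_that("degenerate baseline distribution collapses to the configured mean", {
  cfg <- generator_config(ft4_baseline_thyro_sd = 0, seed = 5L)
  set.seed(cfg$seed)
  cohort <- sample_cohort(cfg)
  expect_true(all(cohort$baseline_ft4[cohort$group == "thyrotoxic"] == 3.08))
})

test_that("baseline draws respect group-specific fT4 ranges and targets", {
  cfg <- generator_config(n_thyrotoxic = 2000L, n_control = 2000L, seed = 9L)
  set.seed(cfg$seed)
  cohort <- sample_cohort(cfg)
  thy <- cohort$baseline_ft4[cohort$group == "thyrotoxic"]
  ctl <- cohort$baseline_ft4[cohort$group == "control"]
  refs <- ref_ranges()
  expect_true(all(thy > refs$ft4_high))
  expect_true(all(ctl >= refs$ft4_low & ctl <= refs$ft4_high))
  # moment-matched truncation keeps the configured mean/SD despite the bound
  expect_lt(abs(mean(thy) - 3.08), 3 * 1.09 / sqrt(2000))
  expect_lt(abs(sd(thy) - 1.09), 0.08)
})

test_that("invalid configurations raise errors naming the offending field", {
  expect_error(generator_config(wear_prob = 1.7), "wear_prob")
  expect_error(generator_config(subject_sd = -1), "subject_sd")
  expect_error(generator_config(n_visits = 0), "n_visits")
  expect_error(generator_config(ft4_control_mean = -2), "ft4_control_mean")
})

test_that("fT4 courses follow the treatment-decay model", {
  cfg <- quiet_config()
  ctl <- list(group = "control", baseline_ft4 = 1.36)
  expect_equal(simulate_ft4_course(ctl, cfg)$ft4, rep(1.36, 3))

  thy <- list(group = "thyrotoxic", baseline_ft4 = 3.08)
  no_decay <- quiet_config(ft4_visit_decay = 0)
  expect_equal(simulate_ft4_course(thy, no_decay)$ft4, rep(3.08, 3))

  # noise-free decay contracts toward the euthyroid target
  traj <- simulate_ft4_course(thy, cfg)$ft4
  expect_true(all(diff(traj) < 0))
  expect_true(all(traj > cfg$ft4_euthyroid_target))
  # TSH suppressed below reference while fT4 elevated
  set.seed(2)
  tsh <- simulate_ft4_course(list(group = "thyrotoxic", baseline_ft4 = 4), cfg)$tsh
  expect_true(all(tsh < ref_ranges()$tsh_low))
})

test_that("with all variation off every HR sample equals the linear resting level", {
  cfg <- quiet_config()
  profile <- list(subject_id = "Z1", group = "thyrotoxic", baseline_ft4 = 3,
                  random_intercept = 2.5, beta_blocker_user = FALSE,
                  wear_compliance = 1)
  log <- simulate_day(profile, 3, "2024-01-05", cfg)
  expected <- cfg$rhr_intercept + cfg$rhr_ft4_slope * 3 + 2.5
  expect_equal(nrow(log$heart), 1440L)
  expect_true(all(log$heart$bpm == expected))
  expect_true(all(log$steps$steps == 0))
})

test_that("zero wear probability yields an empty log", {
  cfg <- generator_config()
  profile <- list(subject_id = "Z1", group = "control", baseline_ft4 = 1.3,
                  random_intercept = 0, beta_blocker_user = FALSE,
                  wear_compliance = 0)
  log <- simulate_day(profile, 1.3, "2024-01-05", cfg)
  expect_equal(nrow(log$heart), 0L)
  expect_equal(nrow(log$steps), 0L)
})

test_that("activity raises HR during bouts and decays away within 3 time constants", {
  cfg <- generator_config(hr_noise_sd = 0, seed = 31L)
  profile <- list(subject_id = "A1", group = "thyrotoxic", baseline_ft4 = 3,
                  random_intercept = 0, beta_blocker_user = FALSE,
                  wear_compliance = 1)
  set.seed(31)
  found_bout <- FALSE
  for (try in 1:10) {
    log <- simulate_day(profile, 3, "2024-01-05", cfg, detail = TRUE)
    comp <- attr(log, "components")
    active <- which(comp$steps > 0) - 1L
    if (!length(active)) next
    found_bout <- TRUE
    # evaluate the recursion's output directly on the generated bout
    expect_true(all(comp$excess[active + 1L] > 0))
    bout_end <- max(active)
    probe <- bout_end + 3 * cfg$hr_recovery_tau
    if (probe <= 1439 && !any(active > bout_end)) {
      expect_lt(comp$excess[probe + 1L], 0.05 * cfg$activity_hr_gain)
    }
    # minute HR during activity exceeds the same subject's resting level
    vec <- thyrowear:::as_minute_vectors(log)
    expect_true(mean(vec$hr[active + 1L]) > comp$rest)
  }
  expect_true(found_bout)
})

test_that("on-site visit measurements follow the latent model", {
  cfg <- quiet_config()
  profile <- list(subject_id = "O1", group = "thyrotoxic", baseline_ft4 = 3,
                  random_intercept = -1, beta_blocker_user = FALSE,
                  wear_compliance = 1)
  visit <- simulate_onsite_visit(profile, 3, cfg)
  expect_equal(visit$onsite_rhr, cfg$rhr_intercept + cfg$rhr_ft4_slope * 3 - 1)
  # extreme fT4 clips the latent HSS total at the scale maximum
  high <- simulate_onsite_visit(profile, 500, cfg)
  expect_equal(high$hss_total, 40L)
  expect_equal(sum(high$hss_items), 40L)
})

test_that("HSS item decomposition preserves totals under per-item caps", {
  for (total in 0:40) {
    items <- hss_item_split(total)
    expect_length(items, 10L)
    expect_equal(sum(items), total)
    expect_true(all(items >= 0 & items <= 4))
  }
})

test_that("increasing the fT4 slope widens the group gap in true resting HR", {
  gaps <- sapply(c(2, 6, 12), function(s) {
    cfg <- generator_config(rhr_ft4_slope = s, seed = 44L)
    set.seed(cfg$seed)
    cohort <- sample_cohort(cfg)
    rest <- cfg$rhr_intercept + s * cohort$baseline_ft4 + cohort$random_intercept
    mean(rest[cohort$group == "thyrotoxic"]) - mean(rest[cohort$group == "control"])
  })
  expect_true(all(diff(gaps) > 0))
})

test_that("generate_study is reproducible and writes byte-identical artifacts", {
  cfg <- generator_config(n_thyrotoxic = 3L, n_control = 2L, seed = 7L)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$visits, s2$visits)
  expect_identical(s1$logs, s2$logs)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_study(cfg, output_dir = d1)
  generate_study(cfg, output_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
})

test_that("study dimensions follow the visit schedule", {
  cfg <- generator_config(seed = 3L)
  study <- generate_study(cfg)
  expect_equal(nrow(study$visits), 38L * 3L)
  expect_equal(length(study$logs), 38L * 3L * 5L)  # 5 wear days per visit
  expect_equal(nrow(study$truth), 38L * 3L)
})
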