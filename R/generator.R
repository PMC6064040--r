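# Synthetic longitudinal study generator.
#
# Emulates a wearable-device thyrotoxicosis cohort: a thyrotoxic group whose
# free T4 declines under antithyroid treatment and a euthyroid control group,
# each wearing a heart-rate/step tracker. Minute-level heart rate is built
# from a subject-level resting component that is exactly linear in free T4,
# plus a circadian rhythm, an activity response with first-order recovery,
# and measurement noise. Defaults are calibrated against the printed summary
# statistics of the motivating cohort (baseline fT4 3.08 (1.09) ng/dL in
# patients, 1.36 (0.12) in controls; on-site resting HR 101.6 (14.5) bpm;
# fT4 visit means 3.08 -> 2.02 -> 1.66; pooled wearable-rHR SD ~ 11.4 bpm;
# standardized linear-GEE effect ~ 0.492). See the methods vignette for the
# calibration procedure.

#' Generator configuration
#'
#' All distributions and effects of the synthetic-study generator, plus the
#' seed. The defaults encode the study conditions the package is calibrated
#' to; see the methods vignette for where each value comes from.
#'
#' @param n_thyrotoxic,n_control Number of subjects per group.
#' @param n_visits Number of clinic visits per subject (>= 1).
#' @param days_between_visits Days between consecutive visits.
#' @param ft4_baseline_thyro_mean,ft4_baseline_thyro_sd Mean/SD (ng/dL) of
#'   thyrotoxic baseline free T4. Draws are truncated above the overt
#'   threshold with a moment-matched parent so the realized mean/SD equal
#'   the configured targets.
#' @param ft4_control_mean,ft4_control_sd Mean/SD (ng/dL) of control free
#'   T4, truncated to the euthyroid reference range.
#' @param ft4_euthyroid_target Free T4 level (ng/dL) treatment decays
#'   toward.
#' @param ft4_visit_decay Per-visit fractional decline of the excess of fT4
#'   over `ft4_euthyroid_target` (0 = no treatment effect).
#' @param ft4_visit_sd SD (ng/dL) of visit-to-visit fT4 noise on follow-up
#'   visits in the thyrotoxic group.
#' @param ft4_control_visit_sd SD (ng/dL) of visit-to-visit fT4 noise in
#'   controls.
#' @param rhr_intercept Resting-HR intercept (bpm).
#' @param rhr_ft4_slope Resting-HR response to free T4 (bpm per ng/dL).
#' @param subject_sd SD (bpm) of the subject random intercept `u_i`.
#' @param rhr_window_sd SD (bpm) of a slowly varying resting-HR deviation,
#'   drawn once per pre-visit wear window (autonomic state, sleep,
#'   temperature: resting-HR variation not driven by thyroid hormone).
#' @param circadian_amplitude Amplitude (bpm) of the sinusoidal circadian
#'   HR rhythm; `circadian_phase` is the hour of its trough.
#' @param circadian_phase Hour of day (0-24) at which circadian HR is lowest.
#' @param activity_bout_rate Expected activity bouts per day (Poisson).
#' @param activity_bout_len_mean Mean bout length, minutes (exponential).
#' @param activity_hr_gain Steady-state HR excess (bpm) at unit activity
#'   intensity; intensity is step cadence / 100, capped at 1.
#' @param hr_recovery_tau Time constant (minutes) of the first-order
#'   exponential HR recovery after activity.
#' @param hr_noise_sd Per-minute HR measurement noise SD (bpm).
#' @param wear_prob Probability that any given minute is recorded by the
#'   device (per-minute independent wear indicator).
#' @param onsite_offset_mean,onsite_offset_sd Mean/SD (bpm) of the clinic
#'   visit effect added to the true resting HR for the on-site measurement
#'   (white-coat effect plus single-reading noise), chosen so on-site rHR is
#'   more variable than the wearable-derived rHR.
#' @param hss_intercept,hss_slope Latent Hyperthyroidism Symptom Scale total
#'   as a linear function of fT4 (points; points per ng/dL).
#' @param hss_noise_sd SD (points) of latent HSS noise.
#' @param beta_blocker_frac Fraction of thyrotoxic subjects flagged as
#'   beta-blocker users (a simple on/off subject flag; default 0).
#' @param beta_blocker_hr_drop HR reduction (bpm) applied over a random
#'   4-hour window on days a flagged user medicates.
#' @param seed Integer seed; the same configuration reproduces the identical
#'   dataset bit-for-bit.
#'
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_thyrotoxic = 28L,
                             n_control = 10L,
                             n_visits = 3L,
                             days_between_visits = 30L,
                             ft4_baseline_thyro_mean = 3.08,
                             ft4_baseline_thyro_sd = 1.09,
                             ft4_control_mean = 1.36,
                             ft4_control_sd = 0.12,
                             ft4_euthyroid_target = 1.475,
                             ft4_visit_decay = 0.66,
                             ft4_visit_sd = 0.49,
                             ft4_control_visit_sd = 0.05,
                             rhr_intercept = 74.8,
                             rhr_ft4_slope = 4.28,
                             subject_sd = 9.51,
                             rhr_window_sd = 4.59,
                             circadian_amplitude = 3,
                             circadian_phase = 4,
                             activity_bout_rate = 8,
                             activity_bout_len_mean = 20,
                             activity_hr_gain = 25,
                             hr_recovery_tau = 4,
                             hr_noise_sd = 2.5,
                             wear_prob = 0.9,
                             onsite_offset_mean = 13.6,
                             onsite_offset_sd = 9.9,
                             hss_intercept = -9.0,
                             hss_slope = 7.0,
                             hss_noise_sd = 6.5,
                             beta_blocker_frac = 0,
                             beta_blocker_hr_drop = 8,
                             seed = 1234L) {
  config <- structure(as.list(environment()), class = "generator_config")
  validate_generator_config(config)
  config
}

validate_generator_config <- function(config) {
  chk <- function(cond, field, what) {
    if (!isTRUE(cond)) {
      stop("invalid generator configuration: '", field, "' ", what,
           call. = FALSE)
    }
  }
  num1 <- function(field) {
    v <- config[[field]]
    chk(is.numeric(v) && length(v) == 1L && is.finite(v), field,
        "must be a single finite number")
    v
  }
  for (f in c("n_thyrotoxic", "n_control")) {
    v <- num1(f); chk(v >= 0 && v == floor(v), f, "must be a non-negative integer")
  }
  v <- num1("n_visits"); chk(v >= 1 && v == floor(v), "n_visits", "must be an integer >= 1")
  chk(num1("days_between_visits") >= 1, "days_between_visits", "must be >= 1")
  for (f in c("ft4_baseline_thyro_mean", "ft4_control_mean", "ft4_euthyroid_target")) {
    chk(num1(f) > 0, f, "must be > 0")
  }
  for (f in c("ft4_baseline_thyro_sd", "ft4_control_sd", "ft4_visit_sd",
              "ft4_control_visit_sd", "subject_sd", "rhr_window_sd",
              "hr_noise_sd", "onsite_offset_sd", "hss_noise_sd")) {
    chk(num1(f) >= 0, f, "must be a non-negative SD")
  }
  for (f in c("wear_prob", "ft4_visit_decay", "beta_blocker_frac")) {
    v <- num1(f); chk(v >= 0 && v <= 1, f, "must be a probability in [0, 1]")
  }
  for (f in c("circadian_amplitude", "activity_bout_rate",
              "activity_bout_len_mean", "activity_hr_gain")) {
    chk(num1(f) >= 0, f, "must be >= 0")
  }
  chk(num1("hr_recovery_tau") > 0, "hr_recovery_tau", "must be > 0")
  v <- num1("circadian_phase"); chk(v >= 0 && v < 24, "circadian_phase", "must be an hour in [0, 24)")
  v <- num1("seed"); chk(v == floor(v), "seed", "must be an integer")
  invisible(config)
}

# --- truncated-normal draws with moment-matched parent ----------------------

truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  Z <- pnorm(b) - pnorm(a)
  da <- dnorm(a); db <- dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (ifelse(is.finite(a), a * da, 0) -
                       ifelse(is.finite(b), b * db, 0)) / Z -
                    ((da - db) / Z)^2)
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

# Parent (mu, sigma) whose truncation to [lower, upper] has the requested
# mean and SD, so configured targets are realized despite truncation.
truncnorm_parent <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(list(mu = mean, sigma = 0))
  obj <- function(p) {
    m <- truncnorm_moments(p[1], exp(p[2]), lower, upper)
    (m$mean - mean)^2 + (m$sd - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  p <- truncnorm_parent(mean, sd, lower, upper)
  lo <- pnorm(lower, p$mu, p$sigma)
  hi <- pnorm(upper, p$mu, p$sigma)
  qnorm(stats::runif(n, lo, hi), p$mu, p$sigma)
}

# --- cohort -----------------------------------------------------------------

#' Draw a synthetic cohort
#'
#' Samples subject profiles: group labels, baseline free T4 (controls inside
#' the reference range, thyrotoxic subjects above the overt threshold),
#' subject-level resting-HR random intercepts, beta-blocker flags and wear
#' compliance.
#'
#' @param config A [generator_config()].
#' @return A tibble with one row per subject: `subject_id`, `group`,
#'   `baseline_ft4`, `random_intercept`, `beta_blocker_user`,
#'   `wear_compliance`.
#' @export
sample_cohort <- function(config) {
  validate_generator_config(config)
  refs <- ref_ranges()
  nt <- as.integer(config$n_thyrotoxic)
  nc <- as.integer(config$n_control)
  n <- nt + nc
  group <- rep(c("thyrotoxic", "control"), c(nt, nc))
  baseline <- numeric(n)
  if (nt > 0) {
    baseline[seq_len(nt)] <- rtruncnorm(nt, config$ft4_baseline_thyro_mean,
                                        config$ft4_baseline_thyro_sd,
                                        lower = refs$ft4_high)
  }
  if (nc > 0) {
    baseline[nt + seq_len(nc)] <- rtruncnorm(nc, config$ft4_control_mean,
                                             config$ft4_control_sd,
                                             lower = refs$ft4_low,
                                             upper = refs$ft4_high)
  }
  tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    group = group,
    baseline_ft4 = baseline,
    random_intercept = stats::rnorm(n, 0, config$subject_sd),
    beta_blocker_user = group == "thyrotoxic" &
      stats::runif(n) < config$beta_blocker_frac,
    wear_compliance = rep(config$wear_prob, n)
  )
}

#' Simulate a subject's free T4/TSH course over visits
#'
#' Thyrotoxic trajectories decline multiplicatively toward the euthyroid
#' target (antithyroid treatment); control trajectories are stationary. TSH
#' is generated as suppressed (below the reference range) while free T4 is
#' elevated and carries no information beyond suppression status.
#'
#' @param profile One row of [sample_cohort()] output (or an equivalent
#'   list with `group` and `baseline_ft4`).
#' @param config A [generator_config()].
#' @return A tibble with columns `visit_index`, `ft4`, `tsh`.
#' @export
simulate_ft4_course <- function(profile, config) {
  validate_generator_config(config)
  refs <- ref_ranges()
  k <- as.integer(config$n_visits)
  ft4 <- numeric(k)
  ft4[1] <- profile$baseline_ft4
  if (identical(profile$group, "thyrotoxic")) {
    keep <- 1 - config$ft4_visit_decay
    for (v in seq_len(k)[-1]) {
      ft4[v] <- config$ft4_euthyroid_target +
        (ft4[v - 1] - config$ft4_euthyroid_target) * keep +
        stats::rnorm(1, 0, config$ft4_visit_sd)
      ft4[v] <- max(ft4[v], 0.15)
    }
    tsh <- ifelse(ft4 >= refs$ft4_high,
                  pmin(0.01 * exp(stats::rnorm(k, 0, 0.2)), refs$tsh_low - 0.01),
                  pmin(pmax(0.01 * exp(stats::rnorm(k, 0, 1.2)), 0.005),
                       refs$tsh_low - 0.01))
  } else {
    if (k > 1) {
      ft4[-1] <- profile$baseline_ft4 +
        stats::rnorm(k - 1, 0, config$ft4_control_visit_sd)
    }
    tsh <- pmin(pmax(exp(stats::rnorm(k, log(1.4), 0.4)), refs$tsh_low + 0.01),
                refs$tsh_high - 0.01)
  }
  tibble::tibble(visit_index = seq_len(k), ft4 = ft4, tsh = tsh)
}

# True (noise-free) resting heart rate implied by the linear model.
true_resting_hr <- function(profile, ft4, config) {
  config$rhr_intercept + config$rhr_ft4_slope * ft4 + profile$random_intercept
}

#' Simulate one day of intraday device data
#'
#' Builds a 1-minute-resolution day log. Minute heart rate is the subject's
#' true resting HR (linear in free T4 plus the subject random intercept and
#' an optional slowly varying window deviation), plus a sinusoidal circadian
#' term, an activity-driven excess with first-order exponential recovery
#' (time constant `hr_recovery_tau`), and Gaussian measurement noise. Step
#' counts are positive exactly during activity bouts. Each minute is
#' recorded independently with probability `wear_prob`; unrecorded minutes
#' carry neither a heart-rate nor a step sample (non-wear).
#'
#' @param profile One row of [sample_cohort()] output.
#' @param true_ft4 The subject's current free T4 (ng/dL, > 0).
#' @param date Calendar date of the log.
#' @param config A [generator_config()].
#' @param window_dev Slowly varying resting-HR deviation (bpm) for this
#'   day's wear window (drawn per visit window by [generate_study()]).
#' @param detail If `TRUE`, attach the deterministic signal components
#'   (`rest`, `circadian`, `excess` per minute) as attribute `"components"`.
#' @return A [device_day_log()].
#' @export
simulate_day <- function(profile, true_ft4, date, config, window_dev = 0,
                         detail = FALSE) {
  stopifnot(true_ft4 > 0)
  minutes <- seq_len(MINUTES_PER_DAY) - 1L
  rest <- true_resting_hr(profile, true_ft4, config) + window_dev
  circ <- -config$circadian_amplitude *
    cos(2 * pi * (minutes / 60 - config$circadian_phase) / 24)

  steps <- numeric(MINUTES_PER_DAY)
  n_bouts <- stats::rpois(1, config$activity_bout_rate)
  if (n_bouts > 0 && config$activity_bout_len_mean > 0) {
    starts <- floor(stats::runif(n_bouts, 6 * 60, 22 * 60))
    lens <- pmax(1, round(stats::rexp(n_bouts, 1 / config$activity_bout_len_mean)))
    for (b in seq_len(n_bouts)) {
      idx <- starts[b]:min(starts[b] + lens[b] - 1L, MINUTES_PER_DAY - 1L)
      steps[idx + 1L] <- steps[idx + 1L] + stats::rpois(length(idx), 95) + 5
    }
  }
  intensity <- pmin(steps / 100, 1)
  phi <- exp(-1 / config$hr_recovery_tau)
  excess <- as.numeric(stats::filter((1 - phi) * config$activity_hr_gain * intensity,
                                     phi, method = "recursive"))

  hr <- rest + circ + excess +
    stats::rnorm(MINUTES_PER_DAY, 0, config$hr_noise_sd)
  if (profile$beta_blocker_user && stats::runif(1) < 0.5) {
    w0 <- floor(stats::runif(1, 0, MINUTES_PER_DAY - 240))
    hr[(w0 + 1L):(w0 + 240L)] <- hr[(w0 + 1L):(w0 + 240L)] -
      config$beta_blocker_hr_drop
  }
  hr <- pmin(pmax(hr, BPM_MIN), BPM_MAX)

  worn <- stats::runif(MINUTES_PER_DAY) < profile$wear_compliance
  log <- device_day_log(
    profile$subject_id, date,
    heart = data.frame(time = minutes[worn], bpm = hr[worn]),
    steps = data.frame(time = minutes[worn], steps = steps[worn])
  )
  if (detail) {
    attr(log, "components") <- list(rest = rest, circadian = circ,
                                    excess = excess, steps = steps)
  }
  log
}

#' Simulate a clinic visit's on-site measurements
#'
#' On-site resting HR is the true resting HR plus a visit effect
#' (white-coat offset and single-reading noise), making it more variable
#' than the wearable-derived rHR. The Hyperthyroidism Symptom Scale total is
#' generated from a latent linear-in-fT4 score plus noise, clipped to
#' \[0, 40\] before decomposition into 10 items by largest-remainder
#' apportionment under the per-item cap of 4.
#'
#' @inheritParams simulate_day
#' @return A list with `onsite_rhr` (bpm), `hss_items` (10 integers, each
#'   0-4) and `hss_total`.
#' @export
simulate_onsite_visit <- function(profile, true_ft4, config) {
  stopifnot(true_ft4 > 0)
  onsite <- true_resting_hr(profile, true_ft4, config) +
    stats::rnorm(1, config$onsite_offset_mean, config$onsite_offset_sd)
  latent <- config$hss_intercept + config$hss_slope * true_ft4 +
    stats::rnorm(1, 0, config$hss_noise_sd)
  total <- as.integer(round(min(40, max(0, latent))))
  items <- hss_item_split(total)
  list(onsite_rhr = onsite, hss_items = items, hss_total = total)
}

#' Split an HSS total into 10 item scores
#'
#' Largest-remainder apportionment of an integer total in \[0, 40\] across
#' 10 items under the per-item cap of 4: every item gets the floor of the
#' equal quota and the remainder is distributed one point at a time.
#'
#' @param total Integer HSS total in \[0, 40\].
#' @return An integer vector of 10 item scores, each in 0-4, summing to
#'   `total`.
#' @export
hss_item_split <- function(total) {
  stopifnot(length(total) == 1L, total == floor(total), total >= 0, total <= 40)
  base <- total %/% 10L
  rem <- total %% 10L
  items <- rep(as.integer(base), 10L)
  if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1L
  items
}

#' Generate a complete synthetic study
#'
#' Runs the whole generator: samples the cohort, simulates each subject's
#' free T4/TSH course, the on-site visit measurements, and five days of
#' intraday device logs before each visit (the wear window the rest-window
#' algorithm consumes). A true-state sidecar records the noise-free resting
#' HR implied by the linear model for recovery tests. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [generator_config()].
#' @param output_dir Optional directory; when given, device logs are written
#'   as one JSON file per subject-day (via [write_day_log()]),
#'   the visit table as `visits.csv`, the sidecar as `truth.csv`, and a
#'   `manifest.json` recording the seed and a configuration hash.
#' @return (Invisibly when writing) a list with `cohort`, `visits`
#'   (columns `subject_id`, `group`, `visit_index`, `visit_date`,
#'   `ft4_ng_dl`, `tsh_miu_l`, `hss_total`, `onsite_rhr_bpm`), `truth`
#'   (adds `true_rest_hr_bpm`), `logs` (list of [device_day_log()]), and
#'   `config`.
#' @export
generate_study <- function(config, output_dir = NULL) {
  validate_generator_config(config)
  set.seed(as.integer(config$seed))
  cohort <- sample_cohort(config)
  epoch <- as.Date("2024-01-01")
  wear_days <- 5L  # length of the pre-visit window the extractor averages
  visit_dates <- epoch + wear_days +
    (seq_len(config$n_visits) - 1L) * config$days_between_visits

  logs <- list()
  visit_rows <- vector("list", nrow(cohort))
  truth_rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    profile <- as.list(cohort[i, ])
    course <- simulate_ft4_course(profile, config)
    onsite_rhr <- hss_total <- true_rest <- numeric(config$n_visits)
    for (v in seq_len(config$n_visits)) {
      w <- stats::rnorm(1, 0, config$rhr_window_sd)
      for (d in seq_len(wear_days)) {
        day <- visit_dates[v] - wear_days + d - 1L
        logs[[length(logs) + 1L]] <-
          simulate_day(profile, course$ft4[v], day, config, window_dev = w)
      }
      site <- simulate_onsite_visit(profile, course$ft4[v], config)
      onsite_rhr[v] <- site$onsite_rhr
      hss_total[v] <- site$hss_total
      true_rest[v] <- true_resting_hr(profile, course$ft4[v], config)
    }
    visit_rows[[i]] <- tibble::tibble(
      subject_id = profile$subject_id,
      group = profile$group,
      visit_index = course$visit_index,
      visit_date = visit_dates,
      ft4_ng_dl = course$ft4,
      tsh_miu_l = course$tsh,
      hss_total = hss_total,
      onsite_rhr_bpm = onsite_rhr
    )
    truth_rows[[i]] <- tibble::tibble(
      subject_id = profile$subject_id,
      visit_index = course$visit_index,
      ft4_true = course$ft4,
      tsh_true = course$tsh,
      true_rest_hr_bpm = true_rest
    )
  }
  study <- list(
    cohort = cohort,
    visits = dplyr::bind_rows(visit_rows),
    truth = dplyr::bind_rows(truth_rows),
    logs = logs,
    config = config
  )
  if (!is.null(output_dir)) {
    write_study(study, output_dir)
    return(invisible(study))
  }
  study
}

write_study <- function(study, output_dir) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory '", output_dir, "'", call. = FALSE)
  }
  log_dir <- file.path(output_dir, "device_logs")
  dir.create(log_dir, showWarnings = FALSE)
  for (log in study$logs) {
    write_day_log(log, file.path(log_dir, day_log_filename(log)))
  }
  utils::write.csv(study$visits, file.path(output_dir, "visits.csv"),
                   row.names = FALSE)
  utils::write.csv(study$truth, file.path(output_dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    seed = as.integer(study$config$seed),
    config_hash = rlang::hash(study$config),
    n_subjects = nrow(study$cohort),
    n_visits = as.integer(study$config$n_visits),
    n_device_logs = length(study$logs)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Simulate clustered data from a marginal logistic model
#'
#' Generates binary outcomes directly from a marginal logistic model in a
#' standardized predictor, so the population odds ratio per 1-SD is exactly
#' `exp(slope)`. Used for logistic-GEE recovery checks (the thresholded-fT4
#' route has no closed-form marginal OR).
#'
#' @param n_clusters Number of clusters (subjects).
#' @param cluster_size Observations per cluster.
#' @param slope True log-odds slope per unit of the standardized predictor.
#' @param intercept True log-odds intercept.
#' @return A tibble with `cluster_id`, `obs_index`, `z`, `y`.
#' @export
simulate_marginal_logistic <- function(n_clusters, cluster_size = 3L,
                                       slope, intercept = 0) {
  n <- n_clusters * cluster_size
  z <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(intercept + slope * z))
  tibble::tibble(
    cluster_id = rep(seq_len(n_clusters), each = cluster_size),
    obs_index = rep(seq_len(cluster_size), n_clusters),
    z = z, y = y
  )
}
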