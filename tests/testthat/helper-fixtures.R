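# Shared fixtures and independent oracles, all built in code.

# Day log with full step coverage and HR everywhere. `active` is a vector of
# minutes with positive step counts.
flat_log <- function(hr = 70, active = integer(0), subject = "T01",
                     date = "2024-03-01", hr_minutes = 0:1439) {
  steps <- rep(0L, 1440)
  steps[active + 1L] <- 80L
  hr <- rep_len(hr, length(hr_minutes))
  device_day_log(subject, date,
                 heart = data.frame(time = hr_minutes, bpm = hr),
                 steps = data.frame(time = 0:1439, steps = steps))
}

# Brute-force re-derivation of the qualifying-minute rule, independent of
# the package's windowed implementation: direct per-minute scan.
brute_force_qualifying <- function(log, lookback = 15L) {
  hr <- rep(NA_real_, 1440); hr[log$heart$time + 1L] <- log$heart$bpm
  st <- rep(NA_real_, 1440); st[log$steps$time + 1L] <- log$steps$steps
  out <- integer(0)
  for (m in 0:1439) {
    if (is.na(hr[m + 1L]) || m < lookback) next
    win <- st[(m - lookback + 1L):(m + 1L)]
    if (!anyNA(win) && all(win == 0)) out <- c(out, m)
  }
  out
}

brute_force_daily_median <- function(log, params = rest_params()) {
  qual <- brute_force_qualifying(log, params$lookback_min)
  hr <- rep(NA_real_, 1440); hr[log$heart$time + 1L] <- log$heart$bpm
  vals <- hr[qual + 1L]
  if (length(vals) < params$min_rest_minutes_per_day) return(NA_real_)
  sort_vals <- sort(vals)
  n <- length(sort_vals)
  if (n %% 2 == 1) sort_vals[(n + 1) / 2] else
    (sort_vals[n / 2] + sort_vals[n / 2 + 1]) / 2
}

# Random log with partial coverage (for round-trip and oracle equivalence).
random_log <- function(subject = "R01", date = "2024-02-10") {
  n_hr <- sample(0:200, 1)
  n_st <- sample(0:400, 1)
  hr_t <- sort(sample(0:1439, n_hr))
  st_t <- sort(sample(0:1439, n_st))
  device_day_log(subject, date,
                 heart = data.frame(time = hr_t,
                                    bpm = round(runif(n_hr, 40, 180), 2)),
                 steps = data.frame(time = st_t,
                                    steps = rpois(n_st, 2)))
}

# Generator configuration with every stochastic HR component switched off:
# minute HR is exactly the linear resting level.
quiet_config <- function(...) {
  defaults <- list(
    subject_sd = 0, rhr_window_sd = 0, circadian_amplitude = 0,
    activity_bout_rate = 0, hr_noise_sd = 0, wear_prob = 1,
    onsite_offset_mean = 0, onsite_offset_sd = 0,
    ft4_visit_sd = 0, ft4_control_visit_sd = 0,
    ft4_baseline_thyro_sd = 0, ft4_control_sd = 0)
  do.call(generator_config, utils::modifyList(defaults, list(...)))
}

# Hand-written Newton-Raphson logistic maximum likelihood (first-principles
# oracle, independent of glm and of the GEE code path).
logistic_ml_oracle <- function(y, X, tol = 1e-12, maxit = 100) {
  beta <- numeric(ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- p * (1 - p)
    score <- drop(crossprod(X, y - p))
    info <- crossprod(X * W, X)
    delta <- solve(info, score)
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
  }
  beta
}

# Exact two-sided Fisher probability for a 2x2 table by enumerating all
# tables with the observed margins (probability-mass rule).
fisher_enumeration_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_obs <- tab[1, 1]
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(a_range, c1, n - c1, r1)
  p_obs <- dhyper(a_obs, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
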