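# End-to-end orchestration: simulate -> extract -> score -> fit -> report.
# Every stage works from plain-text intermediates (JSON device logs and CSV
# tables) so it can be re-run in isolation with identical results.

#' Full-pipeline run configuration
#'
#' @param generator A [generator_config()].
#' @param rest A [rest_params()].
#' @param refs A [ref_ranges()].
#' @param analysis_sets Character subset of
#'   `c("thyrotoxic_only", "all_participants")`; each association table is
#'   produced once per set.
#' @param output_dir Directory for written artifacts (`NULL` keeps results
#'   in memory).
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       rest = rest_params(),
                       refs = ref_ranges(),
                       analysis_sets = c("thyrotoxic_only", "all_participants"),
                       output_dir = NULL) {
  analysis_sets <- match.arg(analysis_sets,
                             c("thyrotoxic_only", "all_participants"),
                             several.ok = TRUE)
  structure(list(generator = generator, rest = rest, refs = refs,
                 analysis_sets = analysis_sets, output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' The file may carry top-level `generator`, `rest`, `refs`,
#' `analysis_sets` and `output_dir` entries; each key under the first three
#' overrides the corresponding constructor default.
#'
#' @param path Path to a YAML configuration file.
#' @param seed Optional seed overriding the file's generator seed.
#' @param output_dir Optional output directory overriding the file's.
#' @return A [run_config()].
#' @export
run_config_from_file <- function(path, seed = NULL, output_dir = NULL) {
  raw <- yaml::read_yaml(path)
  gen_args <- raw$generator %||% list()
  if (!is.null(seed)) gen_args$seed <- as.integer(seed)
  run_config(
    generator = do.call(generator_config, gen_args),
    rest = do.call(rest_params, raw$rest %||% list()),
    refs = do.call(ref_ranges, raw$refs %||% list()),
    analysis_sets = raw$analysis_sets %||% c("thyrotoxic_only", "all_participants"),
    output_dir = output_dir %||% raw$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate-stage runner
#'
#' Generates the synthetic study and, when `config$output_dir` is set,
#' writes device logs, visit table, true-state sidecar and a manifest
#' recording the seed and configuration hash.
#'
#' @param config A [run_config()].
#' @return The study list from [generate_study()].
#' @export
run_simulate <- function(config) {
  out <- if (is.null(config$output_dir)) NULL else
    file.path(config$output_dir, "dataset")
  generate_study(config$generator, output_dir = out)
}

#' Extract-stage runner
#'
#' Computes wearable rHR for every visit and augments the visit table with
#' the derived clinical columns.
#'
#' @param study A study list from [run_simulate()] / [generate_study()], or
#'   a dataset directory written by it.
#' @param config A [run_config()].
#' @return A list with the augmented `visits` table and the `daily` rHR
#'   table.
#' @export
run_extract <- function(study, config) {
  if (is.character(study)) {
    visits <- tibble::as_tibble(
      utils::read.csv(file.path(study, "visits.csv"),
                      colClasses = c(visit_date = "Date")))
    logs <- file.path(study, "device_logs")
  } else {
    visits <- study$visits
    logs <- study$logs
  }
  extracted <- extract_all(logs, visits, config$rest)
  extracted$visits <- augment_visits(extracted$visits, config$refs)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(extracted$daily,
                     file.path(config$output_dir, "daily_rhr.csv"),
                     row.names = FALSE)
    utils::write.csv(extracted$visits,
                     file.path(config$output_dir, "visits_augmented.csv"),
                     row.names = FALSE)
  }
  extracted
}

analysis_set_rows <- function(visits, set) {
  if (set == "thyrotoxic_only") visits[visits$group == "thyrotoxic", ] else visits
}

pipeline_parameters <- c(hss = "hss_total", onsite_rhr = "onsite_rhr_bpm",
                         wd_rhr = "wd_rhr")

#' Analyze-stage runner
#'
#' Produces the report tables: baseline two-group comparisons, per-visit
#' trajectories with repeated-measures tests, the standardized linear-GEE
#' association table, the standardized logistic-GEE odds-ratio table, and
#' per-visit mean/CI data for plotting. Association tables are computed per
#' analysis set, standardizing each parameter over that set's pooled
#' visit-level observations.
#'
#' @param extracted Output of [run_extract()].
#' @param config A [run_config()].
#' @return A list of tibbles: `baseline`, `trajectory`, `linear_gee`,
#'   `logistic_gee`, `figure_data`.
#' @export
run_analyze <- function(extracted, config) {
  visits <- extracted$visits
  frac_missing <- mean(is.na(visits$wd_rhr))
  if (frac_missing > 0.2) {
    warning(sprintf("wearable rHR missing for %d of %d visits (%.0f%%)",
                    sum(is.na(visits$wd_rhr)), nrow(visits),
                    100 * frac_missing), call. = FALSE)
  }

  base <- visits[visits$visit_index == 1, ]
  baseline_vars <- c(ft4_ng_dl = "student_t", onsite_rhr_bpm = "student_t",
                     wd_rhr = "student_t", hss_total = "mann_whitney",
                     tsh_miu_l = "mann_whitney")
  baseline <- dplyr::bind_rows(lapply(names(baseline_vars), function(v) {
    a <- base[[v]][base$group == "thyrotoxic"]
    b <- base[[v]][base$group == "control"]
    res <- baseline_comparison(a[is.finite(a)], b[is.finite(b)],
                               kind = baseline_vars[[v]])
    tibble::tibble(variable = v,
                   thyrotoxic_mean = mean(a, na.rm = TRUE),
                   thyrotoxic_sd = stats::sd(a[is.finite(a)]),
                   control_mean = mean(b, na.rm = TRUE),
                   control_sd = stats::sd(b[is.finite(b)]),
                   test = baseline_vars[[v]], p_value = res$p_value)
  }))

  traj_vars <- c(ft4_ng_dl = "rm_anova_gg", onsite_rhr_bpm = "rm_anova_gg",
                 wd_rhr = "rm_anova_gg", hss_total = "friedman",
                 tsh_miu_l = "friedman")
  trajectory <- dplyr::bind_rows(lapply(names(traj_vars), function(v) {
    dplyr::bind_rows(lapply(unique(visits$group), function(g) {
      gv <- visits[visits$group == g, ]
      per_visit <- dplyr::summarise(
        dplyr::group_by(gv, .data$visit_index),
        mean = mean(.data[[v]], na.rm = TRUE),
        sd = stats::sd(.data[[v]][is.finite(.data[[v]])]),
        n = sum(is.finite(.data[[v]])), .groups = "drop")
      wide <- matrix(gv[[v]], ncol = max(gv$visit_index), byrow = TRUE)
      res <- suppressMessages(repeated_measures_tests(wide, traj_vars[[v]]))
      tibble::tibble(variable = v, group = g,
                     visit_index = per_visit$visit_index,
                     mean = per_visit$mean, sd = per_visit$sd,
                     n = per_visit$n, test = traj_vars[[v]],
                     p_value = res$p_value)
    }))
  }))

  assoc <- function(set, logistic) {
    d <- analysis_set_rows(visits, set)
    dplyr::bind_rows(lapply(names(pipeline_parameters), function(pname) {
      col <- pipeline_parameters[[pname]]
      dd <- d[is.finite(d[[col]]) & is.finite(d$ft4_ng_dl), ]
      sc <- standardize(dd[[col]], variable = pname)
      dd$z <- sc$z
      fit <- tryCatch({
        if (logistic) {
          dd$yy <- as.numeric(dd$thyrotoxic_binary)
          fit_logistic_gee(dd, "yy", "z", "subject_id")
        } else {
          fit_linear_gee(dd, "ft4_ng_dl", "z", "subject_id")
        }
      }, error = function(e) {
        warning(sprintf("%s GEE for %s (%s) failed: %s",
                        if (logistic) "logistic" else "linear",
                        pname, set, conditionMessage(e)), call. = FALSE)
        NULL
      })
      if (is.null(fit)) {
        return(tibble::tibble(
          analysis_set = set, parameter = pname, sd_unit = sc$sd,
          estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
          p_value = NA_real_, alpha_hat = NA_real_,
          n_clusters = NA_integer_, n_obs = NA_integer_))
      }
      tibble::tibble(
        analysis_set = set, parameter = pname, sd_unit = sc$sd,
        estimate = if (logistic) fit$or_value else fit$estimate,
        ci_low = if (logistic) fit$or_ci95[1] else fit$ci95_low,
        ci_high = if (logistic) fit$or_ci95[2] else fit$ci95_high,
        p_value = fit$p_value, alpha_hat = fit$alpha_hat,
        n_clusters = fit$n_clusters, n_obs = fit$n_obs)
    }))
  }
  linear_gee <- dplyr::bind_rows(lapply(config$analysis_sets, assoc,
                                        logistic = FALSE))
  logistic_gee <- dplyr::bind_rows(lapply(config$analysis_sets, assoc,
                                          logistic = TRUE))

  fig_vars <- c("ft4_ng_dl", "hss_total", "onsite_rhr_bpm", "wd_rhr")
  figure_data <- dplyr::bind_rows(lapply(fig_vars, function(v) {
    dplyr::summarise(
      dplyr::group_by(visits, .data$group, .data$visit_index),
      variable = v,
      mean = mean(.data[[v]], na.rm = TRUE),
      ci_low = mean - 1.96 * stats::sd(.data[[v]][is.finite(.data[[v]])]) /
        sqrt(sum(is.finite(.data[[v]]))),
      ci_high = mean + 1.96 * stats::sd(.data[[v]][is.finite(.data[[v]])]) /
        sqrt(sum(is.finite(.data[[v]]))),
      n = sum(is.finite(.data[[v]])), .groups = "drop")
  }))

  list(baseline = baseline, trajectory = trajectory,
       linear_gee = linear_gee, logistic_gee = logistic_gee,
       figure_data = figure_data)
}

#' Report-stage runner
#'
#' Writes the analysis tables as comma-separated files.
#'
#' @param analysis Output of [run_analyze()].
#' @param output_dir Destination directory.
#' @return `output_dir`, invisibly.
#' @export
run_report <- function(analysis, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(analysis)) {
    utils::write.csv(analysis[[name]],
                     file.path(output_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  }
  invisible(output_dir)
}

#' Run the whole pipeline
#'
#' Simulate, extract, analyze and (when `config$output_dir` is set) report.
#'
#' @param config A [run_config()].
#' @return A list with `study`, `extracted` and `analysis`.
#' @export
run_all <- function(config) {
  study <- run_simulate(config)
  extracted <- run_extract(study, config)
  analysis <- run_analyze(extracted, config)
  if (!is.null(config$output_dir)) {
    run_report(analysis, file.path(config$output_dir, "report"))
  }
  list(study = study, extracted = extracted, analysis = analysis)
}
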