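# Descriptive group comparisons and repeated-measures tests: the standard
# two-group tests for baseline tables and the within-subject tests for
# per-visit trajectories. Two-group and rank tests delegate to base R
# (stats::t.test and friends); repeated-measures ANOVA with the
# Greenhouse-Geisser sphericity correction is computed here.

test_result <- function(test_name, statistic, p_value, df = NULL,
                        epsilon = NULL) {
  structure(list(test_name = test_name, statistic = statistic,
                 p_value = p_value, df = df, epsilon = epsilon),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %s, p = %.4g\n", x$test_name,
              format(x$statistic, digits = 4), x$p_value))
  invisible(x)
}

#' Two-group baseline comparison
#'
#' Two-sided tests comparing a characteristic between two groups:
#' `"student_t"` (pooled variance), `"mann_whitney"` (normal approximation
#' with tie correction, no continuity correction), `"chi_square"` (no Yates
#' correction), or `"fisher_exact"` (two-sided by summing hypergeometric
#' probabilities no larger than the observed table's).
#'
#' @param x,y Numeric group vectors for `student_t` / `mann_whitney`. For
#'   `chi_square` / `fisher_exact`, `x` is a contingency matrix of counts
#'   and `y` is ignored.
#' @param kind One of `"student_t"`, `"mann_whitney"`, `"chi_square"`,
#'   `"fisher_exact"`.
#' @return A `test_result` with the test statistic, two-sided p-value and
#'   degrees of freedom where applicable (Fisher's exact test has no
#'   statistic; `NA` is recorded).
#' @export
baseline_comparison <- function(x, y = NULL,
                                kind = c("student_t", "mann_whitney",
                                         "chi_square", "fisher_exact")) {
  kind <- switch(match.arg(kind),
    student_t = {
      if (length(x) < 2L || length(y) < 2L) {
        stop("Student t test needs at least 2 observations per group",
             call. = FALSE)
      }
      tt <- stats::t.test(x, y, var.equal = TRUE)
      return(test_result("student_t", unname(tt$statistic), tt$p.value,
                         df = unname(tt$parameter)))
    },
    mann_whitney = {
      if (!length(x) || !length(y)) {
        stop("Mann-Whitney test needs non-empty groups", call. = FALSE)
      }
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
      return(test_result("mann_whitney", unname(wt$statistic), wt$p.value))
    },
    chi_square = {
      ct <- suppressWarnings(stats::chisq.test(as.matrix(x), correct = FALSE))
      return(test_result("chi_square", unname(ct$statistic), ct$p.value,
                         df = unname(ct$parameter)))
    },
    fisher_exact = {
      ft <- stats::fisher.test(as.matrix(x))
      return(test_result("fisher_exact", NA_real_, ft$p.value))
    }
  )
}

# Greenhouse-Geisser epsilon from the sample covariance of the k repeated
# measures: eps = tr(S_c)^2 / ((k-1) * sum(S_c^2)) with S_c the
# double-centered covariance matrix. eps = 1 exactly under sphericity.
gg_epsilon <- function(S) {
  k <- ncol(S)
  rm_ <- rowMeans(S)
  Sc <- S - outer(rm_, rep(1, k)) - outer(rep(1, k), rm_) + mean(S)
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Repeated-measures tests across visits
#'
#' Within-subject tests of change across visits on a complete-case
#' subjects-by-visits matrix: `"rm_anova_gg"` is the one-way
#' repeated-measures ANOVA F with Greenhouse-Geisser epsilon-adjusted
#' degrees of freedom; `"friedman"` is the Friedman rank test
#' (via [stats::friedman.test()]).
#'
#' @param values Numeric matrix, one row per subject and one column per
#'   visit. Rows with any missing value are dropped (listwise deletion)
#'   with a message.
#' @param kind `"rm_anova_gg"` or `"friedman"`.
#' @return A `test_result`; for `rm_anova_gg` it carries the adjusted
#'   degrees of freedom and the epsilon estimate.
#' @export
repeated_measures_tests <- function(values, kind = c("rm_anova_gg", "friedman")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    message(sum(!complete), " incomplete subject(s) dropped (listwise deletion)")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values); k <- ncol(values)
  if (n < 2L || k < 2L) {
    stop("repeated-measures tests need at least 2 complete subjects and 2 visits",
         call. = FALSE)
  }
  if (kind == "friedman") {
    ft <- stats::friedman.test(values)
    stat <- unname(ft$statistic); p <- ft$p.value
    if (is.nan(stat) && all(apply(values, 1, function(r) diff(range(r))) == 0)) {
      stat <- 0; p <- 1   # every subject constant across visits: no change
    }
    return(test_result("friedman", stat, p, df = unname(ft$parameter)))
  }
  grand <- mean(values)
  ss_subj <- k * sum((rowMeans(values) - grand)^2)
  ss_visit <- n * sum((colMeans(values) - grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_visit
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f_stat <- (ss_visit / df1) / (ss_err / df2)
  eps <- gg_epsilon(stats::cov(values))
  p <- stats::pf(f_stat, eps * df1, eps * df2, lower.tail = FALSE)
  # no within-subject variability at all: no evidence of change
  if (ss_err == 0 && ss_visit == 0) {
    f_stat <- 0; p <- 1
  }
  test_result("rm_anova_gg", f_stat, p, df = c(eps * df1, eps * df2),
              epsilon = eps)
}
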