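# Generalized estimating equations for clustered visit data.
#
# Solves sum_i D_i' V_i^-1 (y_i - mu_i) = 0 by Fisher scoring, re-estimating
# the working-correlation parameter by the moment estimator from Pearson
# residuals between coefficient updates. Variance is the robust sandwich
# estimator; confidence intervals are Wald with z = 1.96. The exchangeable
# working-correlation inverse uses the closed form
#   R^-1 = 1/(1-a) * (I - a/(1+(m-1)a) * J).

gee_families <- list(
  gaussian = list(
    linkinv = identity,
    mu_eta = function(eta) rep(1, length(eta)),
    variance = function(mu) rep(1, length(mu))
  ),
  binomial = list(
    linkinv = stats::plogis,
    mu_eta = function(eta) {
      p <- stats::plogis(eta)
      p * (1 - p)
    },
    variance = function(mu) mu * (1 - mu)
  )
)

gee_fit <- function(y, X, id, family = c("gaussian", "binomial"),
                    corstr = c("exchangeable", "independence"),
                    maxit = 100L, tol = 1e-10) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  fam <- gee_families[[family]]
  ord <- order(id)
  y <- y[ord]; X <- X[ord, , drop = FALSE]; id <- id[ord]
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix (rank deficient)", call. = FALSE)
  clusters <- split(seq_len(n), id)
  m <- lengths(clusters)
  if (length(clusters) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (family == "binomial" && length(unique(y)) < 2L) {
    stop("binary outcome has a single class; logistic GEE is degenerate",
         call. = FALSE)
  }

  beta <- numeric(p)
  if ("(Intercept)" %in% colnames(X)) {
    mu0 <- mean(y)
    beta[match("(Intercept)", colnames(X))] <-
      if (family == "binomial") stats::qlogis(min(max(mu0, 1e-3), 1 - 1e-3)) else mu0
  }
  alpha <- 0
  phi <- 1
  npairs <- sum(m * (m - 1) / 2)

  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- fam$linkinv(eta)
    a_var <- pmax(fam$variance(mu), 1e-10)
    e <- (y - mu) / sqrt(a_var)
    phi <- max(sum(e^2) / (n - p), 1e-12)
    if (corstr == "exchangeable" && npairs > p) {
      cross <- vapply(clusters, function(idx) {
        s <- sum(e[idx])
        (s^2 - sum(e[idx]^2)) / 2
      }, numeric(1))
      alpha <- sum(cross) / ((npairs - p) * phi)
      alpha <- min(max(alpha, -1 / (max(m) - 1) + 1e-6), 0.999)
    }
    H <- matrix(0, p, p)
    U <- numeric(p)
    score_list <- vector("list", length(clusters))
    for (k in seq_along(clusters)) {
      idx <- clusters[[k]]
      mk <- length(idx)
      sa <- sqrt(a_var[idx])
      Dk <- fam$mu_eta(eta[idx]) * X[idx, , drop = FALSE]
      rk <- y[idx] - mu[idx]
      # V^-1 x via the closed-form exchangeable inverse
      vinv <- function(x) {
        xs <- x / sa
        out <- if (mk > 1L && alpha != 0) {
          (xs - (alpha / (1 + (mk - 1) * alpha)) * sum(xs)) / (1 - alpha)
        } else {
          xs
        }
        out / (sa * phi)
      }
      Vi_D <- apply(Dk, 2, vinv)
      if (mk == 1L) Vi_D <- matrix(Vi_D, nrow = 1L)
      H <- H + crossprod(Dk, Vi_D)
      sk <- drop(crossprod(Vi_D, rk))
      U <- U + sk
      score_list[[k]] <- sk
    }
    delta <- tryCatch(solve(H, U), error = function(e)
      stop("singular working information in GEE update", call. = FALSE))
    beta <- beta + delta
    if (max(abs(delta)) < tol) break
    if (iter == maxit) {
      stop(sprintf(paste0("GEE did not converge in %d iterations ",
                          "(last max coefficient update %.3g)"),
                   maxit, max(abs(delta))), call. = FALSE)
    }
  }

  M <- Reduce(`+`, lapply(score_list, tcrossprod))
  Hinv <- solve(H)
  vcov <- Hinv %*% M %*% Hinv
  list(coefficients = stats::setNames(beta, colnames(X)), vcov = vcov,
       alpha_hat = alpha, phi = phi, family = family, corstr = corstr,
       n_clusters = length(clusters), n_obs = n, iterations = iter)
}

gee_summarize <- function(fit, term, logistic = FALSE) {
  est <- fit$coefficients[[term]]
  se <- sqrt(diag(fit$vcov))[[match(term, names(fit$coefficients))]]
  ci <- est + c(-1, 1) * 1.96 * se
  zstat <- if (se > 0) est / se else sign(est) * Inf
  out <- list(
    term = term,
    estimate = est,
    robust_se = se,
    ci95_low = ci[1],
    ci95_high = ci[2],
    p_value = 2 * stats::pnorm(abs(zstat), lower.tail = FALSE),
    working_correlation = fit$corstr,
    alpha_hat = fit$alpha_hat,
    n_clusters = fit$n_clusters,
    n_obs = fit$n_obs,
    coefficients = fit$coefficients,
    vcov = fit$vcov
  )
  if (logistic) {
    out$or_value <- exp(est)
    out$or_ci95 <- exp(ci)
  }
  structure(out, class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("GEE fit (%s working correlation, %d clusters, %d obs)\n",
              x$working_correlation, x$n_clusters, x$n_obs))
  cat(sprintf("  %s: estimate %.4f (robust SE %.4f), 95%% CI %.4f-%.4f, p = %.3g\n",
              x$term, x$estimate, x$robust_se, x$ci95_low, x$ci95_high,
              x$p_value))
  if (!is.null(x$or_value)) {
    cat(sprintf("  OR per 1 SD: %.3f (95%% CI %.3f-%.3f)\n",
                x$or_value, x$or_ci95[1], x$or_ci95[2]))
  }
  invisible(x)
}

#' Linear GEE of a continuous outcome on one predictor
#'
#' Fits the marginal linear model (identity link, Gaussian variance) by
#' generalized estimating equations with the chosen working correlation and
#' reports cluster-robust (sandwich) inference for the predictor. With a
#' standardized predictor the coefficient is the effect per 1 SD.
#'
#' @param data A data frame in long format.
#' @param outcome,predictor,cluster Column names (strings) of the continuous
#'   outcome, the predictor and the cluster (subject) identifier.
#' @param working_correlation `"exchangeable"` (default; repeated visits per
#'   subject) or `"independence"`.
#' @return An object of class `gee_fit`: `estimate`, `robust_se`,
#'   `ci95_low`/`ci95_high`, `p_value`, `working_correlation`, `alpha_hat`,
#'   `n_clusters`, `n_obs`.
#' @export
fit_linear_gee <- function(data, outcome, predictor, cluster,
                           working_correlation = c("exchangeable", "independence")) {
  working_correlation <- match.arg(working_correlation)
  d <- data[stats::complete.cases(data[, c(outcome, predictor, cluster)]), ]
  X <- cbind("(Intercept)" = 1, as.numeric(d[[predictor]]))
  colnames(X)[2] <- predictor
  fit <- gee_fit(as.numeric(d[[outcome]]), X, d[[cluster]],
                 family = "gaussian", corstr = working_correlation)
  gee_summarize(fit, predictor, logistic = FALSE)
}

#' Binary logistic GEE of a binary outcome on one predictor
#'
#' Same estimating-equation scheme with logit link and Bernoulli variance;
#' reports the odds ratio `exp(estimate)` per unit (per 1 SD for a
#' standardized predictor) with a sandwich Wald CI.
#'
#' @inheritParams fit_linear_gee
#' @param outcome Column name of the binary (0/1 or logical) outcome; both
#'   classes must be present.
#' @return An object of class `gee_fit` with additional `or_value` and
#'   `or_ci95`.
#' @export
fit_logistic_gee <- function(data, outcome, predictor, cluster,
                             working_correlation = c("exchangeable", "independence")) {
  working_correlation <- match.arg(working_correlation)
  d <- data[stats::complete.cases(data[, c(outcome, predictor, cluster)]), ]
  y <- as.numeric(d[[outcome]])
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  X <- cbind("(Intercept)" = 1, as.numeric(d[[predictor]]))
  colnames(X)[2] <- predictor
  fit <- gee_fit(y, X, d[[cluster]],
                 family = "binomial", corstr = working_correlation)
  gee_summarize(fit, predictor, logistic = TRUE)
}
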