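# Statistical layer: correlation matrices across densitometric features,
# Poisson GLMs of GAP points on each feature (ranked by log-likelihood),
# and gamma log-link models of FVC/DLco on a feature.
#
# Fitting is iteratively reweighted least squares (stats::glm) with
# deviance tolerance 1e-8 and at most 100 iterations. Slope p-values are
# Wald tests; a likelihood-ratio p-value is also reported. For the gamma
# family the log-likelihood is evaluated at the maximum-likelihood shape
# (profiled given the fitted means, on which the coefficient estimates do
# not depend), so reported log-likelihoods are full-ML quantities.

GLM_CONTROL <- function() stats::glm.control(epsilon = 1e-8, maxit = 100)

new_glm_fit <- function(fit, family, response_name, feature, threshold,
                        log_lik, se, p_wald, p_lrt, shape = NULL) {
  beta <- stats::coef(fit)
  structure(list(
    family = family, link = "log",
    response = response_name, feature = feature, threshold = threshold,
    coef = beta, se = se, exp_coef = exp(beta[2]),
    p_value = p_wald, p_lrt = p_lrt,
    log_lik = log_lik, shape = shape, n = length(fit$y),
    fitted = stats::fitted(fit), y = fit$y,
    converged = fit$converged
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("%s(log) GLM: %s ~ %s [threshold %s], n = %d\n",
              x$family, x$response, x$feature,
              x$threshold %||% "-", x$n))
  cat(sprintf("  beta = %.5f (SE %.5f), exp(beta) = %.4f, Wald p = %.4g\n",
              x$coef[2], x$se[2], x$exp_coef, x$p_value))
  cat(sprintf("  log-lik = %.4f\n", x$log_lik))
  invisible(x)
}

check_feature_column <- function(tbl, nm) {
  if (!nm %in% names(tbl)) stopf("column '%s' not found in feature table", nm)
  x <- tbl[[nm]]
  if (!is.numeric(x) || anyNA(x)) stopf("column '%s' must be numeric without NA", nm)
  x
}

subset_threshold <- function(tbl, threshold) {
  if (is.null(threshold) || !"threshold_hu" %in% names(tbl)) return(tbl)
  tbl[tbl$threshold_hu == threshold, , drop = FALSE]
}

#' Poisson model of GAP response on one densitometric feature
#'
#' Maximum-likelihood Poisson regression with log link of the GAP response
#' (points 0-8 by default, or stage) on a single explanatory feature.
#'
#' @param tbl data.frame with one row per patient (optionally per patient
#'   and threshold; see `threshold`), containing the feature column and the
#'   response column.
#' @param feature name of the explanatory column.
#' @param threshold optional upper HU threshold used to subset a long table
#'   with a `threshold_hu` column; also recorded in the fit.
#' @param response name of the response column (default `"gap_points"`).
#' @return a `glm_fit` with coefficients, SEs, Wald and LRT p-values for
#'   the slope, and the maximized log-likelihood.
#' @export
fit_poisson_gap <- function(tbl, feature, threshold = NULL,
                            response = "gap_points") {
  tbl <- subset_threshold(tbl, threshold)
  y <- check_feature_column(tbl, response)
  x <- check_feature_column(tbl, feature)
  if (length(y) < 5L) stopf("need at least 5 observations, got %d", length(y))
  if (any(y < 0) || any(y != round(y)))
    stopf("Poisson response '%s' must be non-negative integers", response)
  fit <- stats::glm(y ~ x, family = stats::poisson(link = "log"),
                    control = GLM_CONTROL())
  if (!fit$converged) stopf("Poisson IRLS did not converge in 100 iterations")
  mu <- stats::fitted(fit)
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  z <- sm$coefficients["x", "z value"]
  p_wald <- 2 * stats::pnorm(-abs(z))
  null_fit <- stats::glm(y ~ 1, family = stats::poisson(), control = GLM_CONTROL())
  ll0 <- sum(stats::dpois(y, stats::fitted(null_fit), log = TRUE))
  p_lrt <- stats::pchisq(2 * (ll - ll0), df = 1, lower.tail = FALSE)
  new_glm_fit(fit, "poisson", response, feature, threshold, ll, se,
              p_wald, p_lrt)
}

# ML shape for a gamma GLM given fitted means: solves
#   log(k) - digamma(k) = mean(y/mu - log(y/mu) - 1)
gamma_shape_ml <- function(y, mu) {
  s <- mean(y / mu - log(y / mu)) - 1
  # log(k) - digamma(k) ~ 1/(2k) for large k: near-perfect fits get the
  # asymptotic solution instead of a root search
  if (s < 1e-9) return(1 / (2 * max(s, 1e-300)))
  f <- function(logk) {
    k <- exp(logk)
    log(k) - digamma(k) - s
  }
  exp(stats::uniroot(f, c(-10, 25), tol = 1e-12)$root)
}

gamma_loglik <- function(y, mu, shape) {
  sum(stats::dgamma(y, shape = shape, scale = mu / shape, log = TRUE))
}

#' Gamma log-link model of a positive response on one feature
#'
#' Gamma GLM with logarithmic link (the conventional choice for strictly
#' positive, continuous lung-function outcomes such as FVC or DLco
#' %predicted). Reports the slope on the link (natural-log) scale, its SE,
#' the exponentiated slope, Wald and LRT p-values, and the log-likelihood
#' at the ML shape.
#'
#' @inheritParams fit_poisson_gap
#' @param response name of the positive continuous response column
#'   (e.g. `"fvc_pct_pred"` or `"dlco_pct_pred"`).
#' @return a `glm_fit`.
#' @export
fit_gamma_log <- function(tbl, feature, threshold = NULL,
                          response = "fvc_pct_pred") {
  tbl <- subset_threshold(tbl, threshold)
  y <- check_feature_column(tbl, response)
  x <- check_feature_column(tbl, feature)
  if (length(y) < 5L) stopf("need at least 5 observations, got %d", length(y))
  if (any(y <= 0)) {
    i <- which(y <= 0)[1]
    stopf("gamma response '%s' must be strictly positive (row %d is %g)",
          response, i, y[i])
  }
  fit <- stats::glm(y ~ x, family = stats::Gamma(link = "log"),
                    control = GLM_CONTROL())
  if (!fit$converged) stopf("gamma IRLS did not converge in 100 iterations")
  mu <- stats::fitted(fit)
  shape <- gamma_shape_ml(y, mu)
  ll <- gamma_loglik(y, mu, shape)
  sm <- summary(fit, dispersion = 1 / shape)
  se <- sm$coefficients[, "Std. Error"]
  z <- sm$coefficients["x", 1] / se["x"]
  p_wald <- 2 * stats::pnorm(-abs(z))
  null_fit <- stats::glm(y ~ 1, family = stats::Gamma(link = "log"),
                         control = GLM_CONTROL())
  mu0 <- stats::fitted(null_fit)
  shape0 <- gamma_shape_ml(y, mu0)
  p_lrt <- stats::pchisq(2 * (ll - gamma_loglik(y, mu0, shape0)),
                         df = 1, lower.tail = FALSE)
  new_glm_fit(fit, "gamma", response, feature, threshold, ll, se,
              p_wald, p_lrt, shape = shape)
}

#' Pearson correlation matrix of features at one threshold
#'
#' Pairwise Pearson correlations on complete cases. At the -200 HU
#' threshold the high-attenuation area (HAA\%) is dropped automatically:
#' its band lies wholly outside the lung volume there and the feature is
#' identically zero. Zero-variance features yield `NA` rows/columns with a
#' warning.
#'
#' @param tbl long feature table with a `threshold_hu` column (or an
#'   already-subset table).
#' @param threshold upper HU threshold to subset on (optional).
#' @param features character vector of feature column names.
#' @return object of class `correlation_matrix`: list with `labels` and the
#'   symmetric matrix `rho`.
#' @export
correlation_matrix <- function(tbl, threshold = NULL,
                               features = c("nl_pct", "pff_pct", "haa_a_pct",
                                            "kurtosis", "haa_pct", "laa_pct")) {
  tbl <- subset_threshold(tbl, threshold)
  if (!is.null(threshold) && threshold == -200L)
    features <- setdiff(features, "haa_pct")
  X <- sapply(features, function(f) check_feature_column(tbl, f))
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L) stopf("need at least 3 complete rows, got %d", nrow(X))
  sds <- apply(X, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(X))
  if (any(sds == 0)) {
    bad <- features[sds == 0]
    warnf("zero-variance feature(s): %s (correlations undefined)",
          paste(bad, collapse = ", "))
    rho[sds == 0, ] <- NA_real_
    rho[, sds == 0] <- NA_real_
  }
  diag(rho) <- ifelse(sds == 0, NA_real_, 1)
  structure(list(labels = features, rho = rho), class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  print(round(x$rho, 2))
  invisible(x)
}

#' Rank fitted models by log-likelihood
#'
#' Sorts fits (which must share the response and sample size) by
#' log-likelihood, descending, and flags pairs differing by at least
#' `min_diff` points of log-likelihood as "distinguishable" -- the
#' conventional minimum to affirm that two single-feature models do not
#' carry the same information.
#'
#' @param fits list of `glm_fit` objects.
#' @param min_diff log-likelihood difference declaring two models
#'   distinguishable (default 1).
#' @return object of class `loglik_ranking`: data.frame `table` (feature,
#'   threshold, p_value, log_lik, delta_from_best, distinguishable_from_best)
#'   plus the logical pairwise matrix `distinguishable`.
#' @export
rank_by_loglik <- function(fits, min_diff = 1) {
  if (!length(fits)) stopf("no fits to rank")
  resp <- vapply(fits, function(f) f$response, character(1))
  ns <- vapply(fits, function(f) f$n, numeric(1))
  if (length(unique(resp)) != 1L)
    stopf("fits mix responses: %s", paste(unique(resp), collapse = ", "))
  if (length(unique(ns)) != 1L)
    stopf("fits have different sample sizes")
  ll <- vapply(fits, function(f) f$log_lik, numeric(1))
  ord <- order(ll, decreasing = TRUE)
  tab <- data.frame(
    feature = vapply(fits, function(f) f$feature, character(1))[ord],
    threshold = vapply(fits, function(f)
      as.integer(f$threshold %||% NA_integer_), integer(1))[ord],
    p_value = vapply(fits, function(f) f$p_value, numeric(1))[ord],
    log_lik = ll[ord],
    row.names = NULL)
  tab$delta_from_best <- tab$log_lik[1] - tab$log_lik
  tab$distinguishable_from_best <- tab$delta_from_best >= min_diff
  m <- abs(outer(tab$log_lik, tab$log_lik, `-`)) >= min_diff
  dimnames(m) <- list(tab$feature, tab$feature)
  structure(list(table = tab, distinguishable = m, min_diff = min_diff),
            class = "loglik_ranking")
}

#' @export
print.loglik_ranking <- function(x, ...) {
  print(x$table, digits = 4)
  invisible(x)
}

#' Poisson model comparison across features and thresholds
#'
#' Fits [fit_poisson_gap()] for every feature at every threshold and
#' returns a wide report: one row per feature, columns `p` and `loglik`
#' per threshold.
#'
#' @param tbl long feature table (columns `threshold_hu`, the features and
#'   the response). At the -200 HU threshold `haa_pct` is skipped (it is
#'   identically zero there).
#' @param features feature column names.
#' @param thresholds upper HU thresholds present in `tbl`.
#' @param response response column (default `"gap_points"`).
#' @return list with `wide` (the report data.frame) and `fits` (nested list
#'   by threshold then feature).
#' @export
poisson_report <- function(tbl,
                           features = c("kurtosis", "nl_pct", "pff_pct",
                                        "haa_a_pct", "haa_pct", "laa_pct"),
                           thresholds = LUNG_THRESHOLDS,
                           response = "gap_points") {
  fits <- list()
  wide <- data.frame(feature = features)
  for (th in thresholds) {
    ps <- lls <- rep(NA_real_, length(features))
    fits[[as.character(th)]] <- list()
    for (i in seq_along(features)) {
      f <- features[i]
      if (f == "haa_pct" && th == -200L) next  # identically zero band
      fit <- fit_poisson_gap(tbl, f, threshold = th, response = response)
      fits[[as.character(th)]][[f]] <- fit
      ps[i] <- fit$p_value
      lls[i] <- fit$log_lik
    }
    wide[[paste0("p_", th)]] <- ps
    wide[[paste0("loglik_", th)]] <- lls
  }
  list(wide = wide, fits = fits)
}

#' Gamma model report for lung-function responses
#'
#' Fits [fit_gamma_log()] of each response on one feature at each
#' threshold; the report layout mirrors the conventional summary (beta,
#' exp(beta), SE on the link scale, p, log-lik).
#'
#' @param tbl long feature table.
#' @param feature explanatory feature (default `"nl_pct"`).
#' @param responses response columns.
#' @param thresholds upper HU thresholds.
#' @return data.frame with one row per (response, threshold).
#' @export
gamma_report <- function(tbl, feature = "nl_pct",
                         responses = c("fvc_pct_pred", "dlco_pct_pred"),
                         thresholds = c(-200L, 200L)) {
  rows <- list()
  for (resp in responses) {
    for (th in thresholds) {
      fit <- fit_gamma_log(tbl, feature, threshold = th, response = resp)
      rows[[length(rows) + 1L]] <- data.frame(
        response = resp, threshold = th, feature = feature,
        beta = unname(fit$coef[2]), exp_beta = unname(fit$exp_coef),
        se = unname(fit$se[2]), p_value = fit$p_value,
        log_lik = fit$log_lik, row.names = NULL)
    }
  }
  do.call(rbind, rows)
}
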