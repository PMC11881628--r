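#' Fit a random-intercept-and-slope linear mixed model by REML
#'
#' Fits the trajectory model used in stage one of the two-stage risk
#' estimator, for a single cognitive domain:
#' \deqn{y_{ij} = x_{ij}'\beta + b_{0i} + b_{1i} t_{ij} + e_{ij},\qquad
#'       (b_{0i}, b_{1i}) \sim N(0, G),\; e_{ij} \sim N(0, \sigma^2),}
#' where \eqn{t_{ij}} is years since baseline and the fixed covariates are
#' an intercept, time, and the supplied baseline covariates. Variance
#' components are estimated by restricted maximum likelihood: \eqn{\beta} is
#' profiled out by generalized least squares and the \eqn{2 \times 2}
#' relative covariance factor of \eqn{G} is optimized under non-negativity
#' bounds on its Cholesky diagonal, so the \eqn{G = 0} boundary is
#' admissible. Rows with a missing response are dropped, so irregular and
#' incomplete visit schedules are handled without imputation.
#'
#' @param data Long-format data frame, one row per visit.
#' @param response Score column (bare name or string), e.g. a domain
#'   composite in z-units.
#' @param id Subject identifier column name. Default `"id"`.
#' @param time Column with years since baseline (the random-slope
#'   variable). Default `"visit_year"`.
#' @param covariates Character vector of baseline covariate columns entering
#'   the fixed effects after the intercept and time. Default
#'   `c("baseline_age", "sex", "education")`.
#' @param start Optional numeric(3) starting value for the relative
#'   Cholesky parameters (l11, l21, l22).
#' @param control List overriding `nlminb` control parameters.
#' @return An object of class `cdr_lmm`: fixed effects `beta`, random-effect
#'   covariance `G`, residual variance `sigma2`, `reml_loglik`, `converged`,
#'   `slope_pinned` (true when no subject has two visits, in which case the
#'   slope variance is fixed at zero), and fit metadata.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 150), seed = 7)
#' dat <- dplyr::inner_join(cohort$visits, cohort$subjects, by = "id")
#' fit <- fit_lmm_reml(dat, domain_1)
#' glance(fit)
#' @export
fit_lmm_reml <- function(data, response, id = "id", time = "visit_year",
                         covariates = c("baseline_age", "sex", "education"),
                         start = NULL, control = list()) {
  response <- rlang::as_name(rlang::ensym(response))
  cols <- c(response, id, time, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_bad_arg("column(s) not found in data: %s",
                 paste(missing_cols, collapse = ", "))
  }
  y <- data[[response]]
  keep <- !is.na(y)
  if (any(!is.finite(y[keep]))) {
    stop_bad_arg("non-finite values in response '%s'", response)
  }
  dat <- data[keep, , drop = FALSE]
  sub_f <- factor(dat[[id]])
  nsub <- nlevels(sub_f)
  if (nsub < 2L) stop_bad_arg("need at least 2 subjects with observed '%s'",
                              response)
  t_vec <- as.numeric(dat[[time]])
  X <- cbind(`(Intercept)` = 1, stats::model.matrix(
    ~ 0 + ., data = dat[, c(time, covariates), drop = FALSE]))
  if (any(!is.finite(X))) stop_bad_arg("non-finite values in covariates")

  core <- lmm_core(y = as.numeric(dat[[response]]), X = X, t = t_vec,
                   subj = as.integer(sub_f), nsub = nsub,
                   start = start, control = control)

  structure(
    c(core,
      list(response = response, id = id, time = time,
           covariates = covariates, subject_levels = levels(sub_f))),
    class = "cdr_lmm")
}

# Core REML fit on prepared vectors; subj must be 1..nsub integers.
# Returns beta, G, sigma2, theta, vcov_beta, reml_loglik, converged, flags.

# Minimize the profiled -2 REML log-likelihood over the relative Cholesky
# parameters (l11, l21, l22), lower-bounded at zero on the diagonal. When
# the slope variance is pinned only l11 is free. nlminb's "false/singular
# convergence" codes can fire at a genuine optimum under tight tolerances;
# those solutions are accepted when no coordinate probe of size 1e-3
# (respecting the bounds) improves the objective meaningfully.
reml_optimize <- function(obj3, start = NULL, control = list(),
                          slope_pinned = FALSE) {
  ctrl <- modifyList(list(rel.tol = 1e-12, x.tol = 1e-11,
                          iter.max = 500L, eval.max = 2000L), control)
  if (slope_pinned) {
    st <- if (is.null(start)) 0.8 else start[1]
    opt <- nlminb(st, function(l) obj3(c(l, 0, 0)), lower = 0, control = ctrl)
    theta <- c(opt$par, 0, 0)
    free <- c(TRUE, FALSE, FALSE)
  } else {
    st <- if (is.null(start)) c(0.8, 0, 0.15) else start
    st <- pmax(st, c(0, -Inf, 0))
    opt <- nlminb(st, obj3, lower = c(0, -Inf, 0), control = ctrl)
    theta <- opt$par
    free <- rep(TRUE, 3)
  }
  converged <- opt$convergence == 0L
  if (!converged) {
    h <- 1e-3
    f0 <- obj3(theta)
    improved <- FALSE
    for (k in which(free)) {
      for (s in c(1, -1)) {
        cand <- theta
        cand[k] <- cand[k] + s * h
        if (k != 2L && cand[k] < 0) next
        if (obj3(cand) < f0 - 1e-4) {
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    converged <- !improved
  }
  list(theta = theta, opt = opt, converged = converged)
}

lmm_core <- function(y, X, t, subj, nsub, start = NULL, control = list(),
                     warn_pinned = TRUE) {
  # Constant non-intercept columns (e.g. the time column at landmark 0)
  # would make X rank-deficient; drop them and restore zero coefficients.
  keep_col <- c(TRUE, apply(X[, -1L, drop = FALSE], 2,
                            function(col) diff(range(col)) > 0))
  all_names <- colnames(X)
  if (!all(keep_col)) X <- X[, keep_col, drop = FALSE]
  ss <- cdr_suffstats(X, y, t, subj, nsub)
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  yty <- sum(y * y)
  p <- ncol(X)
  n <- length(y)
  if (n <= p) stop_bad_arg("need more observations (%d) than fixed effects (%d)",
                           n, p)

  # Slope variance is unidentified when every subject has a single visit.
  slope_pinned <- max(ss$K[, 1]) < 2
  if (slope_pinned && warn_pinned) {
    warn("all subjects have a single visit; random-slope variance pinned at zero")
  }

  obj3 <- function(th) {
    cdr_reml_eval(th, ss, XtX, Xty, yty)$objective
  }
  res <- reml_optimize(obj3, start, control, slope_pinned)
  theta <- res$theta
  opt <- res$opt
  converged <- res$converged
  fin <- cdr_reml_eval(theta, ss, XtX, Xty, yty)
  if (!isTRUE(fin$ok)) stop_bad_arg("REML evaluation failed at the optimum")
  L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  G <- fin$sigma2 * (L %*% t(L))
  dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
  beta <- setNames(numeric(length(all_names)), all_names)
  beta[keep_col] <- drop(fin$beta)
  vcov_beta <- matrix(NA_real_, length(all_names), length(all_names),
                      dimnames = list(all_names, all_names))
  vcov_beta[keep_col, keep_col] <- fin$vcov_beta

  list(beta = beta, G = G, sigma2 = fin$sigma2, theta = theta,
       vcov_beta = vcov_beta,
       reml_loglik = -0.5 * fin$objective,
       converged = converged,
       iterations = opt$iterations,
       slope_pinned = slope_pinned,
       n_subjects = nsub, n_obs = n)
}

#' Empirical best linear unbiased predictions of subject trajectories
#'
#' Computes, for every subject with at least one observed visit, the
#' conditional mean of its random intercept and slope given the data and the
#' estimated variance components:
#' \deqn{\hat b_i = G Z_i' V_i^{-1} (y_i - X_i \hat\beta),\qquad
#'       V_i = Z_i G Z_i' + \sigma^2 I.}
#' The computation uses the Woodbury identity on the 2-dimensional
#' random-effect space (never forming \eqn{V_i}), which is algebraically
#' identical to the dense formula; \eqn{V_i} is positive definite whenever
#' \eqn{\sigma^2 > 0}, and at \eqn{G = 0} the predictions are exactly zero.
#' Predictions shrink toward zero as visits become fewer or noisier.
#'
#' @param fit A `cdr_lmm` fit.
#' @param data Long-format visit data with the same response, id, time and
#'   covariate columns used for the fit (may contain subjects not in the
#'   original fit).
#' @return A tibble with one row per subject: `id`, `b0_hat` (z-units),
#'   `b1_hat` (z-units/year), `n_visits`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 150), seed = 7)
#' dat <- dplyr::inner_join(cohort$visits, cohort$subjects, by = "id")
#' fit <- fit_lmm_reml(dat, domain_1)
#' head(compute_eblup(fit, dat))
#' @export
compute_eblup <- function(fit, data) {
  stopifnot(inherits(fit, "cdr_lmm"))
  cols <- c(fit$response, fit$id, fit$time, fit$covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop_bad_arg("column(s) not found in data: %s",
                 paste(missing_cols, collapse = ", "))
  }
  keep <- !is.na(data[[fit$response]])
  dat <- data[keep, , drop = FALSE]
  sub_f <- factor(dat[[fit$id]])
  X <- cbind(`(Intercept)` = 1, stats::model.matrix(
    ~ 0 + ., data = dat[, c(fit$time, fit$covariates), drop = FALSE]))
  ss <- cdr_suffstats(X, as.numeric(dat[[fit$response]]),
                      as.numeric(dat[[fit$time]]),
                      as.integer(sub_f), nlevels(sub_f))
  b <- cdr_eblup_all(fit$theta, unname(fit$beta), ss)
  tibble(id = levels(sub_f),
         b0_hat = b[, 1], b1_hat = b[, 2],
         n_visits = as.integer(ss$K[, 1]))
}

#' @export
print.cdr_lmm <- function(x, ...) {
  cat("Linear mixed model (REML), response:", x$response, "\n")
  cat(sprintf("  %d subjects, %d observations; converged: %s%s\n",
              x$n_subjects, x$n_obs, x$converged,
              if (x$slope_pinned) " (slope variance pinned)" else ""))
  cat("  Fixed effects:\n")
  print(round(x$beta, 4))
  cat("  Random-effect covariance G:\n")
  print(round(x$G, 5))
  cat(sprintf("  Residual variance: %.5f   REML log-likelihood: %.3f\n",
              x$sigma2, x$reml_loglik))
  invisible(x)
}
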