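#' Tidy a stage-one mixed-model fit
#'
#' One row per fixed effect, with asymptotic (GLS) standard errors and Wald
#' statistics.
#'
#' @param x A `cdr_lmm`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`.
#' @method tidy cdr_lmm
#' @export
tidy.cdr_lmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  tibble(term = names(x$beta), estimate = unname(x$beta),
         std.error = unname(se), statistic = unname(x$beta / se))
}

#' Summarize a stage-one mixed-model fit in one row
#' @param x A `cdr_lmm`.
#' @param ... Unused.
#' @return One-row tibble with variance components, REML log-likelihood,
#'   convergence and sizes.
#' @method glance cdr_lmm
#' @export
glance.cdr_lmm <- function(x, ...) {
  tibble(sigma2 = x$sigma2,
         var_intercept = x$G[1, 1], var_slope = x$G[2, 2],
         cov_int_slope = x$G[1, 2],
         reml_loglik = x$reml_loglik, converged = x$converged,
         slope_pinned = x$slope_pinned,
         n_subjects = x$n_subjects, n_obs = x$n_obs)
}

#' Tidy a stage-two logistic fit
#'
#' @param x A `cdr_logit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy cdr_logit
#' @export
tidy.cdr_logit <- function(x, ...) {
  est <- x$gamma
  se <- sqrt(diag(x$vcov))[names(est)]
  z <- est / se
  tibble(term = names(est), estimate = unname(est),
         std.error = unname(se), statistic = unname(z),
         p.value = unname(2 * pnorm(-abs(z))))
}

#' Summarize a stage-two logistic fit in one row
#' @param x A `cdr_logit`.
#' @param ... Unused.
#' @return One-row tibble: `loglik`, `converged`, `separable`, `n`,
#'   `n_events`.
#' @method glance cdr_logit
#' @export
glance.cdr_logit <- function(x, ...) {
  tibble(loglik = x$loglik, converged = x$converged,
         separable = x$separable, n = x$n, n_events = x$n_events)
}

#' Tidy a fitted dynamic risk model (stage-two coefficients)
#'
#' Coefficients fixed at zero because their feature was constant in the
#' landmark window (e.g. slope summaries at landmark 0) are flagged.
#'
#' @param x A `cdr_dynfit`.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std.error`, `statistic`, `p.value`,
#'   `constant`.
#' @method tidy cdr_dynfit
#' @export
tidy.cdr_dynfit <- function(x, ...) {
  full <- tibble(term = names(x$stage2$gamma_full),
                 estimate = unname(x$stage2$gamma_full))
  est <- tidy.cdr_logit(x$stage2)
  out <- dplyr::left_join(full, est[, c("term", "std.error", "statistic",
                                        "p.value")], by = "term")
  out$constant <- out$term %in% x$constant_features
  out
}

#' Summarize a fitted dynamic risk model in one row
#' @param x A `cdr_dynfit`.
#' @param ... Unused.
#' @return One-row tibble: landmark year, domains, AUC and Brier of the
#'   fitted risks, stage-two size, validity.
#' @method glance cdr_dynfit
#' @export
glance.cdr_dynfit <- function(x, ...) {
  tibble(landmark_year = x$t,
         domains = paste(x$domains, collapse = "+"),
         auc = compute_auc(x$risks$risk, x$risks$outcome),
         brier = brier_score(x$risks$risk, x$risks$outcome),
         n = x$stage2$n, n_events = x$stage2$n_events,
         n_dropped_missing = x$n_dropped_missing, valid = x$valid)
}
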