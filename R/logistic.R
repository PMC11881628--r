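#' Fit a logistic risk model by maximum likelihood
#'
#' Stage two of the two-stage estimator: a Bernoulli log-likelihood maximized
#' by iteratively reweighted least squares, with the subject-level trajectory
#' summaries (and demographics) as covariates. Iterations continue until the
#' score vector satisfies \eqn{\max_j |X'(y-\mu)|_j < 10^{-8}}; step-halving
#' guards against overshooting. Quasi-separation is flagged (not silently
#' accepted) when a fitted log-odds diverges past 30 in absolute value.
#'
#' @param data Data frame with one row per subject.
#' @param outcome Binary outcome column (bare name or string; values 0/1).
#' @param features Character vector of feature columns. An intercept is
#'   always appended (last, so the coefficient vector is ordered features
#'   then intercept).
#' @param max_iter Iteration cap (default 100).
#' @param tol Convergence threshold on the maximum absolute score component.
#' @return Object of class `cdr_logit`: `gamma` (named coefficients), `vcov`
#'   (inverse Fisher information), `loglik`, `converged`, `separable`, `n`,
#'   `n_events`.
#' @examples
#' d <- tibble::tibble(y = rbinom(200, 1, 0.3), x = rnorm(200))
#' fit <- fit_logistic_mle(d, y, "x")
#' tidy(fit)
#' @export
fit_logistic_mle <- function(data, outcome, features, max_iter = 100L,
                             tol = 1e-8) {
  outcome <- rlang::as_name(rlang::ensym(outcome))
  missing_cols <- setdiff(c(outcome, features), names(data))
  if (length(missing_cols)) {
    stop_bad_arg("column(s) not found in data: %s",
                 paste(missing_cols, collapse = ", "))
  }
  y <- as.numeric(data[[outcome]])
  X <- cbind(as.matrix(data[, features, drop = FALSE]),
             `(Intercept)` = 1)
  storage.mode(X) <- "double"
  fit <- irls_logistic(X, y, max_iter = max_iter, tol = tol)
  structure(c(fit, list(outcome = outcome, features = features)),
            class = "cdr_logit")
}

# IRLS core on a design matrix that already includes its intercept column.
# Works in a column-scaled basis; columns aliased at the qr() tolerance
# (e.g. a slope summary exactly proportional to its intercept summary when
# the random-slope variance collapses) get coefficients fixed at zero.
irls_logistic <- function(X, y, max_iter = 100L, tol = 1e-8) {
  if (any(!is.finite(X))) stop_bad_arg("non-finite feature values")
  if (any(is.na(y)) || !all(y %in% c(0, 1))) {
    stop_bad_arg("outcome must be binary 0/1 without missing values")
  }
  if (length(unique(y)) < 2L) {
    stop_bad_arg("both outcome classes must be present")
  }
  X_in <- X
  col_scale <- apply(abs(X), 2, max)
  col_scale[col_scale <= 0] <- 1
  X <- sweep(X_in, 2, col_scale, "/")
  qr0 <- qr(X)
  aliased <- integer(0)
  if (qr0$rank < ncol(X)) {
    aliased <- sort(qr0$pivot[(qr0$rank + 1L):ncol(X)])
    X <- X[, -aliased, drop = FALSE]
  }
  n <- nrow(X)
  p <- ncol(X)
  kept <- setdiff(seq_len(ncol(X_in)), aliased)
  beta <- numeric(p)
  int_pos <- match(ncol(X_in), kept)
  if (!is.na(int_pos)) beta[int_pos] <- qlogis(mean(y))
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll <- loglik(beta)
  converged <- FALSE
  separable <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    w <- pmax(mu * (1 - mu), 1e-12)
    # weighted least squares via QR (stable under the near-collinear
    # trajectory summaries of early landmarks; normal equations are not)
    sw <- sqrt(w)
    z <- eta + (y - mu) / w
    qrx <- qr(X * sw)
    cand_full <- qr.coef(qrx, sw * z)
    cand_full[is.na(cand_full)] <- 0
    step <- cand_full - beta
    # step-halving: never accept a likelihood decrease
    lam <- 1
    repeat {
      cand <- beta + lam * step
      llc <- loglik(cand)
      if (llc >= ll - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- cand
    ll <- llc
    # Quasi-separation drives fitted log-odds without bound; coefficient
    # magnitudes alone can be large yet harmless when features are nearly
    # collinear (early-landmark trajectory summaries) or tiny in scale.
    if (max(abs(drop(X %*% beta))) > 30) {
      separable <- TRUE
      warn("possible quasi-separation: fitted log-odds diverging past 30")
      break
    }
  }
  mu <- plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X * w, X)
  vcov_s <- tryCatch(solve(XtWX), error = function(e) {
    solve(XtWX + diag(1e-8, p))
  })
  # back to the original column scale; aliased columns get 0 coefficients
  # and undefined (NA) variance entries
  p_all <- ncol(X_in)
  gamma <- setNames(numeric(p_all), colnames(X_in))
  gamma[kept] <- beta / col_scale[kept]
  vcov <- matrix(NA_real_, p_all, p_all,
                 dimnames = list(colnames(X_in), colnames(X_in)))
  vcov[kept, kept] <- vcov_s / tcrossprod(col_scale[kept])
  list(gamma = gamma, vcov = vcov,
       loglik = loglik(beta), converged = converged, separable = separable,
       aliased = colnames(X_in)[aliased],
       fitted = mu, n = n, n_events = sum(y))
}

#' Predict absolute risk from a fitted logistic model
#'
#' Evaluates \eqn{\mathrm{logit}^{-1}(\gamma' x)} for each row; strictly
#' monotone in every feature with the sign of its coefficient.
#'
#' @param fit A `cdr_logit` object.
#' @param newdata Data frame containing the fit's feature columns.
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
predict_risk <- function(fit, newdata) {
  stopifnot(inherits(fit, "cdr_logit"))
  missing_cols <- setdiff(fit$features, names(newdata))
  if (length(missing_cols)) {
    stop_bad_arg("missing covariate(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  X <- cbind(as.matrix(newdata[, fit$features, drop = FALSE]),
             `(Intercept)` = 1)
  if (any(!is.finite(X))) stop_bad_arg("non-finite feature values")
  plogis(drop(X %*% fit$gamma))
}

#' @export
print.cdr_logit <- function(x, ...) {
  cat(sprintf("Logistic risk model: %d subjects, %d events; converged: %s%s\n",
              x$n, x$n_events, x$converged,
              if (x$separable) " (quasi-separation flagged)" else ""))
  print(round(x$gamma, 4))
  invisible(x)
}
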