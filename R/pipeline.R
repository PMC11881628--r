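#' Fit the two-stage dynamic risk model at one landmark
#'
#' Runs the full two-stage estimator on a landmark dataset: one linear mixed
#' model per cognitive domain (REML) on the visits visible in the landmark
#' window, empirical best linear unbiased predictions of each subject's
#' intercept and slope, and a logistic model of the binary AD outcome on the
#' pooled trajectory summaries plus baseline age, sex and education.
#' Subjects with no observed visit in one of the modelled domains cannot
#' contribute trajectory summaries for it and are, by default, dropped from
#' stage two (set `impute_missing_zero = TRUE` to instead shrink their
#' missing summaries fully to the population mean of zero). Stage-two
#' features that are constant across subjects — the slope summaries at
#' landmark 0, where every subject has a single visit — carry a coefficient
#' fixed at zero rather than entering a singular fit.
#'
#' @param landmark A [build_landmark_dataset()] / [build_horizon_dataset()]
#'   object (or any list with `subjects` and `visits` in the same schema).
#' @param domains Character vector of score columns to model; default all
#'   `domain_*` columns of the visit table.
#' @param impute_missing_zero Replace missing trajectory summaries by 0
#'   instead of dropping the subject from stage two.
#' @return Object of class `cdr_dynfit`: `stage1` (named list of `cdr_lmm`),
#'   `effects` (tibble of per-subject summaries), `stage2` (`cdr_logit`),
#'   `risks` (tibble `id`, `outcome`, `risk`), `t`, `domains`,
#'   `n_dropped_missing`, `constant_features`, `valid` (all component fits
#'   converged).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 300), seed = 9)
#' elig <- apply_lifetime_eligibility(cohort$subjects, cohort$visits)
#' lmk <- build_landmark_dataset(elig$subjects, cohort$visits, t = 6)
#' fit <- fit_dynamic_model(lmk)
#' head(fit$risks)
#' @export
fit_dynamic_model <- function(landmark, domains = NULL,
                              impute_missing_zero = FALSE) {
  cl <- compile_landmark(landmark, domains)
  res <- fit_pipeline_core(cl, impute_missing_zero = impute_missing_zero)
  as_dynfit(res, cl, landmark)
}

# ---- internal fast path ----------------------------------------------------

# Precompute per-subject sufficient statistics and visit-pattern groups so
# the pipeline can be refit on a bootstrap resample with a single O(n)
# reweighting pass per domain (no row-level data reconstruction).
compile_landmark <- function(landmark, domains = NULL) {
  s <- landmark$subjects
  v <- landmark$visits
  if (is.null(domains)) {
    domains <- grep("^domain_", names(v), value = TRUE)
  }
  if (!length(domains)) stop_bad_arg("no domain score columns to model")
  missing_cols <- setdiff(domains, names(v))
  if (length(missing_cols)) {
    stop_bad_arg("domain column(s) not in visit table: %s",
                 paste(missing_cols, collapse = ", "))
  }
  need <- c("baseline_age", "sex", "education")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop_bad_arg("subject table lacks: %s",
                                 paste(miss, collapse = ", "))
  n <- nrow(s)
  demo <- cbind(baseline_age = as.numeric(s$baseline_age),
                sex = as.numeric(s$sex),
                education = as.numeric(s$education))
  subj_of_row <- match(v$id, s$id)
  tvec <- as.numeric(v$visit_year)
  x_names <- c("(Intercept)", "visit_year", colnames(demo))
  per_domain <- lapply(domains, function(d) {
    ok <- !is.na(v[[d]]) & !is.na(subj_of_row)
    subj <- subj_of_row[ok]
    tt <- tvec[ok]
    sc <- as.numeric(v[[d]])[ok]
    X <- cbind(1, tt, demo[subj, , drop = FALSE])
    keep_col <- c(TRUE, apply(X[, -1L, drop = FALSE], 2,
                              function(col) diff(range(col)) > 0))
    Xr <- X[, keep_col, drop = FALSE]
    pre <- cdr_lmm_precompute(Xr, sc, tt, subj, n)
    list(pre = pre, keep_col = keep_col, x_names = x_names,
         n_obs = length(sc))
  })
  names(per_domain) <- domains
  list(id = s$id, y = as.integer(s$outcome), demo = demo, n = n,
       domains = domains, per_domain = per_domain, t = landmark$t)
}

# REML fit from precomputed per-subject statistics under multiplicity
# weights w (the nonparametric bootstrap); algebraically identical to
# refitting on the stacked resampled rows.
lmm_core_agg <- function(pre, w, start = NULL, control = list(),
                         warn_pinned = TRUE) {
  if (is.integer(w)) w <- as.numeric(w)
  active <- w > 0
  slope_pinned <- max(pre$K[active, 1]) < 2
  if (slope_pinned && warn_pinned) {
    warn("all subjects have a single visit; random-slope variance pinned at zero")
  }
  agg <- cdr_lmm_aggregate(pre, w)
  obj3 <- function(th) cdr_reml_obj_agg(th, agg)
  res <- reml_optimize(obj3, start, control, slope_pinned)
  fin <- cdr_reml_eval_agg(res$theta, agg, TRUE)
  if (!isTRUE(fin$ok)) stop_bad_arg("REML evaluation failed at the optimum")
  theta <- res$theta
  L <- matrix(c(theta[1], theta[2], 0, theta[3]), 2, 2)
  G <- fin$sigma2 * (L %*% t(L))
  dimnames(G) <- list(c("intercept", "slope"), c("intercept", "slope"))
  list(beta = drop(fin$beta), G = G, sigma2 = fin$sigma2, theta = theta,
       vcov_beta = fin$vcov_beta,
       reml_loglik = -0.5 * fin$objective,
       converged = res$converged,
       iterations = res$opt$iterations,
       slope_pinned = slope_pinned,
       n_subjects = sum(active), n_obs = as.integer(round(agg$Nw)))
}

# Fit stage 1 + stage 2 on the compiled data, optionally on a resample of
# subject indices `take` (with replacement; duplicates are distinct
# subjects). `warm` supplies per-domain starting values for REML.
fit_pipeline_core <- function(cl, take = NULL, warm = NULL,
                              impute_missing_zero = FALSE,
                              control = NULL) {
  # Warm-started bootstrap refits need less optimizer precision than the
  # reported original-data fit; tolerances here are still far below the
  # statistical precision of the variance components.
  if (is.null(control)) {
    control <- if (is.null(take)) list() else
      list(rel.tol = 1e-8, x.tol = 1e-9)
  }
  n_eff <- if (is.null(take)) cl$n else length(take)
  demo <- if (is.null(take)) cl$demo else cl$demo[take, , drop = FALSE]
  y <- if (is.null(take)) cl$y else cl$y[take]
  D <- length(cl$domains)
  w <- if (is.null(take)) rep(1, cl$n) else tabulate(take, cl$n)

  stage1 <- vector("list", D)
  effects <- matrix(NA_real_, n_eff, 2L * D)
  nvis <- matrix(0L, n_eff, D)
  for (k in seq_len(D)) {
    pd <- cl$per_domain[[k]]
    fit <- lmm_core_agg(pd$pre, w,
                        start = if (is.null(warm)) NULL else warm[[k]],
                        control = control,
                        warn_pinned = is.null(take))
    # EBLUPs depend only on a subject's own data given (theta, beta):
    # compute once on the original subjects, then index the resample.
    b <- cdr_eblup_all(fit$theta, fit$beta, pd$pre)
    nv <- as.integer(pd$pre$K[, 1])
    b[nv == 0L, ] <- NA_real_
    if (!is.null(take)) {
      b <- b[take, , drop = FALSE]
      nv <- nv[take]
    }
    effects[, 2L * k - 1L] <- b[, 1]
    effects[, 2L * k] <- b[, 2]
    nvis[, k] <- nv
    stage1[[k]] <- fit
  }
  names(stage1) <- cl$domains
  colnames(effects) <- as.vector(rbind(paste0("b0_", cl$domains),
                                       paste0("b1_", cl$domains)))

  F_full <- cbind(effects, demo)
  if (impute_missing_zero) {
    F_full[, seq_len(2L * D)][is.na(F_full[, seq_len(2L * D)])] <- 0
    kept <- rep(TRUE, n_eff)
  } else {
    kept <- stats::complete.cases(F_full)
  }
  Fk <- F_full[kept, , drop = FALSE]
  yk <- y[kept]
  constant <- apply(Fk, 2, function(col) diff(range(col)) < 1e-10)
  X2 <- cbind(Fk[, !constant, drop = FALSE], `(Intercept)` = 1)
  logit <- irls_logistic(X2, yk)
  gamma_full <- setNames(numeric(ncol(F_full) + 1L),
                         c(colnames(F_full), "(Intercept)"))
  gamma_full[names(logit$gamma)] <- logit$gamma
  logit$gamma_full <- gamma_full

  list(stage1 = stage1, effects = effects, n_visits = nvis,
       logit = logit, risks = logit$fitted, y = yk, kept = kept,
       n_dropped_missing = sum(!kept), constant_features =
         names(constant)[constant],
       valid = all(vapply(stage1, `[[`, TRUE, "converged")) &&
         logit$converged && !logit$separable)
}

as_dynfit <- function(res, cl, landmark) {
  stage1 <- lapply(seq_along(res$stage1), function(k) {
    f <- res$stage1[[k]]
    pd <- cl$per_domain[[k]]
    beta <- setNames(numeric(length(pd$x_names)), pd$x_names)
    beta[pd$keep_col] <- f$beta
    vcov_beta <- matrix(NA_real_, length(beta), length(beta),
                        dimnames = list(pd$x_names, pd$x_names))
    vcov_beta[pd$keep_col, pd$keep_col] <- f$vcov_beta
    f$beta <- beta
    f$vcov_beta <- vcov_beta
    structure(c(f, list(response = cl$domains[k], id = "id",
                        time = "visit_year",
                        covariates = c("baseline_age", "sex", "education"),
                        subject_levels = cl$id)),
              class = "cdr_lmm")
  })
  names(stage1) <- cl$domains
  effects <- dplyr::bind_cols(tibble(id = cl$id), as_tibble(res$effects))
  # expose the full-length coefficient vector (dropped or aliased features
  # carry 0) so prediction on new data is always conformable; their
  # variance entries are undefined
  logit <- res$logit
  gf <- logit$gamma_full
  vcov_full <- matrix(NA_real_, length(gf), length(gf),
                      dimnames = list(names(gf), names(gf)))
  common <- intersect(rownames(logit$vcov), names(gf))
  vcov_full[common, common] <- logit$vcov[common, common]
  logit$gamma <- gf
  logit$vcov <- vcov_full
  stage2 <- structure(
    c(logit, list(outcome = "outcome",
                  features = setdiff(names(gf), "(Intercept)"))),
    class = "cdr_logit")
  risks <- tibble(id = cl$id[res$kept], outcome = res$y, risk = res$risks)
  structure(list(stage1 = stage1, effects = effects, stage2 = stage2,
                 risks = risks, t = landmark$t, domains = cl$domains,
                 n_dropped_missing = res$n_dropped_missing,
                 constant_features = res$constant_features,
                 valid = res$valid),
            class = "cdr_dynfit")
}

#' Predict AD risk for new subjects from a fitted dynamic model
#'
#' Computes trajectory summaries for the supplied visit histories with the
#' frozen stage-one fits, then applies the stage-two logistic model.
#' Features that were constant at fitting time (zero coefficient) contribute
#' nothing, matching the fitted model.
#'
#' @param object A `cdr_dynfit`.
#' @param subjects Subject table (`id`, `baseline_age`, `sex`, `education`).
#' @param visits Visit table with the model's domain columns.
#' @param ... Unused.
#' @return Tibble `id`, `risk`.
#' @export
predict.cdr_dynfit <- function(object, subjects, visits, ...) {
  s <- as_tibble(subjects)
  need <- c("baseline_age", "sex", "education")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop_bad_arg("missing demographic covariate(s): %s",
                                 paste(miss, collapse = ", "))
  if (any(!complete.cases(s[, need]))) {
    stop_bad_arg("missing demographic covariate values")
  }
  dat <- dplyr::inner_join(as_tibble(visits), s, by = "id")
  feats <- tibble(id = s$id)
  for (d in object$domains) {
    eb <- compute_eblup(object$stage1[[d]], dat[!is.na(dat[[d]]), ])
    feats[[paste0("b0_", d)]] <- eb$b0_hat[match(s$id, eb$id)]
    feats[[paste0("b1_", d)]] <- eb$b1_hat[match(s$id, eb$id)]
  }
  feats <- dplyr::left_join(feats, s[, c("id", need)], by = "id")
  for (cf in object$constant_features) feats[[cf]] <- 0  # coefficient is 0
  ok <- complete.cases(feats)
  out <- tibble(id = s$id, risk = NA_real_)
  out$risk[ok] <- predict_risk(object$stage2, feats[ok, , drop = FALSE])
  out
}

#' @export
print.cdr_dynfit <- function(x, ...) {
  lab <- if (is.na(x$t)) "horizon design" else sprintf("landmark year %s", x$t)
  cat(sprintf("Two-stage dynamic risk model (%s)\n", lab))
  cat(sprintf("  domains: %s\n", paste(x$domains, collapse = ", ")))
  cat(sprintf("  stage 2: %d subjects (%d dropped for missing domains), %d events\n",
              x$stage2$n, x$n_dropped_missing, x$stage2$n_events))
  cat(sprintf("  valid: %s\n", x$valid))
  invisible(x)
}
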