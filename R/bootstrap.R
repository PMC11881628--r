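#' Bootstrap confidence interval for the landmark AUC
#'
#' Internal validation of the two-stage model at one landmark: subjects are
#' resampled with replacement (each subject's whole visit history travels
#' with it, and duplicates count as distinct subjects), the entire two-stage
#' pipeline is refit on every resample, and the AUC of the refitted model's
#' risks against the resampled outcomes is recorded. The point estimate is
#' the AUC on the original data; the interval reflects the 2.5/97.5
#' bootstrap quantiles around the point estimate (the reflected or "basic"
#' bootstrap), which corrects the upward shift of the resample-evaluated
#' distribution. Resamples with a single outcome class or a
#' failed fit are redrawn (counted, and capped at 20% of `B`).
#' `refit = FALSE` switches to a fast re-scoring mode that resamples the
#' original fit's risk scores without refitting.
#'
#' @param landmark A landmark dataset.
#' @param domains Domain columns to model (default: all).
#' @param B Number of bootstrap iterations (default 1000).
#' @param seed Integer seed.
#' @param refit Refit the full pipeline per resample (default TRUE).
#' @param redraw_cap Maximum tolerated redraw fraction (default 0.2).
#' @param impute_missing_zero Passed to the pipeline fit.
#' @return One-row tibble of class `cdr_auc`: `landmark_year`, `auc`,
#'   `ci_low`, `ci_high`, `n_bootstrap`, `n_cases`, `n_controls`,
#'   `n_redraws`, `boot_sd`, `brier` (Brier score of the original-data
#'   fit), `valid`.
#' @export
bootstrap_auc_ci <- function(landmark, domains = NULL, B = 1000, seed = NULL,
                             refit = TRUE, redraw_cap = 0.2,
                             impute_missing_zero = FALSE) {
  if (B < 2) stop_bad_arg("B must be >= 2")
  cl <- compile_landmark(landmark, domains)
  full <- fit_pipeline_core(cl, impute_missing_zero = impute_missing_zero)
  auc_point <- compute_auc(full$risks, full$y)
  warm <- lapply(full$stage1, `[[`, "theta")
  risk_by_subject <- rep(NA_real_, cl$n)
  risk_by_subject[which(full$kept)] <- full$risks

  local_seed(seed, {
    n <- cl$n
    aucs <- numeric(B)
    redraws <- 0L
    max_redraws <- ceiling(redraw_cap * B)
    for (b in seq_len(B)) {
      repeat {
        take <- sample.int(n, n, replace = TRUE)
        yb <- cl$y[take]
        ab <- if (length(unique(yb)) < 2L) {
          NA_real_
        } else if (refit) {
          res <- tryCatch(
            fit_pipeline_core(cl, take = take, warm = warm,
                              impute_missing_zero = impute_missing_zero),
            error = function(e) NULL)
          if (is.null(res) || !res$valid) NA_real_ else
            compute_auc(res$risks, res$y)
        } else {
          rb <- risk_by_subject[take]
          ok <- !is.na(rb)
          if (length(unique(yb[ok])) < 2L) NA_real_ else
            compute_auc(rb[ok], yb[ok])
        }
        if (!is.na(ab)) break
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop_bad_arg("bootstrap redraw rate exceeded %.0f%%: dataset too small or imbalanced",
                       100 * redraw_cap)
        }
      }
      aucs[b] <- ab
    }
    # Reflected (basic) bootstrap interval: the resample-refit AUC
    # distribution is upward-shifted relative to the point estimate
    # (each refit is scored on its own resample), so the quantiles are
    # reflected around the original-sample AUC, which corrects that bias
    # to first order.
    q <- unname(quantile(aucs, c(0.025, 0.975)))
    ci <- pmin(pmax(c(2 * auc_point - q[2], 2 * auc_point - q[1]), 0), 1)
    out <- tibble(landmark_year = landmark$t, auc = auc_point,
                  ci_low = ci[1], ci_high = ci[2],
                  n_bootstrap = as.integer(B),
                  n_cases = sum(full$y == 1L),
                  n_controls = sum(full$y == 0L),
                  n_redraws = redraws,
                  boot_sd = sd(aucs),
                  brier = brier_score(full$risks, full$y),
                  valid = full$valid)
    if (out$ci_low > out$auc || out$ci_high < out$auc) {
      warn("point AUC falls outside the percentile interval (Monte-Carlo wobble)")
    }
    class(out) <- c("cdr_auc", class(out))
    out
  })
}

#' Annual landmark AUC table
#'
#' The headline dynamic-evaluation analysis: for each landmark year, builds
#' the landmark dataset (visits up to that year, pre-onset only, capped),
#' refits the two-stage model, and reports the AUC with its bootstrap
#' percentile interval — one row per year. A landmark whose fit fails is
#' marked invalid rather than aborting the table.
#'
#' @param subjects Eligible subject table with `outcome`.
#' @param visits Visit table.
#' @param domains Domain columns to model (default: all `domain_*`).
#' @param years Landmark years (default 0:10).
#' @param B Bootstrap iterations per year (default 1000).
#' @param seed Integer seed.
#' @param max_visits Per-subject visit cap (default 11).
#' @param impute_missing_zero Passed to the pipeline fit.
#' @return Tibble of class `cdr_auc_by_year`, one row per landmark year.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 250), seed = 5)
#' elig <- apply_lifetime_eligibility(cohort$subjects, cohort$visits)
#' tab <- auc_by_year(elig$subjects, cohort$visits, years = c(0, 5),
#'                    B = 20, seed = 1)
#' @export
auc_by_year <- function(subjects, visits, domains = NULL, years = 0:10,
                        B = 1000, seed = NULL, max_visits = 11,
                        impute_missing_zero = FALSE) {
  seeds <- derive_seeds(seed, length(years))
  rows <- lapply(seq_along(years), function(i) {
    t <- years[i]
    res <- tryCatch({
      lmk <- build_landmark_dataset(subjects, visits, t,
                                    max_visits = max_visits)
      bootstrap_auc_ci(lmk, domains = domains, B = B, seed = seeds[i],
                       impute_missing_zero = impute_missing_zero)
    }, error = function(e) {
      warn(sprintf("landmark year %s invalid: %s", t, conditionMessage(e)))
      tibble(landmark_year = t, auc = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, n_bootstrap = as.integer(B),
             n_cases = NA_integer_, n_controls = NA_integer_,
             n_redraws = NA_integer_, boot_sd = NA_real_,
             brier = NA_real_, valid = FALSE)
    })
    res
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cdr_auc_by_year", class(out))
  out
}

#' AUC-based forward stepwise selection of cognitive domains
#'
#' Greedy forward selection at a criterion landmark year: starts from the
#' single domain with the highest AUC, then repeatedly adds the domain whose
#' inclusion raises the AUC most, stopping when the best improvement falls
#' below `threshold` or all candidates are in. AUCs are the original-sample
#' point estimates of the refitted pipeline; with `B >= 2` a bootstrap
#' interval is attached to each selected step.
#'
#' @param subjects Eligible subject table with `outcome`.
#' @param visits Visit table.
#' @param candidates Candidate domain columns (>= 2).
#' @param t_star Criterion landmark year (default 10).
#' @param threshold Minimum AUC improvement to continue (default 0.001).
#' @param B Bootstrap iterations for per-step intervals (0 = none).
#' @param seed Integer seed (used only when `B >= 2`).
#' @param max_visits Per-subject visit cap.
#' @return Tibble of class `cdr_stepwise`: `step`, `domain_added`,
#'   `domains`, `auc`, `improvement` (and CI columns when bootstrapped).
#' @export
stepwise_domain_selection <- function(subjects, visits, candidates,
                                      t_star = 10, threshold = 0.001,
                                      B = 0, seed = NULL, max_visits = 11) {
  if (length(candidates) < 2L) stop_bad_arg("need at least 2 candidate domains")
  lmk <- build_landmark_dataset(subjects, visits, t_star,
                                max_visits = max_visits)
  point_auc <- function(doms) {
    res <- fit_pipeline_core(compile_landmark(lmk, doms))
    compute_auc(res$risks, res$y)
  }
  selected <- character(0)
  path <- list()
  current_auc <- -Inf
  step <- 0L
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    trial <- vapply(remaining, function(d) {
      tryCatch(point_auc(c(selected, d)), error = function(e) NA_real_)
    }, numeric(1))
    if (all(is.na(trial))) {
      warn("all candidate fits failed; returning partial path")
      break
    }
    best <- remaining[which.max(trial)]
    best_auc <- max(trial, na.rm = TRUE)
    improvement <- if (step == 0L) NA_real_ else best_auc - current_auc
    if (step > 0L && (is.na(improvement) || improvement < threshold)) break
    step <- step + 1L
    selected <- c(selected, best)
    current_auc <- best_auc
    path[[step]] <- tibble(step = step, domain_added = best,
                           domains = paste(selected, collapse = "+"),
                           auc = best_auc, improvement = improvement)
  }
  out <- dplyr::bind_rows(path)
  if (B >= 2 && nrow(out)) {
    seeds <- derive_seeds(seed, nrow(out))
    cis <- lapply(seq_len(nrow(out)), function(i) {
      doms <- strsplit(out$domains[i], "+", fixed = TRUE)[[1]]
      bootstrap_auc_ci(lmk, domains = doms, B = B, seed = seeds[i])
    })
    out$ci_low <- vapply(cis, `[[`, numeric(1), "ci_low")
    out$ci_high <- vapply(cis, `[[`, numeric(1), "ci_high")
  }
  class(out) <- c("cdr_stepwise", class(out))
  out
}
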