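#' Validate subject and visit tables against the expected schema
#'
#' Structural checks on the two input tables: required columns, value
#' ranges, and cross-table consistency. Fatal findings make the tables
#' unusable for analysis; warnings flag suspicious but tolerated rows.
#'
#' @param subjects Subject table.
#' @param visits Visit table.
#' @return Tibble of findings (`severity`, `table`, `row`, `message`), with
#'   attribute `ok` (TRUE when no fatal finding). Zero rows means a clean
#'   pass.
#' @export
validate_cohort_tables <- function(subjects, visits) {
  f <- list()
  add <- function(severity, table, row, message) {
    f[[length(f) + 1L]] <<- tibble(severity = severity, table = table,
                                   row = as.integer(row), message = message)
  }
  req_s <- c("id", "baseline_age", "sex", "education", "ad_status",
             "onset_age", "death_age", "last_contact_age")
  req_v <- c("id", "visit_year", "age_at_visit")
  miss_s <- setdiff(req_s, names(subjects))
  miss_v <- setdiff(req_v, names(visits))
  for (m in miss_s) add("fatal", "subjects", NA, paste("missing column:", m))
  for (m in miss_v) add("fatal", "visits", NA, paste("missing column:", m))
  if (!length(miss_s)) {
    is_ad <- subjects$ad_status == "incident_AD"
    bad <- which(is_ad & is.na(subjects$onset_age))
    for (r in bad) add("fatal", "subjects", r, "incident_AD without onset_age")
    bad <- which(!is_ad & !is.na(subjects$onset_age))
    for (r in bad) add("fatal", "subjects", r,
                      "onset_age present for non-AD subject")
    bad <- which(is_ad & !is.na(subjects$onset_age) &
                   subjects$onset_age <= subjects$baseline_age)
    for (r in bad) add("fatal", "subjects", r, "onset_age <= baseline_age")
    bad <- which(!is.na(subjects$death_age) &
                   subjects$death_age <= subjects$baseline_age)
    for (r in bad) add("fatal", "subjects", r, "death_age <= baseline_age")
    bad <- which(!subjects$sex %in% c(0, 1))
    for (r in bad) add("fatal", "subjects", r, "sex must be coded 0/1")
    bad <- which(!subjects$education %in% 0:3)
    for (r in bad) add("fatal", "subjects", r, "education must be ordinal 0-3")
    if (anyDuplicated(subjects$id)) {
      add("fatal", "subjects", NA, "duplicate subject ids")
    }
  }
  if (!length(miss_v)) {
    bad <- which(visits$visit_year < 0)
    for (r in bad) add("fatal", "visits", r, "negative visit_year")
    if (!length(miss_s)) {
      orphan <- which(!visits$id %in% subjects$id)
      for (r in head(orphan, 20L)) {
        add("fatal", "visits", r, "visit for unknown subject id")
      }
      ba <- subjects$baseline_age[match(visits$id, subjects$id)]
      drift <- which(!is.na(ba) &
                       abs(visits$age_at_visit - (ba + visits$visit_year)) > 1.0)
      for (r in head(drift, 20L)) {
        add("warning", "visits", r,
            "age_at_visit deviates from baseline_age + visit_year by > 1 year")
      }
      if (anyDuplicated(visits[, c("id", "visit_year")])) {
        add("warning", "visits", NA, "duplicate (id, visit_year) rows")
      }
    }
  }
  out <- if (length(f)) dplyr::bind_rows(f) else
    tibble(severity = character(), table = character(),
           row = integer(), message = character())
  attr(out, "ok") <- !any(out$severity == "fatal")
  out
}

#' Serialize a fitted dynamic model to JSON
#'
#' Writes the complete parameter set of a `cdr_dynfit` (per-domain fixed
#' effects, random-effect covariance and its Cholesky parameters, residual
#' variance, stage-two coefficients, convergence flags, landmark metadata)
#' to a documented JSON schema, reloadable with [read_model_json()] for
#' prediction on new data.
#'
#' @param fit A `cdr_dynfit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(fit, path) {
  stopifnot(inherits(fit, "cdr_dynfit"))
  obj <- list(
    schema = "cogdynrisk-dynfit-1",
    landmark_year = fit$t,
    domains = fit$domains,
    stage1 = lapply(fit$stage1, function(f) {
      list(beta = as.list(f$beta), theta = f$theta, G = f$G,
           sigma2 = f$sigma2, reml_loglik = f$reml_loglik,
           converged = f$converged, slope_pinned = f$slope_pinned,
           n_subjects = f$n_subjects, n_obs = f$n_obs)
    }),
    stage2 = list(gamma = as.list(fit$stage2$gamma_full),
                  loglik = fit$stage2$loglik,
                  converged = fit$stage2$converged,
                  separable = fit$stage2$separable,
                  n = fit$stage2$n, n_events = fit$stage2$n_events),
    constant_features = fit$constant_features,
    n_dropped_missing = fit$n_dropped_missing,
    valid = fit$valid)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Reload a serialized dynamic model
#'
#' Reconstructs a predict-capable `cdr_dynfit` from the JSON written by
#' [write_model_json()] (parameters only; per-subject fitted quantities are
#' not stored).
#'
#' @param path JSON file path.
#' @return A `cdr_dynfit` usable with [predict.cdr_dynfit()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "cogdynrisk-dynfit-1")) {
    stop_bad_arg("unrecognized model schema in %s", path)
  }
  stage1 <- lapply(seq_along(obj$domains), function(k) {
    f <- obj$stage1[[k]]
    structure(list(beta = unlist(f$beta), theta = f$theta,
                   G = matrix(unlist(f$G), 2, 2), sigma2 = f$sigma2,
                   reml_loglik = f$reml_loglik, converged = f$converged,
                   slope_pinned = f$slope_pinned,
                   n_subjects = f$n_subjects, n_obs = f$n_obs,
                   response = obj$domains[k], id = "id",
                   time = "visit_year",
                   covariates = c("baseline_age", "sex", "education")),
              class = "cdr_lmm")
  })
  names(stage1) <- obj$domains
  gamma <- unlist(obj$stage2$gamma)
  stage2 <- structure(
    list(gamma = gamma, gamma_full = gamma,
         loglik = obj$stage2$loglik, converged = obj$stage2$converged,
         separable = obj$stage2$separable, n = obj$stage2$n,
         n_events = obj$stage2$n_events,
         outcome = "outcome",
         features = setdiff(names(gamma), "(Intercept)")),
    class = "cdr_logit")
  structure(list(stage1 = stage1, stage2 = stage2,
                 t = obj$landmark_year, domains = obj$domains,
                 constant_features = obj$constant_features %||% character(),
                 n_dropped_missing = obj$n_dropped_missing,
                 valid = obj$valid),
            class = "cdr_dynfit")
}

default_run_config <- function() {
  list(variant = "lifetime", domains = "all", years = 0:10,
       bootstrap_B = 1000, seed = 1L, out_dir = "cogdynrisk_run",
       allow_partial = FALSE, plots = FALSE, impute_missing_zero = FALSE,
       stepwise_threshold = 0.001, generator = list(),
       subjects_csv = NULL, visits_csv = NULL)
}

#' Run the full dynamic risk analysis end to end
#'
#' Config-driven pipeline: cohort input (generated synthetically or read
#' from CSV), eligibility filtering for the requested analysis variant,
#' the landmark loop with bootstrap-validated AUC per year, calibration at
#' the final landmark, optional stepwise domain selection, and a
#' Table-1-style cohort summary — all written to an output directory
#' together with the resolved configuration, the exclusion tallies, a log,
#' and the final fitted model in JSON. Deterministic given `seed`.
#'
#' @param config A named list or path to a YAML file. Recognized fields:
#'   `variant` (one of `"lifetime"`, `"pre85"`, `"pre90"`, `"horizon5"`,
#'   `"horizon10"`, `"visits3"`, `"visits4"`), `domains` (`"all"`, a
#'   character vector, or `"stepwise"`), `years`, `bootstrap_B`, `seed`,
#'   `out_dir`, `allow_partial`, `plots`, `impute_missing_zero`,
#'   `generator` (arguments to [cohort_config()]) or `subjects_csv` +
#'   `visits_csv`.
#' @return A list of results (class `cdr_run`), invisibly; side effect is
#'   the populated output directory.
#' @export
run_dynamic_analysis <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(default_run_config(), config)
  variants <- c("lifetime", "pre85", "pre90", "horizon5", "horizon10",
                "visits3", "visits4")
  if (!cfg$variant %in% variants) {
    stop_bad_arg("unknown variant '%s'", cfg$variant)
  }
  if (!is.null(cfg$subjects_csv) && length(cfg$generator)) {
    stop_bad_arg("provide either CSV inputs or a generator config, not both")
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  seeds <- derive_seeds(cfg$seed, 8L)
  say("resolved seed: %d (child seeds: %s)", cfg$seed,
      paste(seeds, collapse = ", "))

  # -- input -----------------------------------------------------------
  if (!is.null(cfg$subjects_csv)) {
    subjects <- as_tibble(utils::read.csv(cfg$subjects_csv))
    visits <- as_tibble(utils::read.csv(cfg$visits_csv))
    say("read %d subjects, %d visits from CSV", nrow(subjects), nrow(visits))
    findings <- validate_cohort_tables(subjects, visits)
    utils::write.csv(findings, file.path(cfg$out_dir, "validation.csv"),
                     row.names = FALSE)
    if (!attr(findings, "ok")) {
      stop_bad_arg("fatal schema violations in input CSVs (see validation.csv): %s",
                   paste(head(findings$message[findings$severity == "fatal"], 3),
                         collapse = "; "))
    }
  } else {
    gen_cfg <- do.call(cohort_config, cfg$generator)
    cohort <- generate_cohort(gen_cfg, seed = seeds[1])
    subjects <- cohort$subjects
    visits <- cohort$visits
    say("generated synthetic cohort: %d subjects (%.1f%% incident AD)",
        nrow(subjects), 100 * mean(subjects$ad_status == "incident_AD"))
    utils::write.csv(subjects, file.path(cfg$out_dir, "subjects.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(visits, file.path(cfg$out_dir, "visits.csv"),
                     row.names = FALSE, na = "")
  }

  # -- eligibility -----------------------------------------------------
  elig <- apply_lifetime_eligibility(subjects, visits)
  tally <- dplyr::mutate(elig$tally, stage = "lifetime")
  say("lifetime eligibility: %d retained, removed: %s", nrow(elig$subjects),
      paste(sprintf("%s=%d", elig$tally$rule, elig$tally$n), collapse = " "))
  s_an <- elig$subjects
  if (cfg$variant %in% c("pre85", "pre90")) {
    cut <- if (cfg$variant == "pre85") 85 else 90
    ab <- apply_age_bounded_eligibility(s_an, cut)
    tally <- dplyr::bind_rows(tally,
                              dplyr::mutate(ab$tally, stage = cfg$variant))
    say("%s eligibility: %d retained", cfg$variant, nrow(ab$subjects))
    s_an <- ab$subjects
  }
  v_an <- visits
  if (cfg$variant %in% c("visits3", "visits4")) {
    k <- if (cfg$variant == "visits3") 3L else 4L
    v_an <- subsample_visits(v_an, k, seed = seeds[2])
    say("visit subsampling to k=%d: %d visit rows retained", k, nrow(v_an))
  }
  utils::write.csv(tally, file.path(cfg$out_dir, "exclusion_tally.csv"),
                   row.names = FALSE)

  domains <- if (identical(cfg$domains, "all") ||
                 identical(cfg$domains, "stepwise")) {
    grep("^domain_", names(v_an), value = TRUE)
  } else {
    cfg$domains
  }

  # -- models + evaluation ---------------------------------------------
  results <- list(config = cfg, tally = tally)
  if (cfg$variant %in% c("horizon5", "horizon10")) {
    horizon <- if (cfg$variant == "horizon5") 5 else 10
    hz <- build_horizon_dataset(s_an, v_an, horizon)
    say("horizon-%d dataset: %d subjects (%d dropped without qualifying visits)",
        horizon, nrow(hz$subjects), hz$tally$n[1])
    auc_tab <- bootstrap_auc_ci(hz, domains = domains, B = cfg$bootstrap_B,
                                seed = seeds[3],
                                impute_missing_zero = cfg$impute_missing_zero)
    final_fit <- fit_dynamic_model(hz, domains,
                                   impute_missing_zero = cfg$impute_missing_zero)
  } else {
    auc_tab <- auc_by_year(s_an, v_an, domains = domains, years = cfg$years,
                           B = cfg$bootstrap_B, seed = seeds[3],
                           impute_missing_zero = cfg$impute_missing_zero)
    if (any(!auc_tab$valid) && !cfg$allow_partial) {
      stop_bad_arg("invalid landmark year(s): %s (set allow_partial to continue)",
                   paste(auc_tab$landmark_year[!auc_tab$valid], collapse = ", "))
    }
    final_lmk <- build_landmark_dataset(s_an, v_an, max(cfg$years))
    final_fit <- fit_dynamic_model(final_lmk, domains,
                                   impute_missing_zero = cfg$impute_missing_zero)
  }
  utils::write.csv(auc_tab, file.path(cfg$out_dir, "auc_by_year.csv"),
                   row.names = FALSE)
  results$auc <- auc_tab

  calib <- calibration_deciles(final_fit$risks$risk, final_fit$risks$outcome)
  utils::write.csv(calib, file.path(cfg$out_dir, "calibration.csv"),
                   row.names = FALSE)
  say("final-model Brier score: %.4f", attr(calib, "brier"))
  results$calibration <- calib
  results$final_fit <- final_fit
  write_model_json(final_fit, file.path(cfg$out_dir, "model_final.json"))

  if (identical(cfg$domains, "stepwise")) {
    sw <- stepwise_domain_selection(s_an, v_an, candidates = domains,
                                    t_star = max(cfg$years),
                                    threshold = cfg$stepwise_threshold,
                                    seed = seeds[4])
    utils::write.csv(sw, file.path(cfg$out_dir, "stepwise_path.csv"),
                     row.names = FALSE)
    say("stepwise selection: %s", paste(sw$domain_added, collapse = " -> "))
    results$stepwise <- sw
  }

  tb1 <- tryCatch(cohort_summary(s_an, v_an, domains),
                  error = function(e) NULL)
  if (!is.null(tb1)) {
    utils::write.csv(tb1, file.path(cfg$out_dir, "cohort_table1.csv"),
                     row.names = FALSE)
    results$table1 <- tb1
  }

  if (isTRUE(cfg$plots)) {
    p1 <- autoplot(auc_tab)
    ggplot2::ggsave(file.path(cfg$out_dir, "auc_by_year.svg"), p1,
                    width = 7, height = 5)
    p2 <- autoplot(calib)
    ggplot2::ggsave(file.path(cfg$out_dir, "calibration.svg"), p2,
                    width = 5, height = 5)
  }

  echo <- cfg
  echo$years <- as.integer(echo$years)
  yaml::write_yaml(echo, file.path(cfg$out_dir, "config_echo.yaml"))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  invisible(structure(results, class = "cdr_run"))
}
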