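#' Configuration for the synthetic longitudinal cohort generator
#'
#' Builds and validates the parameter set of the cohort simulator. The
#' defaults emulate the structure of a large US ageing cohort with annual
#' cognitive assessments: baseline age centred in the mid-70s, about three
#' quarters women, four education levels, five correlated z-scored cognitive
#' domain composites that decline faster in subjects who go on to develop
#' AD, roughly a quarter of subjects developing AD during follow-up, a mean
#' of 7-8 annual visits, and deaths without AD from an age-increasing
#' (Gompertz) hazard independent of cognition.
#'
#' The generative risk model has the same functional form as the analysis
#' model: the lifetime AD indicator is Bernoulli with
#' \eqn{\mathrm{logit}\,P = \gamma_0 + \sum_d (\gamma_{0d} b_{0d} +
#' \gamma_{1d} b_{1d}) + \gamma_a (\mathrm{age}-\bar a) + \gamma_s
#' \mathrm{sex} + \gamma_e \mathrm{edu}}, so parameter recovery by the
#' two-stage estimator is well-posed and the true per-subject risk is known.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_age_mean,baseline_age_sd Baseline age distribution, years.
#' @param prop_female Fraction of women (sex coded female = 1).
#' @param education_probs Probabilities of the four ordinal education levels
#'   (0 = no high school ... 3 = college and higher); must sum to 1.
#' @param n_domains Number of cognitive domains (default 5).
#' @param fixed_effects Matrix (`n_domains` x 5) of per-domain fixed effects
#'   on (intercept, time, centred baseline age, sex, education), z-units.
#'   A single row is recycled.
#' @param re_cov 2x2 positive-semidefinite covariance of each domain's
#'   (intercept, slope) random effects (z-units^2, z-units^2/yr^2), or a
#'   list of one matrix per domain.
#' @param domain_correlation Equicorrelation of random effects across
#'   domains, in \[0, 1\].
#' @param residual_sd Residual SD per domain, z-units (recycled).
#' @param risk_coefficients Named list: `intercept`, `b0` (length
#'   `n_domains`), `b1` (length `n_domains`), `age`, `sex`, `education`.
#' @param max_visits Cap on visits per subject (default 11 = baseline plus a
#'   decade of annual follow-up).
#' @param visit_interval Years between visits (default 1).
#' @param dropout_hazard Per-year probability of leaving the study after a
#'   visit.
#' @param death_rate_params Length-2 vector `(rate, age_slope)`: death
#'   hazard at age \eqn{a} is `rate * exp(age_slope * (a - age_center))`.
#' @param onset_params Length-2 vector `(shape, slope_scale)`: for AD
#'   cases, onset is placed at a Beta-distributed fraction of the survival
#'   time, `Beta(shape * exp(-slope_scale * decline), 1.5)`, where
#'   `decline` is the standardized negative sum of the subject's true slope
#'   effects — onset falls late in life and faster decliners convert
#'   earlier, always strictly between baseline and death.
#' @param tests_per_domain Integer counts of raw tests per domain, used by
#'   [generate_raw_tests()]; default `c(4, 2, 7, 3, 3)` (perceptual speed,
#'   visuospatial, episodic, semantic, working memory).
#' @param prop_baseline_impaired,prop_non_ad_dementia,prop_mci Fractions of
#'   subjects flagged for the eligibility filters (impairment at baseline;
#'   non-AD dementia; an MCI onset time drawn uniformly on 1-15 years for
#'   flagged subjects without AD).
#' @param age_center Centring constant for age terms (defaults to
#'   `baseline_age_mean`).
#' @return A validated list of class `cdr_config`.
#' @export
cohort_config <- function(n_subjects = 2000,
                          baseline_age_mean = 77.5,
                          baseline_age_sd = 7.5,
                          prop_female = 0.755,
                          education_probs = c(0.047, 0.131, 0.178, 0.644),
                          n_domains = 5,
                          fixed_effects = NULL,
                          re_cov = matrix(c(0.30, -0.008, -0.008, 0.004), 2, 2),
                          domain_correlation = 0.5,
                          residual_sd = 0.35,
                          risk_coefficients = NULL,
                          max_visits = 11,
                          visit_interval = 1,
                          dropout_hazard = 0.012,
                          death_rate_params = c(rate = 0.028, age_slope = 0.09),
                          onset_params = c(shape = 4.5, slope_scale = 0.5),
                          tests_per_domain = c(4L, 2L, 7L, 3L, 3L),
                          prop_baseline_impaired = 0,
                          prop_non_ad_dementia = 0.01,
                          prop_mci = 0.10,
                          age_center = NULL) {
  n_domains <- as.integer(n_domains)
  if (is.null(fixed_effects)) {
    fixed_effects <- matrix(c(0.25, -0.035, -0.030, 0.10, 0.08),
                            nrow = 1)
  }
  if (is.null(dim(fixed_effects))) fixed_effects <- matrix(fixed_effects, 1)
  if (nrow(fixed_effects) == 1L) {
    fixed_effects <- fixed_effects[rep(1L, n_domains), , drop = FALSE]
  }
  colnames(fixed_effects) <- c("intercept", "time", "age", "sex", "education")
  if (is.matrix(re_cov)) re_cov <- rep(list(re_cov), n_domains)
  residual_sd <- rep_len(residual_sd, n_domains)
  if (is.null(risk_coefficients)) {
    risk_coefficients <- list(intercept = -1.25,
                              b0 = rep(-0.25, n_domains),
                              b1 = rep(-5.5, n_domains),
                              age = 0.04, sex = 0, education = -0.05)
  }
  if (is.null(age_center)) age_center <- baseline_age_mean

  cfg <- list(n_subjects = as.integer(n_subjects),
              baseline_age_mean = baseline_age_mean,
              baseline_age_sd = baseline_age_sd,
              prop_female = prop_female,
              education_probs = education_probs,
              n_domains = n_domains,
              fixed_effects = fixed_effects,
              re_cov = re_cov,
              domain_correlation = domain_correlation,
              residual_sd = residual_sd,
              risk_coefficients = risk_coefficients,
              max_visits = as.integer(max_visits),
              visit_interval = visit_interval,
              dropout_hazard = dropout_hazard,
              death_rate_params = unname(death_rate_params),
              onset_params = unname(onset_params),
              tests_per_domain = as.integer(tests_per_domain),
              prop_baseline_impaired = prop_baseline_impaired,
              prop_non_ad_dementia = prop_non_ad_dementia,
              prop_mci = prop_mci,
              age_center = age_center)
  validate_config(cfg)
  structure(cfg, class = "cdr_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 1L) stop_bad_arg("n_subjects must be >= 1")
    if (baseline_age_sd <= 0 || any(residual_sd <= 0)) {
      stop_bad_arg("all standard deviations must be > 0")
    }
    probs <- c(prop_female, prop_baseline_impaired, prop_non_ad_dementia,
               prop_mci, dropout_hazard, domain_correlation)
    if (any(probs < 0 | probs > 1)) {
      stop_bad_arg("probabilities must lie in [0, 1]")
    }
    if (length(education_probs) != 4L ||
        abs(sum(education_probs) - 1) > 1e-9 || any(education_probs < 0)) {
      stop_bad_arg("education_probs must be a 4-vector of non-negative values summing to 1 (within 1e-9)")
    }
    if (max_visits < 1L) stop_bad_arg("max_visits must be >= 1")
    for (d in seq_len(n_domains)) {
      S <- re_cov[[d]]
      if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10))) {
        stop_bad_arg("re_cov for domain %d is not symmetric", d)
      }
      if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
        stop_bad_arg("re_cov for domain %d is not positive semi-definite", d)
      }
    }
    if (length(risk_coefficients$b0) != n_domains ||
        length(risk_coefficients$b1) != n_domains) {
      stop_bad_arg("risk_coefficients$b0/b1 must have one entry per domain")
    }
    if (any(tests_per_domain < 1L)) {
      stop_bad_arg("tests_per_domain entries must be positive")
    }
    if (length(tests_per_domain) != n_domains) {
      stop_bad_arg("tests_per_domain must have one entry per domain")
    }
  })
  invisible(cfg)
}

# Draws from N(0, S) for a 2x2 PSD S; n x 2 matrix.
rmvn2 <- function(n, S) {
  ev <- eigen(S, symmetric = TRUE)
  A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
  matrix(rnorm(2 * n), n, 2) %*% t(A)
}

#' Generate a synthetic longitudinal cohort with known ground truth
#'
#' Simulates subjects, their annual visit records with per-domain composite
#' scores, and the true subject-level random effects driving both the score
#' trajectories and the lifetime AD outcome. Visits run annually from
#' baseline until the earliest of dropout, death, AD onset (cases only;
#' strictly before onset), and the visit cap. Output is bit-reproducible
#' given `seed`.
#'
#' @param config A [cohort_config()] object.
#' @param seed Integer seed governing all randomness in this call.
#' @return A list of class `cdr_cohort`:
#' \describe{
#'   \item{subjects}{tibble: `id`, `baseline_age`, `sex` (female = 1),
#'     `education` (0-3), `ad_status` (`"incident_AD"` /
#'     `"cognitively_intact"`), `onset_age`, `death_age`,
#'     `last_contact_age`, `mci_flag` (years from baseline, NA if never),
#'     `non_ad_dementia_flag`, `baseline_impaired_flag`, `cohort_label`,
#'     `true_risk` (generating probability).}
#'   \item{visits}{tibble: `id`, `visit_year`, `age_at_visit`,
#'     `domain_1` ... `domain_<D>`.}
#'   \item{effects}{tibble of true random effects: `id`, `domain`, `b0`,
#'     `b1`.}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 300), seed = 42)
#' dplyr::count(cohort$subjects, ad_status)
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  validate_config(config)
  local_seed(seed, {
    n <- config$n_subjects
    D <- config$n_domains
    rc <- config$risk_coefficients

    age0 <- rnorm(n, config$baseline_age_mean, config$baseline_age_sd)
    sex <- rbinom(n, 1, config$prop_female)
    edu <- sample(0:3, n, replace = TRUE, prob = config$education_probs)
    agec <- age0 - config$age_center

    # Cross-domain equicorrelated random effects preserving each domain's
    # marginal covariance: b_d = sqrt(rho) C_d w + sqrt(1 - rho) C_d v_d.
    rho <- config$domain_correlation
    shared <- matrix(rnorm(2 * n), n, 2)
    b0 <- matrix(0, n, D)
    b1 <- matrix(0, n, D)
    for (d in seq_len(D)) {
      ev <- eigen(config$re_cov[[d]], symmetric = TRUE)
      A <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2)
      own <- matrix(rnorm(2 * n), n, 2)
      bd <- (sqrt(rho) * shared + sqrt(1 - rho) * own) %*% t(A)
      b0[, d] <- bd[, 1]
      b1[, d] <- bd[, 2]
    }

    eta <- rc$intercept + drop(b0 %*% rc$b0) + drop(b1 %*% rc$b1) +
      rc$age * agec + rc$sex * sex + rc$education * edu
    true_risk <- plogis(eta)
    ad <- rbinom(n, 1, true_risk) == 1L

    # Death: Gompertz hazard rate * exp(slope * (age - center)), sampled by
    # inversion from each subject's baseline age.
    dr <- config$death_rate_params
    r0 <- dr[1] * exp(dr[2] * agec)
    u <- runif(n)
    death_t <- log1p(-dr[2] * log(u) / r0) / dr[2]
    death_age <- age0 + death_t

    # AD onset strictly between baseline and death: placed as a Beta-
    # distributed fraction of the survival time, Beta(a_i, 1.5) with
    # a_i = shape * exp(-slope_scale * decline), so onset falls late in
    # life (as it must for incident AD observed before death) and faster
    # decliners convert earlier. Generator convention; any placement
    # between baseline and death is admissible.
    op <- config$onset_params
    decline <- -rowSums(b1)
    decline <- decline / sd(decline)
    a_i <- op[1] * exp(-op[2] * decline)
    onset_t <- death_t * stats::qbeta(runif(n), a_i, 1.5)
    onset_age <- ifelse(ad, age0 + onset_t, NA_real_)

    # Visit schedule: annual until min(dropout, death, onset, cap).
    extra <- if (config$dropout_hazard > 0) {
      rgeom(n, config$dropout_hazard)  # visits after baseline if unconstrained
    } else {
      rep(Inf, n)
    }
    horizon_t <- ifelse(ad, onset_t, death_t)
    max_year <- pmin(extra,
                     ceiling(horizon_t / config$visit_interval) - 1L,
                     config$max_visits - 1L)
    max_year <- pmax(max_year, 0L)
    n_visits <- max_year + 1L

    ids <- sprintf("S%05d", seq_len(n))
    idx <- rep(seq_len(n), n_visits)
    vyear <- unlist(lapply(n_visits, function(k) seq_len(k) - 1L),
                    use.names = FALSE) * config$visit_interval
    age_visit <- age0[idx] + vyear

    fe <- config$fixed_effects
    scores <- matrix(NA_real_, length(idx), D)
    for (d in seq_len(D)) {
      mu <- fe[d, 1] + fe[d, 2] * vyear + fe[d, 3] * agec[idx] +
        fe[d, 4] * sex[idx] + fe[d, 5] * edu[idx] +
        b0[idx, d] + b1[idx, d] * vyear
      scores[, d] <- mu + rnorm(length(idx), 0, config$residual_sd[d])
    }
    colnames(scores) <- paste0("domain_", seq_len(D))

    # Flags consumed by the eligibility filters.
    impaired <- runif(n) < config$prop_baseline_impaired
    non_ad_dem <- !ad & runif(n) < config$prop_non_ad_dementia
    mci_draw <- runif(n) < config$prop_mci
    mci_flag <- ifelse(!ad & mci_draw, runif(n, 1, 15), NA_real_)
    mci_flag[ad & mci_draw] <- pmax(0.5, onset_t[ad & mci_draw] -
                                      runif(sum(ad & mci_draw), 1, 3))

    last_contact <- age0 + (n_visits - 1L) * config$visit_interval

    subjects <- tibble(
      id = ids, baseline_age = age0, sex = sex, education = edu,
      ad_status = ifelse(ad, "incident_AD", "cognitively_intact"),
      onset_age = onset_age, death_age = death_age,
      last_contact_age = last_contact,
      mci_flag = mci_flag,
      non_ad_dementia_flag = non_ad_dem,
      baseline_impaired_flag = impaired,
      cohort_label = "synthetic",
      true_risk = true_risk)
    visits <- dplyr::bind_cols(
      tibble(id = ids[idx], visit_year = vyear, age_at_visit = age_visit),
      as_tibble(scores))
    effects <- tibble(id = rep(ids, each = D),
                      domain = rep(paste0("domain_", seq_len(D)), n),
                      b0 = as.vector(t(b0)), b1 = as.vector(t(b1)))
    structure(list(subjects = subjects, visits = visits, effects = effects,
                   config = config),
              class = "cdr_cohort")
  })
}

#' @export
print.cdr_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort: %d subjects, %d visits, %d domains; %.1f%% incident AD\n",
    nrow(x$subjects), nrow(x$visits), x$config$n_domains,
    100 * mean(x$subjects$ad_status == "incident_AD")))
  invisible(x)
}

#' Canonical test-to-domain mapping for the five cognitive domains
#'
#' The 19 neuropsychological tests and the domain each contributes to:
#' 4 perceptual-speed, 2 visuospatial, 7 episodic-memory, 3 semantic-memory
#' and 3 working-memory tests.
#'
#' @return Tibble with columns `test` and `domain`.
#' @export
cognitive_test_map <- function() {
  tibble(
    test = c("symbol_digit", "number_comparison", "stroop_color_naming",
             "stroop_word_reading",
             "line_orientation", "progressive_matrices",
             "word_list_immediate", "word_list_recall", "word_list_recognition",
             "east_boston_immediate", "east_boston_delayed",
             "logical_memory_immediate", "logical_memory_delayed",
             "boston_naming", "category_fluency", "reading_test",
             "digits_forward", "digits_backward", "digit_ordering"),
    domain = rep(c("perceptual_speed", "visuospatial", "episodic_memory",
                   "semantic_memory", "working_memory"),
                 times = c(4L, 2L, 7L, 3L, 3L)))
}

#' Generate raw test scores consistent with simulated domain composites
#'
#' Expands each visit's domain composite into `tests_per_domain[d]` raw test
#' scores: each test is the composite rescaled to a test-specific mean and
#' SD plus independent noise. Re-standardizing the raw tests and averaging
#' within domain approximately recovers the composite, which makes the
#' composite-construction pipeline testable end to end.
#'
#' @param visits Visit table containing `domain_*` composite columns.
#' @param config The [cohort_config()] that produced the visits.
#' @param seed Integer seed.
#' @param noise_sd SD of the per-test noise on the z-scale (default 0.2; 0
#'   makes each test an exact affine image of its composite).
#' @return List with `raw` (tibble: `id`, `visit_year`, one column per
#'   test) and `test_map` (tibble: `test`, `domain`, with the true `mean`
#'   and `sd` used for rescaling). Test columns reuse the canonical test
#'   names when `tests_per_domain` matches [cognitive_test_map()], else
#'   `d<d>_test<k>`.
#' @export
generate_raw_tests <- function(visits, config, seed, noise_sd = 0.2) {
  validate_config(config)
  D <- config$n_domains
  cols <- paste0("domain_", seq_len(D))
  missing_cols <- setdiff(cols, names(visits))
  if (length(missing_cols)) {
    stop_bad_arg("visit table lacks composite column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  canonical <- identical(config$tests_per_domain, c(4L, 2L, 7L, 3L, 3L)) &&
    D == 5L
  map <- if (canonical) {
    cognitive_test_map()
  } else {
    tibble(
      test = unlist(lapply(seq_len(D), function(d) {
        sprintf("d%d_test%d", d, seq_len(config$tests_per_domain[d]))
      }), use.names = FALSE),
      domain = rep(cols, config$tests_per_domain))
  }
  if (canonical) {
    map$domain <- cols[match(map$domain, unique(map$domain))]
  }
  nt <- nrow(map)
  map$mean <- 10 + 3 * seq_len(nt)
  map$sd <- 1 + 0.5 * (seq_len(nt) %% 4)

  local_seed(seed, {
    raw <- matrix(NA_real_, nrow(visits), nt)
    for (k in seq_len(nt)) {
      comp <- visits[[map$domain[k]]]
      z <- comp + if (noise_sd > 0) rnorm(length(comp), 0, noise_sd) else 0
      raw[, k] <- map$mean[k] + map$sd[k] * z
    }
    colnames(raw) <- map$test
    list(raw = dplyr::bind_cols(visits[, c("id", "visit_year")],
                                as_tibble(raw)),
         test_map = map)
  })
}
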