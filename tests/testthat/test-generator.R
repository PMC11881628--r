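test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(n_subjects = 120)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$visits, b$visits)
  expect_identical(a$effects, b$effects)
  c <- generate_cohort(cfg, seed = 8)
  expect_false(identical(a$subjects, c$subjects))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(re_cov = matrix(c(1, 2, 2, 1), 2, 2)),
               "positive semi-definite")
  expect_error(cohort_config(re_cov = matrix(c(1, 0.1, 0.2, 1), 2, 2)),
               "symmetric")
  expect_error(cohort_config(education_probs = c(0.3, 0.3, 0.3, 0.3)),
               "summing to 1")
  expect_error(cohort_config(prop_female = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(residual_sd = 0), "> 0")
  expect_error(cohort_config(max_visits = 0), "max_visits")
  expect_error(cohort_config(tests_per_domain = c(4L, -1L, 7L, 3L, 3L)),
               "positive")
})

test_that("marginals at n = 5000 match the configuration", {
  cfg <- cohort_config(n_subjects = 5000)
  co <- generate_cohort(cfg, seed = 31)
  s <- co$subjects
  expect_lt(abs(mean(s$baseline_age) - cfg$baseline_age_mean), 0.5)
  expect_lt(abs(mean(s$sex) - cfg$prop_female), 0.02)
  expect_lte(max(table(co$visits$id)), cfg$max_visits)
})

test_that("visit schedules respect death and AD onset", {
  co <- std_cohort(n = 800)$cohort
  v <- dplyr::inner_join(co$visits, co$subjects, by = "id")
  expect_true(all(v$age_at_visit < v$death_age))
  ad <- v[v$ad_status == "incident_AD", ]
  expect_true(all(ad$age_at_visit < ad$onset_age))
  s <- co$subjects
  expect_true(all(is.na(s$onset_age) == (s$ad_status != "incident_AD")))
  expect_true(all(s$onset_age > s$baseline_age, na.rm = TRUE))
  expect_true(all(s$onset_age < s$death_age, na.rm = TRUE))
})

test_that("zero risk signal gives prevalence logistic(intercept) and null AUC", {
  cfg <- cohort_config(
    n_subjects = 4000,
    risk_coefficients = list(intercept = -1, b0 = rep(0, 5), b1 = rep(0, 5),
                             age = 0, sex = 0, education = 0))
  co <- generate_cohort(cfg, seed = 11)
  y <- as.integer(co$subjects$ad_status == "incident_AD")
  expect_lt(abs(mean(y) - plogis(-1)), 0.025)
  eff <- tidyr::pivot_wider(co$effects, names_from = "domain",
                            values_from = c("b0", "b1"))
  auc <- compute_auc(eff$b1_domain_1[match(co$subjects$id, eff$id)], y)
  expect_lt(abs(auc - 0.5), 0.03)
})

test_that("stage-1 REML recovers the generating variance components", {
  # re_cov diag(0.25, 0.01), residual sd 0.3 at n = 2000
  cfg <- cohort_config(n_subjects = 2000,
                       re_cov = matrix(c(0.25, 0, 0, 0.01), 2, 2),
                       residual_sd = 0.3, dropout_hazard = 0)
  co <- generate_cohort(cfg, seed = 5)
  dat <- dplyr::inner_join(co$visits, co$subjects, by = "id")
  fit <- fit_lmm_reml(dat, domain_1)
  expect_true(fit$converged)
  expect_lt(abs(fit$G[1, 1] - 0.25) / 0.25, 0.15)
  expect_lt(abs(fit$G[2, 2] - 0.01) / 0.01, 0.15)
  expect_lt(abs(fit$sigma2 - 0.09) / 0.09, 0.15)
})

test_that("stronger slope signal raises the year-10 AUC", {
  scales <- c(0, -3, -8)
  mean_auc <- vapply(scales, function(b1c) {
    aucs <- vapply(1:5, function(sd) {
      cfg <- cohort_config(
        n_subjects = 1500,
        risk_coefficients = list(intercept = -1.25, b0 = rep(-0.25, 5),
                                 b1 = rep(b1c, 5), age = 0.04, sex = 0,
                                 education = -0.05))
      co <- generate_cohort(cfg, seed = 200 + sd)
      el <- apply_lifetime_eligibility(co$subjects, co$visits)
      lmk <- build_landmark_dataset(el$subjects, co$visits, 10)
      fit <- fit_dynamic_model(lmk)
      compute_auc(fit$risks$risk, fit$risks$outcome)
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  expect_true(all(diff(mean_auc) > 0))
})

test_that("raw tests invert to the generating composites", {
  cfg <- cohort_config(n_subjects = 60, tests_per_domain = rep(1L, 5))
  co <- generate_cohort(cfg, seed = 3)
  rt <- generate_raw_tests(co$visits, cfg, seed = 4, noise_sd = 0)
  comp <- compute_domain_composites(
    rt$raw, rt$test_map,
    stats = rt$test_map[, c("test", "mean", "sd")])
  for (d in paste0("domain_", 1:5)) {
    expect_lt(max(abs(comp[[d]] - co$visits[[d]])), 1e-9)
  }
})

test_that("noisy multi-test composites correlate strongly with the truth", {
  cfg <- cohort_config(n_subjects = 200, tests_per_domain = rep(3L, 5))
  co <- generate_cohort(cfg, seed = 13)
  expect_gte(nrow(co$visits), 1000)
  rt <- generate_raw_tests(co$visits, cfg, seed = 14, noise_sd = 0.2)
  comp <- compute_domain_composites(rt$raw, rt$test_map)
  for (d in paste0("domain_", 1:3)) {
    expect_gt(cor(comp[[d]], co$visits[[d]]), 0.9)
  }
})

test_that("raw-test generation validates its inputs", {
  cfg <- cohort_config(n_subjects = 20)
  co <- generate_cohort(cfg, seed = 2)
  bad <- co$visits[, setdiff(names(co$visits), "domain_5")]
  expect_error(generate_raw_tests(bad, cfg, seed = 1), "domain_5")
})
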