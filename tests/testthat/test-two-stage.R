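test_that("the landmark-0 pipeline returns valid risks with pinned slopes", {
  co <- std_cohort(n = 400)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 0)
  fit <- suppressWarnings(fit_dynamic_model(lmk))
  expect_true(fit$valid)
  expect_true(all(fit$risks$risk >= 0 & fit$risks$risk <= 1))
  # slope summaries are all zero at a single-visit landmark -> excluded
  expect_true(all(paste0("b1_domain_", 1:5) %in% fit$constant_features))
  td <- tidy(fit)
  expect_true(all(td$estimate[td$constant] == 0))
})

test_that("stage two weights the truly informative slope most heavily", {
  cfg <- cohort_config(
    n_subjects = 1500,
    risk_coefficients = list(intercept = -1.3, b0 = rep(0, 5),
                             b1 = c(0, 0, -8, 0, 0), age = 0, sex = 0,
                             education = 0),
    domain_correlation = 0)
  co <- generate_cohort(cfg, seed = 71)
  el <- apply_lifetime_eligibility(co$subjects, co$visits)
  lmk <- build_landmark_dataset(el$subjects, co$visits, 10)
  fit <- fit_dynamic_model(lmk)
  td <- tidy(fit)
  slopes <- td[grepl("^b1_", td$term), ]
  zmax <- slopes$term[which.max(abs(slopes$statistic))]
  expect_identical(zmax, "b1_domain_3")
})

test_that("a one-domain model equals the multi-domain fit on one domain", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 8)
  fit1 <- fit_dynamic_model(lmk, domains = "domain_2")
  lmk2 <- lmk
  lmk2$visits <- lmk$visits[, c("id", "visit_year", "age_at_visit",
                                "domain_2")]
  fit2 <- fit_dynamic_model(lmk2)
  expect_equal(fit1$stage2$gamma_full, fit2$stage2$gamma_full,
               tolerance = 1e-10)
  expect_equal(fit1$risks$risk, fit2$risks$risk, tolerance = 1e-10)
})

test_that("the pipeline is invariant to subject relabeling and row order", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 6)
  fit1 <- fit_dynamic_model(lmk)
  lmk2 <- lmk
  relabel <- setNames(sprintf("zz%04d", seq_len(nrow(lmk$subjects))),
                      lmk$subjects$id)
  lmk2$subjects$id <- unname(relabel[lmk2$subjects$id])
  lmk2$visits$id <- unname(relabel[lmk2$visits$id])
  set.seed(1)
  lmk2$visits <- lmk2$visits[sample(nrow(lmk2$visits)), ]
  lmk2$subjects <- lmk2$subjects[sample(nrow(lmk2$subjects)), ]
  fit2 <- fit_dynamic_model(lmk2)
  expect_equal(sort(unname(fit1$stage2$gamma_full)),
               sort(unname(fit2$stage2$gamma_full)), tolerance = 1e-6)
  r1 <- fit1$risks$risk[order(fit1$risks$id)]
  orig_of <- setNames(names(relabel), unname(relabel))
  r2 <- fit2$risks$risk[order(orig_of[fit2$risks$id])]
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("repeat fits on identical inputs are identical", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 5)
  fit1 <- fit_dynamic_model(lmk)
  fit2 <- fit_dynamic_model(lmk)
  expect_identical(fit1$stage2$gamma_full, fit2$stage2$gamma_full)
  expect_identical(fit1$risks, fit2$risks)
})

test_that("subjects missing a whole domain are dropped or zero-imputed", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 6)
  blank_id <- lmk$subjects$id[1]
  lmk$visits$domain_4[lmk$visits$id == blank_id] <- NA
  fit <- fit_dynamic_model(lmk)
  expect_identical(fit$n_dropped_missing, 1L)
  expect_false(blank_id %in% fit$risks$id)
  fit0 <- fit_dynamic_model(lmk, impute_missing_zero = TRUE)
  expect_identical(fit0$n_dropped_missing, 0L)
  expect_true(blank_id %in% fit0$risks$id)
})

test_that("a manual three-visit subject reproduces the closed-form pipeline", {
  # fixed stage-1 parameters
  beta <- c(`(Intercept)` = 0.3, visit_year = -0.04, baseline_age = -0.02,
            sex = 0.1, education = 0.05)
  G <- matrix(c(0.2, -0.01, -0.01, 0.008), 2, 2)
  s2 <- 0.09
  L <- t(chol(G / s2))
  fit1 <- structure(list(beta = beta, G = G, sigma2 = s2,
                         theta = c(L[1, 1], L[2, 1], L[2, 2]),
                         response = "domain_1", id = "id",
                         time = "visit_year",
                         covariates = c("baseline_age", "sex", "education")),
                    class = "cdr_lmm")
  visits <- tibble::tibble(id = "w", visit_year = 0:2,
                           age_at_visit = 76:78,
                           baseline_age = 76, sex = 1, education = 2,
                           domain_1 = c(0.4, 0.1, -0.3))
  eb <- compute_eblup(fit1, visits)
  # dense GLS evaluation
  X <- cbind(1, 0:2, 76, 1, 2)
  Z <- cbind(1, 0:2)
  V <- Z %*% G %*% t(Z) + s2 * diag(3)
  bhat <- drop(G %*% t(Z) %*% solve(V, visits$domain_1 - X %*% beta))
  expect_equal(c(eb$b0_hat, eb$b1_hat), bhat, tolerance = 1e-10)
  # stage 2 by hand
  gamma <- c(b0_domain_1 = -0.5, b1_domain_1 = -4, baseline_age = 0.03,
             sex = 0.1, education = -0.05, `(Intercept)` = -1)
  fit2 <- structure(list(gamma = gamma,
                         features = names(gamma)[-6]), class = "cdr_logit")
  feats <- tibble::tibble(b0_domain_1 = eb$b0_hat, b1_domain_1 = eb$b1_hat,
                          baseline_age = 76, sex = 1, education = 2)
  lp <- sum(gamma[-6] * as.numeric(feats[1, ])) + unname(gamma[6])
  expect_equal(predict_risk(fit2, feats), plogis(lp), tolerance = 1e-12)
})

test_that("serialized models reload and reproduce predictions", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 6)
  fit <- fit_dynamic_model(lmk)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$stage2$gamma_full, fit$stage2$gamma_full,
               tolerance = 1e-12)
  p1 <- predict(fit, lmk$subjects, lmk$visits)
  p2 <- predict(back, lmk$subjects, lmk$visits)
  expect_equal(p1$risk, p2$risk, tolerance = 1e-9)
  # predictions agree with the in-sample fitted risks
  m <- match(fit$risks$id, p1$id)
  expect_equal(p1$risk[m], fit$risks$risk, tolerance = 1e-6)
})

test_that("prediction requires complete demographics", {
  co <- std_cohort(n = 300)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 4)
  fit <- fit_dynamic_model(lmk)
  s <- lmk$subjects[1:5, ]
  s$education[2] <- NA
  expect_error(predict(fit, s, lmk$visits), "demographic")
})
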