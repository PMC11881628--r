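test_that("AUC matches hand-checkable instances", {
  expect_equal(compute_auc(c(0.9, 0.1), c(1, 0)), 1.0)
  expect_equal(compute_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(compute_auc(c(3, 1, 2, 4), c(1, 0, 1, 0)), 0.5)
  expect_error(compute_auc(c(1, 2), c(1, 1)), "both classes")
  expect_error(compute_auc(1:3, 1:2), "length")
})

test_that("AUC equals pair enumeration on random tied and untied instances", {
  set.seed(12)
  for (i in 1:50) {
    n <- sample(5:120, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_identical(compute_auc(scores, labels),
                     auc_by_enumeration(scores, labels))
  }
})

test_that("Brier score matches its definition and validates inputs", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 8), rbinom(8, 1, 0.5)), 0.25)
  expect_equal(brier_score(c(0.8, 0.4), c(1, 0)), (0.04 + 0.16) / 2)
  expect_error(brier_score(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("decile calibration partitions subjects into ten bins", {
  set.seed(14)
  p <- runif(500)
  y <- rbinom(500, 1, p)
  cal <- calibration_deciles(p, y)
  expect_identical(nrow(cal), 10L)
  expect_identical(sum(cal$n), 500L)
  expect_equal(attr(cal, "brier"), brier_score(p, y))
  expect_warning(calibration_deciles(rep(c(0.2, 0.8), 10), rbinom(20, 1, 0.5)),
                 "distinct")
  expect_error(calibration_deciles(runif(5), rbinom(5, 1, 0.5)), "at least 10")
})

test_that("the DeLong test is null for identical scores and antisymmetric", {
  set.seed(15)
  s <- rnorm(60)
  lab <- rep(c(1, 0), 30)
  same <- delong_test(s, s, lab)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  s2 <- rnorm(60)
  ab <- delong_test(s, s2, lab)
  ba <- delong_test(s2, s, lab)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p_value, ba$p_value)
  expect_error(delong_test(s, s2[-1], lab), "equal length")
})

test_that("DeLong variance matches direct placement-value enumeration", {
  set.seed(16)
  n1 <- 10; n0 <- 10
  lab <- rep(c(1, 0), c(n1, n0))
  sa <- rnorm(20); sb <- 0.5 * sa + rnorm(20)
  got <- delong_test(sa, sb, lab)
  # brute force: psi matrices and placement variances
  psi <- function(s) outer(s[lab == 1], s[lab == 0],
                           function(a, b) (a > b) + 0.5 * (a == b))
  pa <- psi(sa); pb <- psi(sb)
  v10 <- rowMeans(pa) - rowMeans(pb)
  v01 <- colMeans(pa) - colMeans(pb)
  vd <- var(v10) / n1 + var(v01) / n0
  z <- (mean(pa) - mean(pb)) / sqrt(vd)
  expect_equal(got$auc_a, mean(pa), tolerance = 1e-12)
  expect_equal(got$auc_b, mean(pb), tolerance = 1e-12)
  expect_equal(got$z, z, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-10)
})

test_that("DeLong agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  lab <- rep(c(1, 0), c(40, 60))
  sa <- rnorm(100) + lab
  sb <- rnorm(100) + 0.5 * lab
  got <- delong_test(sa, sb, lab)
  ref <- pROC::roc.test(pROC::roc(lab, sa, quiet = TRUE),
                        pROC::roc(lab, sb, quiet = TRUE), method = "delong")
  expect_equal(unname(got$p_value), unname(ref$p.value), tolerance = 1e-8)
})

test_that("a two-pattern cohort has a degenerate bootstrap distribution", {
  # every subject is a copy of one case or one control pattern
  n <- 40
  s <- tibble::tibble(id = sprintf("p%02d", 1:n),
                      baseline_age = 75, sex = rep(c(1, 0), n / 2),
                      education = 2,
                      ad_status = rep(c("incident_AD", "cognitively_intact"),
                                      n / 2),
                      outcome = rep(c(1L, 0L), n / 2))
  v <- tidyr::crossing(id = s$id, visit_year = 0:5)
  v$age_at_visit <- 75 + v$visit_year
  case <- s$outcome[match(v$id, s$id)] == 1
  v$domain_1 <- ifelse(case, 0.5 - 0.3 * v$visit_year, 0.5) +
    0.01 * sin(seq_len(nrow(v)))  # tiny jitter keeps variances positive
  lmk <- build_landmark_dataset(s, v, 5)
  # the perfectly separated patterns make the logistic MLE divergent by
  # construction (flagged), so the resampling distribution is examined in
  # re-scoring mode: with no sampling variability the interval collapses
  res <- suppressWarnings(bootstrap_auc_ci(lmk, domains = "domain_1",
                                           B = 40, seed = 2, refit = FALSE))
  expect_equal(res$auc, 1.0)
  expect_lt(res$ci_high - res$ci_low, 1e-9)
})

test_that("the fast re-scoring bootstrap runs without refitting", {
  co <- std_cohort(n = 400)
  lmk <- build_landmark_dataset(co$subjects, co$visits, 6)
  res <- bootstrap_auc_ci(lmk, B = 50, seed = 3, refit = FALSE)
  expect_true(res$ci_low < res$auc & res$auc < res$ci_high)
  expect_error(bootstrap_auc_ci(lmk, B = 1, seed = 1), "B must be")
})

test_that("bootstrap interval width shrinks with sample size", {
  small <- std_cohort(n = 200, seed = 61)
  big <- std_cohort(n = 1600, seed = 62)
  w <- vapply(list(small, big), function(co) {
    lmk <- build_landmark_dataset(co$subjects, co$visits, 8)
    r <- bootstrap_auc_ci(lmk, domains = "domain_1", B = 60, seed = 4)
    r$ci_high - r$ci_low
  }, numeric(1))
  expect_lt(w[2], w[1])
})

test_that("stepwise selection finds the informative domain first", {
  hits <- 0L
  n_runs <- 40L
  for (i in seq_len(n_runs)) {
    cfg <- cohort_config(
      n_subjects = 600,
      risk_coefficients = list(intercept = -1.4, b0 = c(0, 0, -1.5, 0, 0),
                               b1 = c(0, 0, -8, 0, 0), age = 0, sex = 0,
                               education = 0),
      domain_correlation = 0,
      onset_params = c(4.5, 0))  # onset timing independent of decline
    co <- generate_cohort(cfg, seed = 500 + i)
    el <- apply_lifetime_eligibility(co$subjects, co$visits)
    path <- stepwise_domain_selection(el$subjects, co$visits,
                                      candidates = paste0("domain_", 1:5),
                                      t_star = 10)
    hits <- hits + (path$domain_added[1] == "domain_3")
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("redundant candidate domains stop the selection after one step", {
  co <- std_cohort(n = 400)
  v <- co$visits
  v$domain_2 <- v$domain_1
  v$domain_3 <- v$domain_1
  path <- stepwise_domain_selection(co$subjects, v,
                                    candidates = paste0("domain_", 1:3),
                                    t_star = 8)
  expect_identical(nrow(path), 1L)
  expect_identical(formals(stepwise_domain_selection)$threshold, 0.001)
  expect_error(stepwise_domain_selection(co$subjects, v, "domain_1"),
               "at least 2")
})

test_that("the annual AUC table has one row per requested year", {
  co <- std_cohort(n = 400)
  tab <- suppressWarnings(  # landmark 0 legitimately pins the slope variance
    auc_by_year(co$subjects, co$visits, domains = "domain_1",
                years = c(0, 4, 8), B = 20, seed = 9))
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$landmark_year, c(0, 4, 8))
  expect_true(all(tab$valid))
  expect_true(all(tab$ci_low <= tab$auc & tab$auc <= tab$ci_high))
  expect_s3_class(autoplot(tab), "ggplot")
})
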