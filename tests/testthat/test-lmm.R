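simulate_lmm <- function(nsub, nvis, beta = c(0.2, -0.05, -0.01, 0.1, 0.05),
                         G = matrix(c(0.25, 0, 0, 0.01), 2, 2),
                         sigma = 0.3, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(nsub), each = nvis)
  tt <- rep(seq_len(nvis) - 1, nsub)
  age <- rep(rnorm(nsub, 77, 7), each = nvis)
  sex <- rep(rbinom(nsub, 1, 0.75), each = nvis)
  edu <- rep(sample(0:3, nsub, TRUE), each = nvis)
  ev <- eigen(G, symmetric = TRUE)
  b <- matrix(rnorm(2 * nsub), nsub, 2) %*%
    (diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors))
  y <- beta[1] + beta[2] * tt + beta[3] * age + beta[4] * sex + beta[5] * edu +
    b[id, 1] + b[id, 2] * tt + rnorm(length(id), 0, sigma)
  tibble::tibble(id = id, visit_year = tt, baseline_age = age, sex = sex,
                 education = edu, score = y)
}

# Recovery design with covariates informative enough to identify every
# coefficient (time-varying, well spread): a coefficient of 0.01 cannot be
# pinned to 10% by any estimator when its covariate is subject-constant and
# the random-intercept SD is 0.5, so the identification scale is part of
# the design, not a property of the estimator.
simulate_lmm_recovery <- function(nsub, nvis,
                                  beta = c(0.2, -0.05, -0.01, 0.1, 0.05),
                                  G = matrix(c(0.25, 0, 0, 0.01), 2, 2),
                                  sigma = 0.3, seed = 1) {
  set.seed(seed)
  id <- rep(seq_len(nsub), each = nvis)
  tt <- rep(seq_len(nvis) - 1, nsub)
  n <- nsub * nvis
  X <- cbind(rnorm(n, 0, 5), rnorm(n, 0, 5), rnorm(n, 0, 5))
  ev <- eigen(G, symmetric = TRUE)
  b <- matrix(rnorm(2 * nsub), nsub, 2) %*%
    (diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors))
  y <- beta[1] + beta[2] * tt + drop(X %*% beta[3:5]) +
    b[id, 1] + b[id, 2] * tt + rnorm(n, 0, sigma)
  tibble::tibble(id = id, visit_year = tt, baseline_age = X[, 1],
                 sex = X[, 2], education = X[, 3], score = y)
}

test_that("REML recovers the generating parameters at n = 1000 x 8", {
  beta <- c(0.2, -0.05, -0.01, 0.1, 0.05)
  dat <- simulate_lmm_recovery(1000, 8, beta = beta, seed = 77)
  fit <- fit_lmm_reml(dat, score)
  expect_true(fit$converged)
  expect_true(all(abs(fit$beta - beta) / abs(beta) < 0.10))
  expect_lt(abs(fit$G[1, 1] - 0.25) / 0.25, 0.20)
  expect_lt(abs(fit$G[2, 2] - 0.01) / 0.01, 0.20)
  expect_lt(abs(fit$sigma2 - 0.09) / 0.09, 0.20)
})

test_that("a noise-free dataset pins the residual variance at zero", {
  # sigma2 = 0 and G = 0: the response is exactly linear in the fixed effects
  set.seed(3)
  nsub <- 40
  id <- rep(seq_len(nsub), each = 3)
  tt <- rep(0:2, nsub)
  age <- rep(rnorm(nsub, 75, 5), each = 3)
  sex <- rep(rbinom(nsub, 1, 0.5), each = 3)
  edu <- rep(sample(0:3, nsub, TRUE), each = 3)
  y <- 1 + 0.5 * tt - 0.02 * age + 0.3 * sex + 0.1 * edu
  dat <- tibble::tibble(id = id, visit_year = tt, baseline_age = age,
                        sex = sex, education = edu, score = y)
  fit <- fit_lmm_reml(dat, score)
  expect_lte(fit$sigma2, 1e-6)
  ols <- coef(lm(score ~ visit_year + baseline_age + sex + education, dat))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 1e-6)
})

test_that("balanced random-intercept case matches the ANOVA closed form", {
  set.seed(8)
  nsub <- 60
  nvis <- 5
  id <- rep(seq_len(nsub), each = nvis)
  a <- rnorm(nsub, 0, sqrt(0.4))
  y <- 2 + a[id] + rnorm(nsub * nvis, 0, 0.5)
  dat <- tibble::tibble(id = id, visit_year = 0, baseline_age = 70,
                        sex = 0, education = 0, score = y)
  fit <- fit_lmm_reml(dat, score, covariates = character())
  mse <- sum(tapply(y, id, function(v) sum((v - mean(v))^2))) /
    (nsub * (nvis - 1))
  msa <- nvis * sum((tapply(y, id, mean) - mean(y))^2) / (nsub - 1)
  expect_equal(fit$sigma2, mse, tolerance = 1e-6)
  expect_equal(fit$G[1, 1], (msa - mse) / nvis, tolerance = 1e-6)
})

test_that("estimates agree with a reference mixed-model implementation", {
  skip_if_not_installed("lme4")
  suppressMessages(requireNamespace("lme4"))
  for (i in 1:50) {
    dat <- simulate_lmm(40, 6,
                        G = matrix(c(0.3, -0.02, -0.02, 0.015), 2, 2),
                        sigma = 0.4, seed = 1000 + i)
    fit <- fit_lmm_reml(dat, score)
    ref <- suppressWarnings(suppressMessages(lme4::lmer(
      score ~ visit_year + baseline_age + sex + education +
        (1 + visit_year | id), dat, REML = TRUE)))
    vc <- lme4::VarCorr(ref)$id
    expect_lt(max(abs(fit$beta - lme4::fixef(ref))), 1e-4)
    expect_lt(max(abs(fit$G - vc[1:2, 1:2])), 1e-3)
    expect_lt(abs(fit$sigma2 - attr(lme4::VarCorr(ref), "sc")^2), 1e-3)
  }
})

test_that("the REML objective never ends above its starting value", {
  dat <- simulate_lmm(80, 5, seed = 5)
  fit <- fit_lmm_reml(dat, score)
  st <- c(0.8, 0, 0.15)
  X <- cbind(1, dat$visit_year, dat$baseline_age, dat$sex, dat$education)
  ss <- cdr_suffstats(X, dat$score, dat$visit_year, as.integer(factor(dat$id)),
                      length(unique(dat$id)))
  obj_at <- function(th) {
    cdr_reml_eval(th, ss, crossprod(X), drop(crossprod(X, dat$score)),
                  sum(dat$score^2))$objective
  }
  expect_lte(obj_at(fit$theta), obj_at(st))
})

test_that("single-visit data pin the slope variance with a warning", {
  dat <- simulate_lmm(50, 1, seed = 11)
  expect_warning(fit <- fit_lmm_reml(dat, score), "pinned")
  expect_true(fit$slope_pinned)
  expect_identical(unname(fit$G[2, 2]), 0)
  eb <- compute_eblup(fit, dat)
  expect_true(all(eb$b1_hat == 0))
})

test_that("EBLUPs vanish at G = 0 and reach subject OLS as noise vanishes", {
  dat <- simulate_lmm(30, 4, seed = 21)
  fit <- fit_lmm_reml(dat, score)
  fit0 <- fit
  fit0$theta <- c(0, 0, 0)
  eb0 <- compute_eblup(fit0, dat)
  expect_true(all(eb0$b0_hat == 0 & eb0$b1_hat == 0))

  # sigma2 -> 0: predictions approach each subject's own least-squares
  # deviation from the fixed-effect fit
  fit_small <- fit
  fit_small$theta <- fit$theta * 1e4  # relative covariance huge vs noise
  eb <- compute_eblup(fit_small, dat)
  one <- dat[dat$id == 1, ]
  r <- one$score - cbind(1, one$visit_year, one$baseline_age, one$sex,
                         one$education) %*% fit$beta
  ls <- coef(lm(r ~ one$visit_year))
  expect_equal(eb$b0_hat[eb$id == "1"], unname(ls[1]), tolerance = 1e-3)
  expect_equal(eb$b1_hat[eb$id == "1"], unname(ls[2]), tolerance = 1e-3)
})

test_that("EBLUP shrinkage never exceeds the raw subject deviation", {
  # intercept-only case: |bhat| <= |subject mean residual deviation|
  set.seed(31)
  nsub <- 40
  id <- rep(seq_len(nsub), each = 3)
  y <- rnorm(nsub, 0, 0.7)[id] + rnorm(3 * nsub, 0, 0.5)
  dat <- tibble::tibble(id = id, visit_year = 0, baseline_age = 70, sex = 0,
                        education = 0, score = y)
  fit <- fit_lmm_reml(dat, score, covariates = character())
  eb <- compute_eblup(fit, dat)
  dev <- tapply(y - mean(fit$beta[1]) - (y * 0), id, mean)
  dev <- tapply(dat$score, dat$id, mean) - fit$beta[1]
  expect_true(all(abs(eb$b0_hat) <= abs(dev[eb$id]) + 1e-12))
})

test_that("fits are invariant to row order and subject relabeling", {
  dat <- simulate_lmm(40, 5, seed = 41)
  fit1 <- fit_lmm_reml(dat, score)
  shuf <- dat[sample(nrow(dat)), ]
  shuf$id <- paste0("zz", shuf$id)
  fit2 <- fit_lmm_reml(shuf, score)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-8)
  expect_equal(fit1$G, fit2$G, tolerance = 1e-8)
  expect_equal(fit1$reml_loglik, fit2$reml_loglik, tolerance = 1e-8)
})

test_that("non-finite responses and missing columns are rejected", {
  dat <- simulate_lmm(10, 3)
  dat$score[4] <- Inf
  expect_error(fit_lmm_reml(dat, score), "non-finite")
  expect_error(fit_lmm_reml(dat[, -3], score), "not found")
})

test_that("tidy and glance expose the fit components", {
  dat <- simulate_lmm(60, 5, seed = 51)
  fit <- fit_lmm_reml(dat, score)
  td <- tidy(fit)
  expect_identical(td$term[1:2], c("(Intercept)", "visit_year"))
  expect_true(all(is.finite(td$std.error)))
  gl <- glance(fit)
  expect_identical(gl$n_subjects, 60L)
  expect_true(gl$converged)
})
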