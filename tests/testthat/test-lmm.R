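test_that("design rows implement the centred quartic age/BMI basis", {
  d <- build_design(50, 25, centering = 10)
  expect_equal(as.numeric(d$x), c(1, 0, 0, 0, 0, 25, 0))
  expect_equal(as.numeric(d$z), c(1, 0))
  d <- build_design(55, 20, centering = 10)
  expect_equal(as.numeric(d$x), c(1, 1, 1, 1, 1, 20, 20))
  expect_equal(as.numeric(d$z), c(1, 1))
  d <- build_design(45, 30, centering = 0)
  expect_equal(unname(d$x[1, 5]), 9^4)   # a = 9, quartic term 6561
  expect_equal(unname(d$x[1, 7]), 9 * 30)
})

test_that("marginal log-likelihood matches the dense MVN oracle and is additive", {
  p <- test_params()
  co <- random_cohort(n = 5, max_k = 4, seed = 11)
  expect_equal(lmm_marginal_loglik(p, co), dense_loglik_oracle(p, co),
               tolerance = 1e-10)
  # additivity over independent women
  ids <- unique(co$screens$woman_id)
  parts <- vapply(ids, function(id) {
    sub <- structure(list(
      screens = co$screens[co$screens$woman_id == id, ],
      outcomes = co$outcomes[co$outcomes$woman_id == id, ]),
      class = "cohort")
    lmm_marginal_loglik(p, sub)
  }, numeric(1))
  expect_equal(sum(parts), lmm_marginal_loglik(p, co), tolerance = 1e-10)
  # G = 0, single screen: univariate normal closed form
  p0 <- lmm_params(p$beta, matrix(0, 2, 2), p$sigma2, p$centering)
  one <- structure(list(
    screens = co$screens[co$screens$woman_id == ids[1], ][1, ],
    outcomes = co$outcomes[co$outcomes$woman_id == ids[1], ]),
    class = "cohort")
  d <- build_design(one$screens$age, one$screens$bmi, p$centering)
  mu <- as.numeric(d$x %*% p0$beta)
  expect_equal(lmm_marginal_loglik(p0, one),
               dnorm(one$screens$birads, mu, sqrt(p0$sigma2), log = TRUE))
})

test_that("ML fit degenerates to pooled OLS when data carry no random effects", {
  # simulate with G = 0 and small noise; beta-hat must match OLS closely
  p <- lmm_params(c(2.6, -0.08, 0, 0, 0, -0.03, 0.001),
                  matrix(0, 2, 2), 0.1, 10)
  cfg <- sim_config(n_women = 400, seed = 21, true_lmm = p,
                    discretize = FALSE,
                    bmi_missing_baseline = 0, bmi_missing_followup = 0)
  co <- simulate_cohort(cfg)$cohort
  fit <- fit_lmm_ml(co)
  s <- co$screens
  d <- build_design(s$age, s$bmi, 10)
  ols <- lm.fit(d$x, s$birads)$coefficients
  expect_lt(max(abs(fit$params$beta - ols)), 1e-3)
  expect_lt(fit$params$G[1, 1], 5e-3)
})

test_that("ML recovers generating parameters and beats the truth's likelihood", {
  cfg <- sim_config(n_women = 1200, seed = 31, discretize = FALSE,
                    bmi_missing_baseline = 0, bmi_missing_followup = 0)
  co <- simulate_cohort(cfg)$cohort
  truth <- cfg$true_lmm
  fit <- fit_lmm_ml(co)
  expect_true(fit$converged)
  # optimality: fitted loglik >= loglik at the generating parameters
  expect_gte(fit$loglik + 1e-6, lmm_marginal_loglik(truth, co))
  # variance components in the right neighbourhood (single replicate here;
  # the multi-replicate 3-MC-SE check runs in the acceptance suite)
  expect_equal(fit$params$G[1, 1], truth$G[1, 1], tolerance = 0.15)
  expect_equal(fit$params$sigma2, truth$sigma2, tolerance = 0.1)
})

test_that("fitted values are invariant to the centering constant", {
  cfg <- sim_config(n_women = 300, seed = 41, discretize = FALSE,
                    bmi_missing_baseline = 0, bmi_missing_followup = 0)
  co <- simulate_cohort(cfg)$cohort
  f0 <- fit_lmm_ml(co, centering = 0)
  f10 <- fit_lmm_ml(co, centering = 10)
  expect_equal(f0$loglik, f10$loglik, tolerance = 1e-7)
  e0 <- sequential_estimates(co, f0$params)
  e10 <- sequential_estimates(co, f10$params)
  expect_lt(max(abs(e0$value - e10$value)), 1e-6)
})

test_that("profiled beta satisfies the GLS normal equations at the optimum", {
  co <- random_cohort(n = 40, max_k = 5, seed = 51)
  fit <- fit_lmm_ml(co)
  p <- fit$params
  s <- co$screens
  score <- numeric(7)
  for (id in unique(s$woman_id)) {
    rows <- s[s$woman_id == id, ]
    d <- build_design(rows$age, rows$bmi, p$centering)
    V <- d$z %*% p$G %*% t(d$z) + p$sigma2 * diag(nrow(rows))
    score <- score + as.numeric(crossprod(d$x, solve(V, rows$birads -
                                                       d$x %*% p$beta)))
  }
  expect_lt(sqrt(sum(score^2)), 1e-6)
})

test_that("ML estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("nlme")
  cfg <- sim_config(n_women = 250, seed = 61, discretize = FALSE,
                    bmi_missing_baseline = 0, bmi_missing_followup = 0)
  co <- simulate_cohort(cfg)$cohort
  fit <- fit_lmm_ml(co)
  s <- co$screens
  d <- build_design(s$age, s$bmi, 10)
  df <- data.frame(y = s$birads, a = d$x[, 2], a2 = d$x[, 3], a3 = d$x[, 4],
                   a4 = d$x[, 5], bmi = d$x[, 6], abmi = d$x[, 7],
                   id = s$woman_id)
  ref <- nlme::lme(y ~ a + a2 + a3 + a4 + bmi + abmi,
                   random = ~ a | id, data = df, method = "ML",
                   control = nlme::lmeControl(opt = "optim",
                                              returnObject = TRUE))
  # likelihood cross-check: my marginal loglik evaluated at nlme's
  # estimates must equal nlme's reported logLik
  refp <- lmm_params(nlme::fixef(ref),
                     matrix(nlme::getVarCov(ref), 2, 2),
                     ref$sigma^2, centering = 10)
  expect_equal(lmm_marginal_loglik(refp, co),
               as.numeric(stats::logLik(ref)), tolerance = 1e-6)
  # optimizer cross-check: my ML optimum is at least as good as nlme's
  expect_gte(fit$loglik, as.numeric(stats::logLik(ref)) - 1e-6)
  expect_equal(unname(fit$params$beta), unname(nlme::fixef(ref)),
               tolerance = 0.05)
})

test_that("robust sandwich covariance is symmetric PSD and near model-based SEs", {
  cfg <- sim_config(n_women = 800, seed = 71, discretize = FALSE,
                    bmi_missing_baseline = 0, bmi_missing_followup = 0)
  co <- simulate_cohort(cfg)$cohort
  fit <- fit_lmm_ml(co)
  rob <- robust_sandwich_cov(fit, co)
  expect_equal(rob, t(rob), tolerance = 1e-12)
  expect_gte(min(eigen(rob, symmetric = TRUE, only.values = TRUE)$values),
             -1e-12)
  # correctly specified model: robust SEs within 20% of model-based SEs
  ss <- longdens:::lmm_suffstats(co, fit$params$centering)
  A <- longdens:::lmm_beta_scores(fit$params, ss)$A
  se_model <- sqrt(diag(solve(A)))
  se_rob <- sqrt(diag(rob))
  expect_true(all(abs(se_rob / se_model - 1) < 0.2))
})

test_that("single-screen clusters collapse the sandwich B to per-observation form", {
  co <- random_cohort(n = 30, max_k = 1, seed = 81)
  fit <- fit_lmm_ml(co)
  expect_false(fit$G_identified)
  p <- fit$params
  ss <- longdens:::lmm_suffstats(co, p$centering)
  sc <- longdens:::lmm_beta_scores(p, ss)
  # every woman has one screen: per-woman scores are per-observation scores
  s <- co$screens
  d <- build_design(s$age, s$bmi, p$centering)
  v <- as.numeric(d$z %*% p$G %*% t(d$z))  # not used when k = 1 per woman
  r <- s$birads - d$x %*% p$beta
  Vii <- rowSums((d$z %*% p$G) * d$z) + p$sigma2
  per_obs <- crossprod(d$x * as.numeric(r) / Vii)
  expect_equal(unname(crossprod(sc$scores)), unname(per_obs),
               tolerance = 1e-8)
})

test_that("parameter files round-trip through JSON exactly", {
  p <- test_params()
  f <- tempfile(fileext = ".json")
  write_lmm_params(p, f)
  q <- read_lmm_params(f)
  expect_equal(p$beta, q$beta)
  expect_equal(p$G, q$G)
  expect_equal(p$sigma2, q$sigma2)
  expect_equal(p$centering, q$centering)
})
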