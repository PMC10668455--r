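test_that("empty history returns the prior; G = 0 pins the posterior at zero", {
  p <- test_params()
  post <- eb_posterior(matrix(0, 0, 7), matrix(0, 0, 2), numeric(0), p)
  expect_equal(post$b_hat, c(0, 0))
  expect_equal(post$b_cov, p$G)
  p0 <- lmm_params(p$beta, matrix(0, 2, 2), p$sigma2, p$centering)
  d <- build_design(c(48, 50, 53), c(24, 25, 26), 10)
  post0 <- eb_posterior(d$x, d$z, c(4, 4, 4), p0)
  expect_equal(post0$b_hat, c(0, 0))
  # and the prediction falls back to the population surface
  v <- predict_longitudinal_density(list(age = 48, bmi = 24, birads = 4),
                                    50, 25, p0)
  expect_equal(v, as.numeric(build_design(50, 25, 10)$x %*% p$beta))
})

test_that("one-observation posterior matches a 2-D numeric-integration Bayes oracle", {
  p <- test_params()
  d <- build_design(56, 28, 10)
  y <- 3
  # grid integration of prior N(0, G) x likelihood over the random effects
  r <- as.numeric(y - d$x %*% p$beta)
  sd0 <- sqrt(p$G[1, 1]); sd1 <- sqrt(p$G[2, 2])
  b0 <- seq(-6 * sd0, 6 * sd0, length.out = 601)
  b1 <- seq(-6 * sd1, 6 * sd1, length.out = 601)
  gr <- expand.grid(b0 = b0, b1 = b1)
  Ginv <- solve(p$G)
  logprior <- -0.5 * (Ginv[1, 1] * gr$b0^2 + 2 * Ginv[1, 2] * gr$b0 * gr$b1 +
                        Ginv[2, 2] * gr$b1^2)
  mu <- d$z[1, 1] * gr$b0 + d$z[1, 2] * gr$b1
  loglik <- -0.5 * (r - mu)^2 / p$sigma2
  wgt <- exp(logprior + loglik)
  oracle <- c(sum(gr$b0 * wgt), sum(gr$b1 * wgt)) / sum(wgt)
  post <- eb_posterior(d$x, d$z, y, p)
  expect_lt(max(abs(post$b_hat - oracle)), 1e-4)
})

test_that("posterior equals the dense-matrix BLUP on randomized histories", {
  p <- test_params()
  set.seed(99)
  for (rep in 1:25) {
    k <- sample(1:10, 1)
    ages <- sort(45 + cumsum(runif(k, 0.5, 2)))
    bmis <- runif(k, 18, 34)
    d <- build_design(ages, bmis, 10)
    y <- sample(1:4, k, replace = TRUE)
    post <- eb_posterior(d$x, d$z, y, p)
    oracle <- dense_blup_oracle(d$x, d$z, y, p)
    expect_lt(max(abs(post$b_hat - oracle$b_hat)), 1e-8)
    expect_lt(max(abs(post$b_cov - oracle$b_cov)), 1e-8)
  }
})

test_that("sequential estimates equal per-screen dense BLUP predictions", {
  p <- test_params()
  co <- random_cohort(n = 20, max_k = 6, seed = 7)
  est <- sequential_estimates(co, p)
  s <- co$screens
  for (i in seq_len(nrow(s))) {
    id <- s$woman_id[i]
    prior <- which(s$woman_id == id & s$exam_time <= s$exam_time[i])
    d <- build_design(s$age[prior], s$bmi[prior], p$centering)
    oracle <- dense_blup_oracle(d$x, d$z, s$birads[prior], p)
    dt <- build_design(s$age[i], s$bmi[i], p$centering)
    v <- as.numeric(dt$x %*% p$beta + dt$z %*% oracle$b_hat)
    expect_lt(abs(est$value[i] - v), 1e-8)
    expect_equal(est$n_obs_used[i], length(prior))
  }
})

test_that("estimates have no lookahead and shrink toward the population mean", {
  p <- test_params()
  co <- random_cohort(n = 12, max_k = 6, seed = 13)
  est <- sequential_estimates(co, p)
  # appending a later screen never changes earlier estimates
  s <- co$screens
  id <- names(which.max(table(s$woman_id)))
  trunc_screens <- s[s$woman_id != id | seq_len(nrow(s)) %in%
                       utils::head(which(s$woman_id == id), 2), ]
  trunc <- structure(list(screens = trunc_screens,
                          outcomes = co$outcomes), class = "cohort")
  # outcomes mismatch is irrelevant for estimation; rebuild a valid cohort
  trunc <- cohort_table(trunc_screens,
                        co$outcomes[co$outcomes$woman_id %in%
                                      trunc_screens$woman_id, ])
  est_t <- sequential_estimates(trunc, p)
  joint <- merge(est, est_t, by = c("woman_id", "exam_time"))
  expect_equal(joint$value.x, joint$value.y, tolerance = 1e-12)

  # shrinkage on a constant-design flip-flopping woman
  screens <- data.frame(woman_id = "f", exam_time = (0:3) * 1e-3,
                        age = 50 + (0:3) * 1e-3, bmi = 25,
                        birads = c(3, 2, 3, 2))
  outcomes <- data.frame(woman_id = "f", exit_time = 5, event = 0,
                         censor_reason = "admin_end")
  flip <- cohort_table(screens, outcomes)
  est_f <- sequential_estimates(flip, p)
  expect_lt(diff(range(est_f$value)), diff(range(screens$birads)))
  # |estimate - population mean| <= |running mean reading - population mean|
  mu <- as.numeric(build_design(screens$age, screens$bmi, 10)$x %*% p$beta)
  run_mean <- cumsum(screens$birads) / (1:4)
  expect_true(all(abs(est_f$value - mu) <= abs(run_mean - mu) + 1e-9))
})

test_that("posterior covariance is non-increasing in history length", {
  p <- test_params()
  ages <- c(47, 49, 50.5, 52, 54)
  d <- build_design(ages, rep(26, 5), 10)
  y <- c(2, 3, 2, 2, 3)
  prev <- p$G
  for (k in 1:5) {
    post <- eb_posterior(d$x[1:k, , drop = FALSE], d$z[1:k, , drop = FALSE],
                         y[1:k], p)
    dmat <- prev - post$b_cov
    expect_gte(min(eigen(dmat, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
    prev <- post$b_cov
  }
})

test_that("with G = 0 the estimate is the fixed-effect age-BMI surface", {
  p <- test_params()
  p0 <- lmm_params(p$beta, matrix(0, 2, 2), p$sigma2, p$centering)
  co <- random_cohort(n = 10, max_k = 4, seed = 17)
  est <- sequential_estimates(co, p0)
  d <- build_design(co$screens$age, co$screens$bmi, p$centering)
  expect_equal(est$value, as.numeric(d$x %*% p$beta), tolerance = 1e-12)
})

test_that("categorisation respects the published boundary conventions", {
  cuts <- default_cutpoints()
  expect_equal(categorize(3.7, cuts), 8L)    # >= 3.6 is Extremely dense II
  expect_equal(categorize(1.49, cuts), 1L)   # < 1.5 is Fatty I
  expect_equal(categorize(2.0, cuts), 3L)    # 2.0 opens Scattered I
  expect_equal(categorize(c(-5, 1.5, 2.19, 2.6, 3.59, 99), cuts),
               c(1L, 2L, 3L, 5L, 7L, 8L))
  est_cat4 <- ceiling(categorize(c(1.4, 1.8, 2.1, 2.5, 2.7, 3.0, 3.4, 4.0),
                                 cuts) / 2)
  expect_equal(est_cat4, c(1, 1, 2, 2, 3, 3, 4, 4))
})

test_that("derived cut points split the baseline distribution as intended", {
  # uniform values with equal BI-RADS quarters -> evenly spaced octile cuts
  n <- 4000
  vals <- (seq_len(n) - 0.5) / n
  birads <- rep(1:4, each = n / 4)
  cuts <- derive_cutpoints(vals, birads)
  expect_equal(cuts$thresholds, seq(0.125, 0.875, by = 0.125),
               tolerance = 1e-3)
  # self-consistency: applying the cuts reproduces the eight target
  # proportions within 1/n each
  set.seed(31)
  vals2 <- rnorm(n, 2.6, 0.7)
  birads2 <- pmin(pmax(round(vals2 + rnorm(n, 0, 0.4)), 1), 4)
  cuts2 <- derive_cutpoints(vals2, birads2)
  got <- tabulate(categorize(vals2, cuts2), 8) / n
  p <- tabulate(birads2, 4) / n
  target <- rep(p / 2, each = 2)
  expect_true(all(abs(got - target) <= 1 / n + 1e-12))
  expect_error(derive_cutpoints(1:5, rep(1, 5)), "at least 8")
  # degenerate: everything BI-RADS A collapses the upper cuts
  expect_warning(derive_cutpoints(vals, rep(1L, n)), "degenerate")
})

test_that("cut points round-trip through JSON with provenance", {
  f <- tempfile(fileext = ".json")
  write_cutpoints(default_cutpoints(), f, provenance = "paper_default")
  j <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(j$provenance, "paper_default")
  expect_equal(read_cutpoints(f)$thresholds, default_cutpoints()$thresholds)
})
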