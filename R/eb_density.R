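#' Category cut points for the eight-level longitudinal density measure
#'
#' Seven thresholds splitting the continuous measure into eight categories
#' ('Fatty' I/II, 'Scattered' I/II, 'Heterogeneous' I/II, 'Extremely dense'
#' I/II). [default_cutpoints()] returns the published reference values
#' (1.5, 2.0, 2.2, 2.6, 2.9, 3.2, 3.6), which are only meaningful together
#' with a compatible parameter file; cut points are re-derived with
#' [derive_cutpoints()] whenever the model is refit.
#'
#' @param thresholds seven non-decreasing reals
#' @return object of class `"cutpoints"`
#' @export
cutpoints <- function(thresholds) {
  thresholds <- as.numeric(thresholds)
  stopifnot(length(thresholds) == 7)
  if (is.unsorted(thresholds)) stop("cut points must be non-decreasing")
  if (any(diff(thresholds) == 0))
    warning("degenerate cut points: ties present; some categories are empty")
  structure(list(thresholds = thresholds), class = "cutpoints")
}

#' @rdname cutpoints
#' @export
default_cutpoints <- function() {
  cutpoints(c(1.5, 2.0, 2.2, 2.6, 2.9, 3.2, 3.6))
}

#' Empirical-Bayes posterior of a woman's random effects
#'
#' Given a woman's observation history and the population parameters,
#' returns the posterior mean and covariance of her random intercept and
#' age slope: \eqn{\hat b = G Z' V^{-1} (y - X\beta)} and
#' \eqn{\mathrm{Cov} = G - G Z' V^{-1} Z G} with
#' \eqn{V = Z G Z' + \sigma^2 I}. An empty history returns the prior
#' (mean 0, covariance G). Computed through the Cholesky factor of G, so a
#' singular G (including G = 0) is handled exactly.
#'
#' @param x k x 7 fixed-effects design matrix of the history (may have 0 rows)
#' @param z k x 2 random-effects design matrix
#' @param y length-k vector of observed readings
#' @param params an [lmm_params()] object
#' @return list with `b_hat` (length 2) and `b_cov` (2 x 2)
#' @export
eb_posterior <- function(x, z, y, params) {
  x <- matrix(x, ncol = 7)
  z <- matrix(z, ncol = 2)
  L <- chol_psd(params$G)
  s2 <- params$sigma2
  if (length(y) == 0L)
    return(list(b_hat = c(0, 0), b_cov = params$G))
  r <- as.numeric(y - x %*% params$beta)
  K <- diag(2) + crossprod(z %*% L) / s2
  Ki <- solve(K)
  b_hat <- as.numeric(L %*% Ki %*% crossprod(L, crossprod(z, r)) / s2)
  b_cov <- L %*% Ki %*% t(L)
  list(b_hat = b_hat, b_cov = (b_cov + t(b_cov)) / 2)
}

#' Predict continuous longitudinal density at a time point
#'
#' The continuous longitudinal density at (age_t, bmi_t) given the history
#' observed so far: the population surface \eqn{x'\beta} plus the
#' empirical-Bayes random-effect prediction \eqn{z'\hat b}. The output is
#' real-valued and deliberately not clipped to [1, 4]; the categorical
#' measure absorbs the tails.
#'
#' @param history list with elements `age`, `bmi`, `birads` (equal-length
#'   vectors; may be empty) — the screens observed up to the prediction time
#' @param age_t,bmi_t age and (preprocessed) BMI at the prediction point
#' @param params an [lmm_params()] object
#' @return scalar density value
#' @export
predict_longitudinal_density <- function(history, age_t, bmi_t, params) {
  d <- if (length(history$age))
    build_design(history$age, history$bmi, params$centering)
  else list(x = matrix(0, 0, 7), z = matrix(0, 0, 2))
  post <- eb_posterior(d$x, d$z, history$birads, params)
  dt <- build_design(age_t, bmi_t, params$centering)
  as.numeric(dt$x %*% params$beta + dt$z %*% post$b_hat)
}

#' Sequential per-screen density estimates for a whole cohort
#'
#' For each woman and each screen k (in time order) computes the
#' longitudinal density estimate using her screens 1..k inclusive (set
#' `inclusive = FALSE` to exclude the current screen's reading, for
#' sensitivity analyses). Estimates at screen k never use later screens.
#' Implemented with within-woman cumulative sufficient statistics, so the
#' whole cohort is processed in vectorised closed form.
#'
#' @param cohort preprocessed `"cohort"` (no missing bmi/birads)
#' @param params an [lmm_params()] object
#' @param cuts a [cutpoints()] object used to attach categories
#' @param inclusive include the current screen's reading (default TRUE)
#' @return data.frame with columns `woman_id`, `exam_time`, `value`,
#'   `eb_intercept`, `eb_slope`, `n_obs_used`, `category8`, `category4`
#' @export
sequential_estimates <- function(cohort, params, cuts = default_cutpoints(),
                                 inclusive = TRUE) {
  s <- cohort$screens
  if (anyNA(s$bmi) || anyNA(s$birads))
    stop("cohort must be preprocessed: no missing bmi/birads")
  d <- build_design(s$age, s$bmi, params$centering)
  a <- d$z[, 2]
  r <- as.numeric(s$birads - d$x %*% params$beta)
  id <- s$woman_id
  csum <- function(v) stats::ave(v, id, FUN = cumsum)
  n_k <- csum(rep(1, length(r)))
  Sa <- csum(a); Sa2 <- csum(a * a)
  Sr <- csum(r); Sar <- csum(a * r)
  if (!inclusive) {
    # drop the current row's contribution from each cumulative statistic
    n_used <- n_k - 1
    Sa <- Sa - a; Sa2 <- Sa2 - a * a; Sr <- Sr - r; Sar <- Sar - a * r
  } else n_used <- n_k
  L <- chol_psd(params$G)
  s2 <- params$sigma2
  l11 <- L[1, 1]; l21 <- L[2, 1]; l22 <- L[2, 2]
  # K = I + L' Szz L / s2 with Szz = [[n, Sa], [Sa, Sa2]]
  c11 <- l11^2 * n_used + 2 * l11 * l21 * Sa + l21^2 * Sa2
  c12 <- l11 * l22 * Sa + l21 * l22 * Sa2
  c22 <- l22^2 * Sa2
  k11 <- 1 + c11 / s2; k12 <- c12 / s2; k22 <- 1 + c22 / s2
  detK <- k11 * k22 - k12 * k12
  # w = L' Z' r = (l11 Sr + l21 Sar, l22 Sar)
  w1 <- l11 * Sr + l21 * Sar
  w2 <- l22 * Sar
  # K^-1 w
  q1 <- (k22 * w1 - k12 * w2) / detK
  q2 <- (-k12 * w1 + k11 * w2) / detK
  b0 <- (l11 * q1) / s2
  b1 <- (l21 * q1 + l22 * q2) / s2
  value <- as.numeric(d$x %*% params$beta) + b0 + a * b1
  cat8 <- categorize(value, cuts)
  data.frame(woman_id = id, exam_time = s$exam_time, value = value,
             eb_intercept = b0, eb_slope = b1, n_obs_used = n_used,
             category8 = cat8, category4 = ceiling(cat8 / 2),
             stringsAsFactors = FALSE)
}

#' Categorise continuous density into the eight-level measure
#'
#' Left-closed, right-open intervals: category j iff
#' `cuts[j-1] <= value < cuts[j]` (outer bounds at -Inf and +Inf); a value
#' exactly on a boundary goes to the upper category, matching the
#' "(2.0 to < 2.2)" convention of the published category table.
#'
#' @param value numeric vector of continuous density values
#' @param cuts a [cutpoints()] object
#' @return integer vector of categories 1--8
#' @export
categorize <- function(value, cuts = default_cutpoints()) {
  findInterval(value, cuts$thresholds) + 1L
}

#' Derive eight-category cut points from the baseline distribution
#'
#' Chooses thresholds so that the baseline proportions of women in derived
#' categories 1--2, 3--4, 5--6 and 7--8 match the baseline BI-RADS A--D
#' proportions, with an equal split inside each pair (e.g. the lower half of
#' BI-RADS A at baseline lands in category 1, the upper half in category 2).
#' Quantiles use the inverse empirical CDF (type 1: lower value at ties).
#'
#' @param baseline_values continuous densities at baseline, one per woman
#' @param baseline_birads baseline BI-RADS readings (integers 1--4)
#' @return a [cutpoints()] object
#' @export
derive_cutpoints <- function(baseline_values, baseline_birads) {
  stopifnot(length(baseline_values) == length(baseline_birads))
  if (length(baseline_values) < 8)
    stop("validation error: need at least 8 baseline observations")
  p <- tabulate(baseline_birads, nbins = 4) / length(baseline_birads)
  cp <- cumsum(p)
  probs <- c(p[1] / 2, cp[1], cp[1] + p[2] / 2, cp[2], cp[2] + p[3] / 2,
             cp[3], cp[3] + p[4] / 2)
  th <- stats::quantile(baseline_values, probs = probs, type = 1,
                        names = FALSE)
  cutpoints(th)
}

#' Write density estimates and cut points to disk
#'
#' `estimates.csv` holds one row per (woman, screen); `cutpoints.json`
#' records the thresholds and their provenance (`"paper_default"` for the
#' published reference values, `"derived"` for refit-derived ones).
#'
#' @param estimates data.frame from [sequential_estimates()]
#' @param path output CSV path
#' @export
write_estimates <- function(estimates, path) {
  utils::write.csv(estimates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_estimates
#' @param cuts a [cutpoints()] object
#' @param provenance `"paper_default"` or `"derived"`
#' @export
write_cutpoints <- function(cuts, path, provenance = "derived") {
  jsonlite::write_json(list(thresholds = cuts$thresholds,
                            provenance = provenance),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_estimates
#' @export
read_cutpoints <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutpoints(j$thresholds)
}
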