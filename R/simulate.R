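#' Default generative parameters of the synthetic screening cohort
#'
#' The defaults emulate a community screening cohort: staggered baseline
#' ages uniform on 40--73 (median 50), inter-screen gaps averaging 1.8
#' years, per-visit stopping that combines with the censoring process so
#' the median woman has 3 screens and roughly a quarter have a baseline
#' screen only, BMI centred near 27 kg/m²
#' with ~5% missing at baseline and ~16% at follow-up, a latent density
#' trajectory whose discretised readings give roughly 8/35/43/14%
#' A/B/C/D at baseline, and a proportional hazard in the TRUE latent
#' density (linear log-HR 1.71, quadratic -0.19 about reference density
#' 2.6) with baseline rate 0.003/yr, giving ~2% cumulative incidence.
#'
#' @return an [lmm_params()] object (for `default_true_lmm`) or a
#'   `"sim_config"` list (for `sim_config`)
#' @export
default_true_lmm <- function() {
  lmm_params(beta = c(3.7, -0.08, -0.003, 4e-4, -5e-5, -0.04, 0.001),
             G = matrix(c(0.45, -0.0085, -0.0085, 0.004), 2, 2),
             sigma2 = 0.15, centering = 10)
}

#' @rdname default_true_lmm
#' @param n_women number of women to simulate
#' @param seed RNG seed; every stream of randomness flows from it
#' @param true_lmm generative [lmm_params()] for the latent trajectory
#' @param age0_range baseline-age range, years
#' @param bmi0_intercept,bmi0_slope baseline BMI mean as a linear function
#'   of (age0 - 50); kg/m² and kg/m² per yr
#' @param bmi_sd between-woman baseline BMI SD, kg/m²
#' @param bmi_drift mean BMI change per year, kg/m²
#' @param bmi_missing_baseline,bmi_missing_followup missingness probabilities
#' @param interscreen_mean,interscreen_sd inter-screen gap distribution, yr
#' @param screen_stop_prob per-visit probability that a woman stops screening
#' @param max_screens cap on screens per woman
#' @param discretize round-and-clip readings to integers 1--4 (TRUE) or
#'   report the continuous noisy reading (FALSE)
#' @param hazard list: `log_hr_density`, `log_hr_density2`, `log_hr_age0`,
#'   `log_hr_bmi`, `baseline_rate` (per yr), and reference values
#'   `density_ref`, `age_ref`, `bmi_ref` the log-linear terms are centred at
#' @param admin_end administrative end of follow-up, years after entry
#' @param followup_shape shape of the right-skewed potential-follow-up draw
#'   (larger = shorter follow-up; 2.2 gives median ~5 yr at admin_end 19)
#' @param age_censor censoring age, years
#' @export
sim_config <- function(n_women = 2000, seed = 1,
                       true_lmm = default_true_lmm(),
                       age0_range = c(40, 73),
                       bmi0_intercept = 27, bmi0_slope = 0.05,
                       bmi_sd = 5.5, bmi_drift = 0.1,
                       bmi_missing_baseline = 0.05,
                       bmi_missing_followup = 0.16,
                       interscreen_mean = 1.8, interscreen_sd = 0.5,
                       screen_stop_prob = 0.05, max_screens = 10,
                       discretize = TRUE,
                       hazard = list(log_hr_density = 1.71,
                                     log_hr_density2 = -0.19,
                                     log_hr_age0 = 0.05,
                                     log_hr_bmi = 0.005,
                                     baseline_rate = 0.003,
                                     density_ref = 2.6, age_ref = 50,
                                     bmi_ref = 27),
                       admin_end = 19, followup_shape = 2.2,
                       age_censor = 75) {
  cfg <- list(n_women = n_women, seed = seed, true_lmm = true_lmm,
              age0_range = age0_range, bmi0_intercept = bmi0_intercept,
              bmi0_slope = bmi0_slope, bmi_sd = bmi_sd,
              bmi_drift = bmi_drift,
              bmi_missing_baseline = bmi_missing_baseline,
              bmi_missing_followup = bmi_missing_followup,
              interscreen_mean = interscreen_mean,
              interscreen_sd = interscreen_sd,
              screen_stop_prob = screen_stop_prob,
              max_screens = max_screens, discretize = discretize,
              hazard = hazard, admin_end = admin_end,
              followup_shape = followup_shape, age_censor = age_censor)
  stopifnot(n_women >= 1, interscreen_mean > 0, interscreen_sd >= 0,
            bmi_sd > 0, hazard$baseline_rate >= 0,
            bmi_missing_baseline >= 0, bmi_missing_baseline <= 1,
            bmi_missing_followup >= 0, bmi_missing_followup <= 1,
            screen_stop_prob >= 0, screen_stop_prob < 1)
  if (max_screens < 1)
    stop("validation error: config implies zero screens")
  structure(cfg, class = "sim_config")
}

#' Round-and-clip a latent density to an integer BI-RADS reading
#'
#' Adds Gaussian reading noise, rounds to the nearest integer and clips to
#' the 1--4 scale. Uses the current RNG stream.
#'
#' @param latent latent density value(s)
#' @param sigma reading-noise standard deviation (>= 0)
#' @return integer vector in 1--4
#' @export
discretize_birads <- function(latent, sigma) {
  stopifnot(sigma >= 0)
  noisy <- latent + if (sigma > 0) stats::rnorm(length(latent), 0, sigma)
  else 0
  pmin(pmax(round(noisy), 1L), 4L)
}

#' Simulate a synthetic screening cohort with known truth
#'
#' Per woman: baseline age uniform in range; random intercept/slope
#' b ~ N(0, G); screens at jittered ~1.8-yr intervals until geometric
#' stopping, the screen cap, or the end of her potential follow-up; BMI as
#' a drifting random walk with missingness; latent density
#' \eqn{x'\beta + z'b}; the observed reading adds N(0, sigma²) noise and is
#' (optionally) rounded and clipped to 1--4. The invasive-cancer event time
#' is drawn from a piecewise-exponential hazard
#' `baseline_rate * exp(lp)` whose linear predictor uses the TRUE latent
#' density (linear + quadratic), baseline age and current BMI, each centred
#' at its reference value, and is piecewise constant between screens. Exit
#' is the earliest of the event, the administrative end, and the age-75
#' crossing. Fully reproducible under the config seed.
#'
#' @param config a [sim_config()]
#' @return list with `cohort` (a `"cohort"`) and `truth`: `women`
#'   (woman_id, age0, b0, b1, potential follow-up) and `screens`
#'   (woman_id, exam_time, latent density)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(config$seed)
  p <- config$true_lmm
  Lg <- chol_psd(p$G)
  hz <- config$hazard
  ids <- sprintf("w%05d", seq_len(config$n_women))
  screens <- vector("list", config$n_women)
  truth_s <- vector("list", config$n_women)
  outcomes <- vector("list", config$n_women)
  women <- vector("list", config$n_women)
  for (i in seq_len(config$n_women)) {
    age0 <- stats::runif(1, config$age0_range[1], config$age0_range[2])
    b <- as.numeric(Lg %*% stats::rnorm(2))
    # potential follow-up: right-skewed staggered-entry censoring, capped
    # by the age-75 crossing
    fu_admin <- config$admin_end *
      stats::rbeta(1, 1, config$followup_shape)
    fu_age <- config$age_censor - age0
    fu <- max(min(fu_admin, fu_age), 0.05)
    censor_reason <- if (fu_age <= fu_admin) "age75" else "admin_end"
    # screen times
    t <- 0
    times <- 0
    while (length(times) < config$max_screens) {
      if (stats::runif(1) < config$screen_stop_prob) break
      gap <- max(stats::rnorm(1, config$interscreen_mean,
                              config$interscreen_sd), 0.3)
      t <- t + gap
      if (t >= fu || age0 + t >= config$age_censor) break
      times <- c(times, t)
    }
    k <- length(times)
    ages <- age0 + times
    # BMI random walk with drift
    bmi <- numeric(k)
    bmi[1] <- stats::rnorm(1, config$bmi0_intercept +
                             config$bmi0_slope * (age0 - 50),
                           config$bmi_sd)
    bmi[1] <- max(bmi[1], 14)
    if (k > 1)
      for (j in 2:k)
        bmi[j] <- max(bmi[j - 1] + config$bmi_drift * (times[j] -
                                                         times[j - 1]) +
                        stats::rnorm(1, 0, 0.5), 14)
    d <- build_design(ages, winsorize_bmi(bmi), p$centering)
    latent <- as.numeric(d$x %*% p$beta + d$z %*% b)
    reading <- if (config$discretize)
      discretize_birads(latent, sqrt(p$sigma2))
    else latent + stats::rnorm(k, 0, sqrt(p$sigma2))
    # BMI missingness after the trajectory is used for the truth
    bmi_obs <- bmi
    if (stats::runif(1) < config$bmi_missing_baseline) bmi_obs[1] <- NA
    if (k > 1) {
      mfu <- stats::runif(k - 1) < config$bmi_missing_followup
      bmi_obs[which(mfu) + 1] <- NA
    }
    # piecewise-exponential event time on segments between screens
    lp <- hz$log_hr_density * (latent - hz$density_ref) +
      hz$log_hr_density2 * (latent^2 - hz$density_ref^2) +
      hz$log_hr_age0 * (age0 - hz$age_ref) +
      hz$log_hr_bmi * (winsorize_bmi(bmi) - hz$bmi_ref)
    rates <- hz$baseline_rate * exp(lp)
    bounds <- c(times, fu)
    ev_time <- Inf
    if (hz$baseline_rate > 0) {
      u <- stats::rexp(1)           # total hazard to accumulate
      acc <- 0
      for (j in seq_len(k)) {
        seg <- bounds[j + 1] - bounds[j]
        h <- rates[j] * seg
        if (acc + h >= u) {
          ev_time <- bounds[j] + (u - acc) / rates[j]
          break
        }
        acc <- acc + h
      }
    }
    event <- as.integer(ev_time < fu)
    exit <- if (event == 1) ev_time else fu
    # keep only screens strictly before exit
    keep <- times < exit
    if (!any(keep)) { keep[1] <- TRUE; exit <- max(exit, times[1] + 0.02) }
    screens[[i]] <- data.frame(woman_id = ids[i], exam_time = times[keep],
                               age = ages[keep], bmi = bmi_obs[keep],
                               birads = reading[keep])
    truth_s[[i]] <- data.frame(woman_id = ids[i], exam_time = times[keep],
                               latent = latent[keep])
    outcomes[[i]] <- data.frame(
      woman_id = ids[i], exit_time = exit, event = event,
      censor_reason = if (event == 1) "none" else censor_reason)
    women[[i]] <- data.frame(woman_id = ids[i], age0 = age0, b0 = b[1],
                             b1 = b[2], potential_followup = fu)
  }
  cohort <- cohort_table(do.call(rbind, screens), do.call(rbind, outcomes))
  list(cohort = cohort,
       truth = list(women = do.call(rbind, women),
                    screens = do.call(rbind, truth_s)))
}
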