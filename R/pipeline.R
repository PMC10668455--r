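#' Pipeline configuration
#'
#' Loads a YAML run configuration (or accepts a list) and merges it over
#' defaults. Sections: `paths` (working directory and file names),
#' `preprocess` (eligibility window, winsor bounds, BMI bin width, entry
#' lag), `model` (centering, ties, start screen, update mode), `predict`
#' (cut-point source), `evaluate` (bootstrap size, seed, window) and
#' `simulate` (any [sim_config()] argument except `true_lmm`).
#'
#' @param config path to a YAML file, or a list with the same structure
#' @return a merged configuration list of class `"run_config"`
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    paths = list(dir = ".", screens = "screens.csv",
                 outcomes = "outcomes.csv", truth = "truth.csv",
                 params = "lmm_params.json", fit_report = "lmm_fit.json",
                 estimates = "estimates.csv", cutpoints = "cutpoints.json",
                 intervals = "risk_intervals.csv",
                 models = "model_reports.json",
                 concordance = "concordance.csv",
                 stability = "stability.csv", summary = "summary.json"),
    preprocess = list(min_age = 40, max_age = 73, min_followup = 0.5,
                      winsor_lo = 15, winsor_hi = 35, bin_width = 5,
                      entry_lag = 0.5),
    model = list(centering = 10, ties = "efron", start_at_screen = 1,
                 mode = "time_varying"),
    predict = list(cuts = "derived"),
    evaluate = list(n_boot = 1000, seed = 1, window = 1.0),
    simulate = list(n_women = 2000, seed = 1))
  for (sec in names(defaults)) {
    user <- config[[sec]]
    for (k in names(user)) defaults[[sec]][[k]] <- user[[k]]
  }
  extra <- setdiff(names(config), names(defaults))
  if (length(extra)) stop("unknown config section: ", extra[1])
  structure(defaults, class = "run_config")
}

cfg_path <- function(config, key) {
  file.path(config$paths$dir, config$paths[[key]])
}

#' Apply the standard preprocessing chain
#'
#' Eligibility filtering (drop screens without a reading, restrict baseline
#' age, require minimum follow-up), BMI imputation (age-bin means at
#' baseline, LOCF at follow-up) and winsorization.
#'
#' @param cohort a `"cohort"` object
#' @param config a [run_config()] (its `preprocess` section is used)
#' @return preprocessed `"cohort"` with no missing bmi or birads
#' @export
preprocess_cohort <- function(cohort, config = run_config()) {
  pp <- config$preprocess
  out <- apply_eligibility(cohort, pp$min_age, pp$max_age, pp$min_followup)
  out <- impute_bmi(out, pp$bin_width, pp$min_age)
  out$screens$bmi <- winsorize_bmi(out$screens$bmi, pp$winsor_lo,
                                   pp$winsor_hi)
  out
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Wraps [simulate_cohort()]; writes `screens.csv`, `outcomes.csv` and
#' `truth.csv` into the configured directory and logs the seed and row
#' counts.
#'
#' @param config a [run_config()] or path/list accepted by it
#' @return the simulation result, invisibly
#' @export
cmd_simulate <- function(config = list()) {
  config <- run_config(config)
  dir.create(config$paths$dir, showWarnings = FALSE, recursive = TRUE)
  sc <- do.call(sim_config, config$simulate)
  sim <- simulate_cohort(sc)
  write_cohort(sim$cohort, cfg_path(config, "screens"),
               cfg_path(config, "outcomes"))
  truth <- merge(sim$truth$screens, sim$truth$women, by = "woman_id")
  utils::write.csv(truth, cfg_path(config, "truth"), row.names = FALSE,
                   quote = FALSE)
  message(sprintf("simulate: seed %d, %d women, %d screens, %d events",
                  sc$seed, n_women(sim$cohort), nrow(sim$cohort$screens),
                  sum(sim$cohort$outcomes$event)))
  invisible(sim)
}

#' Pipeline stage: fit the density mixed model
#'
#' Reads the cohort, preprocesses it, fits the linear mixed model by
#' maximum likelihood and writes the parameter exchange file plus a fit
#' report with robust (cluster sandwich) standard errors for the fixed
#' effects.
#'
#' @param config a [run_config()] or path/list accepted by it
#' @return the `"lmm_fit"`, invisibly
#' @export
cmd_fit <- function(config = list()) {
  config <- run_config(config)
  cohort <- read_cohort(cfg_path(config, "screens"),
                        cfg_path(config, "outcomes"))
  cohort <- preprocess_cohort(cohort, config)
  fit <- fit_lmm_ml(cohort, centering = config$model$centering)
  if (!fit$converged) stop("mixed-model fit did not converge")
  rob <- robust_sandwich_cov(fit, cohort)
  write_lmm_params(fit$params, cfg_path(config, "params"))
  jsonlite::write_json(
    list(loglik = fit$loglik, n_women = fit$n_women, n_obs = fit$n_obs,
         beta = fit$params$beta, robust_se_beta = sqrt(diag(rob)),
         G = fit$params$G, sigma2 = fit$params$sigma2,
         centering = fit$params$centering),
    cfg_path(config, "fit_report"), digits = NA)
  message(sprintf("fit: %d women, %d screens, loglik %.2f",
                  fit$n_women, fit$n_obs, fit$loglik))
  invisible(fit)
}

#' Pipeline stage: sequential density estimates and cut points
#'
#' Reads the parameter file and cohort, computes the per-screen sequential
#' estimates, derives cut points from the baseline distribution (or uses
#' the published defaults when `predict$cuts` is `"paper_default"`), and
#' writes `estimates.csv` and `cutpoints.json`.
#'
#' @param config a [run_config()] or path/list accepted by it
#' @return the estimates data.frame, invisibly
#' @export
cmd_predict <- function(config = list()) {
  config <- run_config(config)
  params <- read_lmm_params(cfg_path(config, "params"))
  cohort <- read_cohort(cfg_path(config, "screens"),
                        cfg_path(config, "outcomes"))
  cohort <- preprocess_cohort(cohort, config)
  est <- sequential_estimates(cohort, params)
  if (identical(config$predict$cuts, "paper_default")) {
    cuts <- default_cutpoints()
    prov <- "paper_default"
  } else {
    base <- est[est$n_obs_used == 1, ]
    base_birads <- cohort$screens$birads[!duplicated(cohort$screens$woman_id)]
    cuts <- derive_cutpoints(base$value, base_birads)
    prov <- "derived"
  }
  cat8 <- categorize(est$value, cuts)
  est$category8 <- cat8
  est$category4 <- ceiling(cat8 / 2)
  write_estimates(est, cfg_path(config, "estimates"))
  write_cutpoints(cuts, cfg_path(config, "cutpoints"), provenance = prov)
  message(sprintf("predict: %d estimates for %d women (%s cut points)",
                  nrow(est), length(unique(est$woman_id)), prov))
  invisible(est)
}

#' Pipeline stage: fit and compare the density risk models
#'
#' Reads the cohort and estimates, fits the three density Cox models and
#' the age+BMI reference model, computes likelihood-ratio gains, the yearly
#' concordance curves (BI-RADS vs continuous longitudinal density) with a
#' cluster-bootstrap comparison, and the second-to-third-mammogram
#' stability analysis for both measures. Writes one JSON report per model,
#' `concordance.csv`, `stability.csv` and `summary.json`.
#'
#' @param config a [run_config()] or path/list accepted by it
#' @return list with the model fits, concordance results and stability
#'   results, invisibly
#' @export
cmd_evaluate <- function(config = list()) {
  config <- run_config(config)
  cohort <- read_cohort(cfg_path(config, "screens"),
                        cfg_path(config, "outcomes"))
  cohort <- preprocess_cohort(cohort, config)
  est <- utils::read.csv(cfg_path(config, "estimates"),
                         stringsAsFactors = FALSE)
  est$woman_id <- as.character(est$woman_id)
  dm <- density_models(cohort, est, mode = config$model$mode,
                       start_at_screen = config$model$start_at_screen,
                       entry_lag = config$preprocess$entry_lag,
                       ties = config$model$ties)
  n_short <- n_women(cohort) - length(unique(dm$intervals$woman_id))
  if (config$model$start_at_screen > 1)
    message(sprintf("evaluate: %d women excluded with < %d screens",
                    n_short, config$model$start_at_screen))
  lp_b <- cox_linear_predictor(dm$birads, dm$intervals)
  lp_c <- cox_linear_predictor(dm$continuous, dm$intervals)
  yc_b <- yearly_concordance(dm$intervals, lp_b,
                             window = config$evaluate$window)
  yc_c <- yearly_concordance(dm$intervals, lp_c,
                             window = config$evaluate$window)
  cmp <- compare_models_concordance(dm$intervals, lp_c, lp_b,
                                    n_boot = config$evaluate$n_boot,
                                    seed = config$evaluate$seed,
                                    window = config$evaluate$window)
  stab <- evaluate_stability(cohort, est, dm)
  # reports
  reports <- lapply(c("reduced", "birads", "continuous", "category8"),
                    function(nm) {
    f <- dm[[nm]]
    r <- list(model = nm, coef = as.list(f$coef),
              hr_table = hazard_ratio_table(f),
              loglik = f$loglik, loglik_null = f$loglik_null,
              n_events = f$n_events, n_intervals = f$n_intervals)
    if (nm != "reduced") {
      lr <- lr_statistic(f, dm$reduced)
      r$delta_lr <- lr$delta_lr
      r$df <- lr$df
    }
    r
  })
  jsonlite::write_json(reports, cfg_path(config, "models"), digits = NA,
                       auto_unbox = TRUE)
  curve <- rbind(cbind(model = "birads", yc_b$curve),
                 cbind(model = "continuous", yc_c$curve))
  utils::write.csv(curve, cfg_path(config, "concordance"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(stab)) {
    st <- cbind(measure = rep(c("birads", "longitudinal"),
                              each = nrow(stab$birads$table)),
                rbind(stab$birads$table, stab$longitudinal$table))
    utils::write.csv(st, cfg_path(config, "stability"),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(delta = dm$delta, mean_yC_birads = yc_b$mean_yC,
         mean_yC_continuous = yc_c$mean_yC,
         diff_yC = cmp$diff, diff_yC_ci = cmp$ci,
         frac_outside_birads =
           if (is.null(stab)) NA else stab$birads$frac_outside,
         frac_outside_longitudinal =
           if (is.null(stab)) NA else stab$longitudinal$frac_outside),
    cfg_path(config, "summary"), digits = NA, auto_unbox = TRUE)
  write_risk_intervals(dm$intervals, cfg_path(config, "intervals"))
  message(sprintf(
    "evaluate: delta_lr birads %.1f (df %d), continuous %.1f (df %d), cat8 %.1f (df %d)",
    dm$delta$delta_lr[1], dm$delta$df[1], dm$delta$delta_lr[2],
    dm$delta$df[2], dm$delta$delta_lr[3], dm$delta$df[3]))
  invisible(list(models = dm, concordance = list(birads = yc_b,
                                                 continuous = yc_c),
                 comparison = cmp, stability = stab))
}

# second/third-screen stability for both measures, using the full-cohort
# model fits; NULL when no woman has three screens
evaluate_stability <- function(cohort, estimates, dm) {
  s <- cohort$screens
  cnt <- table(s$woman_id)
  ids <- names(cnt)[cnt >= 3]
  if (!length(ids)) return(NULL)
  nth <- function(v, k) v[k]
  s3 <- s[s$woman_id %in% ids, ]
  birads2 <- as.numeric(tapply(s3$birads, s3$woman_id, nth, 2)[ids])
  birads3 <- as.numeric(tapply(s3$birads, s3$woman_id, nth, 3)[ids])
  e3 <- estimates[estimates$woman_id %in% ids, ]
  ld2 <- as.numeric(tapply(e3$value, e3$woman_id, nth, 2)[ids])
  ld3 <- as.numeric(tapply(e3$value, e3$woman_id, nth, 3)[ids])
  list(birads = stability_analysis(birads2, birads3, dm$birads, "birads"),
       longitudinal = stability_analysis(ld2, ld3, dm$continuous,
                                         "longitudinal"))
}
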