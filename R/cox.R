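#' Specification of a time-varying-covariate Cox model
#'
#' @param covariates list of terms, each a list with `name` (a column of the
#'   risk-interval table) and `coding`: `"continuous"`, `"factor"` (with a
#'   `ref` reference level), or `"quadratic"` (continuous linear + squared
#'   term).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`
#' @return object of class `"cox_spec"`
#' @export
cox_spec <- function(covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  for (cv in covariates) {
    stopifnot(is.list(cv), !is.null(cv$name))
    if (!cv$coding %in% c("continuous", "factor", "quadratic"))
      stop("unknown coding: ", cv$coding)
  }
  structure(list(covariates = covariates, ties = ties), class = "cox_spec")
}

# expand a risk-interval table into the model matrix the spec implies
cox_model_matrix <- function(intervals, spec) {
  cols <- list(); info <- list()
  for (cv in spec$covariates) {
    v <- intervals[[cv$name]]
    if (is.null(v)) stop("covariate ", cv$name, " not found in intervals")
    if (cv$coding == "continuous") {
      cols[[cv$name]] <- v
      info[[length(info) + 1L]] <- list(term = cv$name, covariate = cv$name,
                                        level = NA)
    } else if (cv$coding == "quadratic") {
      cols[[cv$name]] <- v
      cols[[paste0(cv$name, "_sq")]] <- v^2
      info[[length(info) + 1L]] <- list(term = cv$name, covariate = cv$name,
                                        level = NA)
      info[[length(info) + 1L]] <- list(term = paste0(cv$name, "_sq"),
                                        covariate = cv$name, level = NA)
    } else {
      lev <- sort(unique(v))
      if (!cv$ref %in% lev)
        stop("reference level ", cv$ref, " of ", cv$name, " not observed")
      for (l in lev[lev != cv$ref]) {
        nm <- paste0(cv$name, l)
        cols[[nm]] <- as.numeric(v == l)
        info[[length(info) + 1L]] <- list(term = nm, covariate = cv$name,
                                          level = l)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, info = info)
}

# partial log-likelihood, score and information at beta for counting-process
# data; risk set at event time t is {rows: start < t <= stop}
cox_pll <- function(X, start, stop, event, beta, ties) {
  eta <- as.numeric(X %*% beta)
  w <- exp(eta)
  etimes <- sort(unique(stop[event == 1]))
  p <- ncol(X)
  ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
  for (t in etimes) {
    risk <- which(start < t & t <= stop)
    dset <- risk[event[risk] == 1 & stop[risk] == t]
    d <- length(dset)
    Xr <- X[risk, , drop = FALSE]; wr <- w[risk]
    S0 <- sum(wr)
    S1 <- colSums(wr * Xr)
    S2 <- crossprod(Xr, wr * Xr)
    ll <- ll + sum(eta[dset])
    grad <- grad + colSums(X[dset, , drop = FALSE])
    if (ties == "breslow" || d == 1L) {
      ll <- ll - d * log(S0)
      grad <- grad - d * S1 / S0
      hess <- hess - d * (S2 / S0 - tcrossprod(S1 / S0))
    } else {
      Xd <- X[dset, , drop = FALSE]; wd <- w[dset]
      S0d <- sum(wd); S1d <- colSums(wd * Xd)
      S2d <- crossprod(Xd, wd * Xd)
      for (j in seq_len(d) - 1L) {
        f <- j / d
        D0 <- S0 - f * S0d
        D1 <- S1 - f * S1d
        D2 <- S2 - f * S2d
        ll <- ll - log(D0)
        grad <- grad - D1 / D0
        hess <- hess - (D2 / D0 - tcrossprod(D1 / D0))
      }
    }
  }
  list(loglik = ll, grad = grad, hess = hess)
}

#' Fit a time-varying-covariate Cox model
#'
#' Maximises the counting-process partial likelihood (risk set at event
#' time t: rows with start < t <= stop) by Newton-Raphson with step
#' halving; ties handled by the Efron (default) or Breslow approximation.
#'
#' @param intervals a `"risk_intervals"` data.frame
#'   (see [build_risk_intervals()])
#' @param spec a [cox_spec()]
#' @param tol convergence tolerance on the maximum absolute score component
#' @param maxit Newton iteration cap
#' @return object of class `"cox_fit"`: `coef` (named, log-HR scale), `cov`
#'   (inverse information), `loglik`, `loglik_null`, `n_events`,
#'   `n_intervals`, `spec`, `term_info`
#' @export
fit_cox <- function(intervals, spec, tol = 1e-9, maxit = 50) {
  if (sum(intervals$event) < 1) stop("need at least one event")
  mm <- cox_model_matrix(intervals, spec)
  X <- mm$X
  start <- intervals$start; stop_ <- intervals$stop
  event <- intervals$event
  p <- ncol(X)
  beta <- numeric(p)
  pl0 <- cox_pll(X, start, stop_, event, beta, spec$ties)
  ll_null <- pl0$loglik
  pl <- pl0
  trace <- numeric(0)
  at_boundary <- function(b, g) {
    # a factor level with no events drifts to -Inf along a flat likelihood;
    # accept the boundary once its score is negligible (coxph behaviour)
    bnd <- abs(b) > 15
    any(bnd) && all(abs(g[bnd]) < 1e-3) &&
      (all(bnd) || max(abs(g[!bnd])) < tol)
  }
  for (it in seq_len(maxit)) {
    if (max(abs(pl$grad)) < tol || at_boundary(beta, pl$grad)) break
    step <- tryCatch(solve(-pl$hess, pl$grad), error = function(e) {
      # degenerate directions contribute no information; step in the
      # informative subspace only
      sv <- svd(-(pl$hess + t(pl$hess)) / 2)
      pos <- sv$d > max(sv$d, 1e-300) * 1e-12
      if (!any(pos)) return(numeric(p))
      as.numeric(sv$v[, pos, drop = FALSE] %*%
                   ((t(sv$u[, pos, drop = FALSE]) %*% pl$grad) / sv$d[pos]))
    })
    lam <- 1
    repeat {
      cand <- beta + lam * step
      plc <- cox_pll(X, start, stop_, event, cand, spec$ties)
      if (is.finite(plc$loglik) && plc$loglik >= pl$loglik - 1e-12) break
      lam <- lam / 2
      if (lam < 1e-8)
        stop("non-convergence: step-halving failed; trace: ",
             paste(sprintf("%.4f", trace), collapse = " "))
    }
    beta <- cand; pl <- plc
    trace <- c(trace, pl$loglik)
    if (any(abs(beta) > 30 & abs(pl$grad) > 1e-3))
      stop("complete separation suspected for covariate ",
           colnames(X)[which.max(abs(beta))])
  }
  if (max(abs(pl$grad)) >= tol && !at_boundary(beta, pl$grad))
    stop("non-convergence after ", maxit, " iterations; loglik trace: ",
         paste(sprintf("%.4f", trace), collapse = " "))
  cov <- tryCatch(solve(-pl$hess), error = function(e) {
    # degenerate directions (e.g. a constant covariate) carry no
    # information; report a pseudo-inverse with Inf variance there
    sv <- svd((-pl$hess - t(pl$hess)) / -2)
    pos <- sv$d > max(sv$d) * 1e-12
    v <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) /
                                          sv$d[pos])
    diag(v)[diag(-pl$hess) < 1e-12] <- Inf
    v
  })
  cov <- (cov + t(cov)) / 2
  names(beta) <- colnames(X)
  dimnames(cov) <- list(colnames(X), colnames(X))
  structure(list(coef = beta, cov = cov, loglik = pl$loglik,
                 loglik_null = ll_null, n_events = sum(event),
                 n_intervals = nrow(intervals), spec = spec,
                 term_info = mm$info),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox model (%s ties): %d intervals, %d events, loglik %.3f\n",
              x$spec$ties, x$n_intervals, x$n_events, x$loglik))
  se <- sqrt(diag(x$cov))
  tab <- data.frame(coef = x$coef, HR = exp(x$coef), se = se)
  print(round(tab, 4))
  invisible(x)
}

#' Linear predictor of a fitted Cox model on interval rows
#'
#' @param fit a `"cox_fit"`
#' @param intervals a `"risk_intervals"` data.frame carrying the covariate
#'   columns the fit's spec names
#' @return numeric vector, one value per row
#' @export
cox_linear_predictor <- function(fit, intervals) {
  X <- cox_model_matrix(intervals, fit$spec)$X
  as.numeric(X[, names(fit$coef), drop = FALSE] %*% fit$coef)
}

#' Likelihood-ratio statistic between nested Cox fits
#'
#' @param full,reduced `"cox_fit"` objects on identical intervals, with the
#'   reduced model's terms a subset of the full model's
#' @return list with `delta_lr` = 2 (loglik_full - loglik_reduced) and `df`
#' @export
lr_statistic <- function(full, reduced) {
  if (!all(names(reduced$coef) %in% names(full$coef)))
    stop("contract error: models are not nested")
  if (full$n_intervals != reduced$n_intervals ||
      full$n_events != reduced$n_events)
    stop("contract error: fits are not on identical intervals")
  list(delta_lr = 2 * (full$loglik - reduced$loglik),
       df = length(full$coef) - length(reduced$coef))
}

#' Hazard-ratio table with Wald confidence intervals
#'
#' One row per coefficient, `HR = exp(coef)` with
#' `exp(coef -/+ z se)` bounds; factor reference levels appear as rows with
#' HR = 1 and no interval.
#'
#' @param fit a `"cox_fit"`
#' @param level coverage of the Wald interval (default 0.95)
#' @return data.frame with columns `name`, `HR`, `lo`, `hi`
#' @export
hazard_ratio_table <- function(fit, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(diag(fit$cov))
  rows <- data.frame(name = names(fit$coef), HR = exp(fit$coef),
                     lo = exp(fit$coef - z * se),
                     hi = exp(fit$coef + z * se), row.names = NULL)
  # insert reference rows for factor covariates
  for (cv in fit$spec$covariates) {
    if (cv$coding == "factor") {
      rows <- rbind(rows, data.frame(
        name = paste0(cv$name, cv$ref, " [Reference]"),
        HR = 1, lo = NA_real_, hi = NA_real_))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Fit the three density models and the age+BMI reference model
#'
#' Builds counting-process risk intervals from the cohort and the
#' per-screen density estimates, then fits: (1) BI-RADS density as a
#' 4-level factor (reference: Scattered = 2); (2) continuous longitudinal
#' density with linear and quadratic terms; (3) the eight-category measure
#' as a factor (reference: category 3); plus the reduced model with age at
#' entry and time-varying BMI only. All models adjust for age at the entry
#' screen (per year, continuous) and time-varying BMI (per kg/m², continuous).
#'
#' @param cohort preprocessed `"cohort"`
#' @param estimates data.frame from [sequential_estimates()] covering every
#'   (woman, screen)
#' @param mode `"time_varying"` (covariates update at each screen) or
#'   `"frozen_at_entry"` (covariates held at their entry-screen values)
#' @param start_at_screen follow-up starts at this screen (1 = baseline;
#'   3 reproduces the at-least-three-mammograms secondary analysis, where
#'   women with fewer screens are excluded and age at the third mammogram
#'   is the age adjustment)
#' @param entry_lag years between the entry screen and the start of
#'   follow-up (default 0.5)
#' @param ties tie-handling method passed to [cox_spec()]
#' @param which subset of the three density models to fit (all by default)
#' @return list with elements `reduced`, `birads`, `continuous`,
#'   `category8` (each a `"cox_fit"`), `intervals`, and `delta` — a
#'   data.frame of likelihood-ratio gains (`model`, `delta_lr`, `df`)
#'   relative to the reduced model
#' @export
density_models <- function(cohort, estimates,
                           mode = c("time_varying", "frozen_at_entry"),
                           start_at_screen = 1L, entry_lag = 0.5,
                           ties = "efron",
                           which = c("birads", "continuous", "category8")) {
  mode <- match.arg(mode)
  which <- match.arg(which, several.ok = TRUE)
  s <- cohort$screens
  key_s <- paste(s$woman_id, format(s$exam_time, digits = 15))
  key_e <- paste(estimates$woman_id, format(estimates$exam_time, digits = 15))
  pos <- match(key_s, key_e)
  if (anyNA(pos))
    stop("estimates do not cover every (woman, screen) pair")
  # age at entry screen, constant within woman
  nth_age <- function(v) if (length(v) >= start_at_screen)
    rep(v[start_at_screen], length(v)) else rep(NA_real_, length(v))
  age0 <- stats::ave(s$age, s$woman_id, FUN = nth_age)
  covsrc <- data.frame(woman_id = s$woman_id, exam_time = s$exam_time,
                       age0 = age0, bmi = s$bmi, birads = s$birads,
                       ldens = estimates$value[pos],
                       cat8 = estimates$category8[pos])
  covsrc <- covsrc[!is.na(covsrc$age0), , drop = FALSE]
  keep_cohort <- structure(list(
    screens = s[s$woman_id %in% covsrc$woman_id, , drop = FALSE],
    outcomes = cohort$outcomes[cohort$outcomes$woman_id %in% covsrc$woman_id,
                               , drop = FALSE]), class = "cohort")
  intervals <- build_risk_intervals(
    keep_cohort, covsrc, entry_lag = entry_lag,
    entry_screen = start_at_screen,
    freeze_at_entry = (mode == "frozen_at_entry"))
  adj <- list(list(name = "age0", coding = "continuous"),
              list(name = "bmi", coding = "continuous"))
  spec_red <- cox_spec(adj, ties = ties)
  spec_b <- cox_spec(c(adj, list(list(name = "birads", coding = "factor",
                                      ref = 2))), ties = ties)
  spec_c <- cox_spec(c(adj, list(list(name = "ldens", coding = "quadratic"))),
                     ties = ties)
  spec_8 <- cox_spec(c(adj, list(list(name = "cat8", coding = "factor",
                                      ref = 3))), ties = ties)
  reduced <- fit_cox(intervals, spec_red)
  specs <- list(birads = spec_b, continuous = spec_c, category8 = spec_8)
  fits <- lapply(specs[which], function(sp) fit_cox(intervals, sp))
  delta <- do.call(rbind, lapply(names(fits), function(nm) {
    lr <- lr_statistic(fits[[nm]], reduced)
    data.frame(model = nm, delta_lr = lr$delta_lr, df = lr$df)
  }))
  c(list(reduced = reduced), fits,
    list(intervals = intervals, delta = delta))
}
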