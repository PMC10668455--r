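#' Yearly at-risk concordance curve
#'
#' For each yearly window (starting at 0.5 years of follow-up), every event
#' in the window is compared with every subject at risk at the event time
#' who does not have an event then: the pair is concordant when the case's
#' current linear predictor exceeds the at-risk subject's (ties count one
#' half). Subjects are women; a woman is never compared with herself.
#' yC(t) is the concordant-pair fraction in the window, with a per-event
#' clustered (U-statistic) standard error, and `mean_yC` the pair-weighted
#' mean over windows (set `weight = "equal"` for an unweighted mean).
#'
#' @param intervals a `"risk_intervals"` data.frame
#' @param linear_predictor one value per interval row (any risk score; the
#'   curve depends on it only through ranks)
#' @param window window width in years (default 1)
#' @param weight `"pairs"` (pair-count weighting, default) or `"equal"`
#' @return object of class `"concordance_curve"`: data.frame `curve` with
#'   columns `time`, `yC`, `se`, `n_pairs`, plus `mean_yC`
#' @export
yearly_concordance <- function(intervals, linear_predictor, window = 1.0,
                               weight = c("pairs", "equal")) {
  weight <- match.arg(weight)
  stopifnot(length(linear_predictor) == nrow(intervals))
  res <- concordance_windows(intervals$start, intervals$stop,
                             intervals$event, intervals$woman_id,
                             linear_predictor, window)
  ok <- res$n_pairs > 0
  mean_yC <- if (!any(ok)) NA_real_
  else if (weight == "pairs")
    sum(res$yC[ok] * res$n_pairs[ok]) / sum(res$n_pairs[ok])
  else mean(res$yC[ok])
  structure(list(curve = res, mean_yC = mean_yC, weight = weight),
            class = "concordance_curve")
}

#' @export
print.concordance_curve <- function(x, ...) {
  cat(sprintf("Yearly at-risk concordance: mean yC = %.4f (%s-weighted)\n",
              x$mean_yC, x$weight))
  print(round(x$curve, 4))
  invisible(x)
}

# windowed concordance over counting-process rows; windows [t, t+window)
# with t = 0.5, 1.5, ...; returns one row per window that contains events
concordance_windows <- function(start, stop, event, woman, lp, window) {
  ev <- which(event == 1)
  if (!length(ev))
    return(data.frame(time = numeric(0), yC = numeric(0), se = numeric(0),
                      n_pairs = integer(0)))
  if (max(stop) < 0.5)
    return(data.frame(time = numeric(0), yC = numeric(0), se = numeric(0),
                      n_pairs = integer(0)))
  t0 <- seq(0.5, max(stop), by = window)
  out <- lapply(t0, function(tw) {
    ew <- ev[stop[ev] >= tw & stop[ev] < tw + window]
    if (!length(ew)) return(NULL)
    ph <- numeric(length(ew)); mh <- numeric(length(ew))
    for (k in seq_along(ew)) {
      e <- ew[k]; s <- stop[e]
      risk <- which(start < s & s <= stop & woman != woman[e] &
                      !(event == 1 & stop == s))
      m <- length(risk)
      if (m == 0) { ph[k] <- NA; mh[k] <- 0; next }
      conc <- sum(lp[e] > lp[risk]) + 0.5 * sum(lp[e] == lp[risk])
      ph[k] <- conc / m
      mh[k] <- m
    }
    use <- mh > 0
    if (!any(use)) return(NULL)
    ph <- ph[use]; mh <- mh[use]
    n_pairs <- sum(mh)
    yC <- sum(ph * mh) / n_pairs
    se <- sqrt(sum(mh^2 * (ph - yC)^2)) / n_pairs
    data.frame(time = tw, yC = yC, se = se, n_pairs = n_pairs)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(time = numeric(0), yC = numeric(0), se = numeric(0),
                      n_pairs = integer(0))
  rownames(out) <- NULL
  out
}

#' Bootstrap comparison of two risk scores by mean yearly concordance
#'
#' Resamples whole women (clusters) with replacement, recomputes the
#' difference in pair-weighted mean yC between predictors A and B on each
#' resample, and returns the observed difference with a percentile
#' confidence interval. Deterministic under a fixed seed.
#'
#' @param intervals a `"risk_intervals"` data.frame
#' @param lpA,lpB linear predictors on the same rows
#' @param n_boot bootstrap resamples (default 10000)
#' @param seed RNG seed
#' @param level CI coverage (default 0.95)
#' @param window passed to [yearly_concordance()]
#' @return list with `diff` (mean yC of A minus B), `ci` (length 2),
#'   `n_boot`, and `warning` (non-NULL when n_boot < 100)
#' @export
compare_models_concordance <- function(intervals, lpA, lpB, n_boot = 10000,
                                       seed = 1, level = 0.95, window = 1.0) {
  stopifnot(length(lpA) == nrow(intervals), length(lpB) == nrow(intervals))
  warn <- if (n_boot < 100) "n_boot < 100: interval is unreliable" else NULL
  myc <- function(idx, woman) {
    a <- concordance_windows(intervals$start[idx], intervals$stop[idx],
                             intervals$event[idx], woman, lpA[idx], window)
    b <- concordance_windows(intervals$start[idx], intervals$stop[idx],
                             intervals$event[idx], woman, lpB[idx], window)
    wa <- sum(a$yC * a$n_pairs) / sum(a$n_pairs)
    wb <- sum(b$yC * b$n_pairs) / sum(b$n_pairs)
    wa - wb
  }
  obs <- myc(seq_len(nrow(intervals)), intervals$woman_id)
  rows_by_woman <- split(seq_len(nrow(intervals)), intervals$woman_id)
  ids <- names(rows_by_woman)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  diffs <- vapply(seq_len(n_boot), function(b) {
    pick <- sample(length(ids), replace = TRUE)
    idx <- unlist(rows_by_woman[pick], use.names = FALSE)
    # copies of the same woman become distinct subjects in the resample
    wom <- rep(paste0(ids[pick], "#", seq_along(pick)),
               lengths(rows_by_woman[pick]))
    myc(idx, wom)
  }, numeric(1))
  alpha <- (1 - level) / 2
  ci <- as.numeric(stats::quantile(diffs, c(alpha, 1 - alpha), type = 1,
                                   na.rm = TRUE))
  list(diff = obs, ci = ci, n_boot = n_boot, warning = warn)
}

#' Second-to-third-mammogram risk stability
#'
#' For women with at least three screens, computes each woman's relative
#' risk at the second and third mammogram from the density contribution to
#' a fitted Cox model's linear predictor, normalises each screen's relative
#' risks to mean one across women, and reports the fraction of women whose
#' screen-3 to screen-2 ratio falls outside the stable range [4/5, 5/4].
#'
#' @param values2,values3 per-woman density values at the second and third
#'   screen: BI-RADS readings for `measure = "birads"`, continuous
#'   longitudinal density for `measure = "longitudinal"`
#' @param fit a `"cox_fit"` supplying the density coefficients (factor
#'   levels for BI-RADS; linear + quadratic terms for longitudinal)
#' @param measure `"birads"` or `"longitudinal"`
#' @param stable_range relative-risk ratio band regarded as stable
#' @return object of class `"stability_result"`: data.frame `table`
#'   (`rr2`, `rr3`, `ratio`), `frac_outside`, `cdf_points`
#' @export
stability_analysis <- function(values2, values3, fit,
                               measure = c("birads", "longitudinal"),
                               stable_range = c(4 / 5, 5 / 4)) {
  measure <- match.arg(measure)
  if (length(values2) != length(values3))
    stop("contract error: screen-2 and screen-3 values differ in length")
  if (anyNA(values2) || anyNA(values3))
    stop("contract error: missing density value at screen 2 or 3")
  contrib <- function(v) {
    if (measure == "birads") {
      cf <- fit$coef[paste0("birads", v)]
      cf[is.na(cf)] <- 0          # reference level
      as.numeric(cf)
    } else {
      as.numeric(fit$coef["ldens"] * v + fit$coef["ldens_sq"] * v^2)
    }
  }
  rr2 <- exp(contrib(values2)); rr2 <- rr2 / mean(rr2)
  rr3 <- exp(contrib(values3)); rr3 <- rr3 / mean(rr3)
  ratio <- rr3 / rr2
  frac <- mean(ratio < stable_range[1] | ratio > stable_range[2])
  srt <- sort(ratio)
  cdf <- data.frame(ratio = srt,
                    cumfrac = seq_along(srt) / length(srt))
  structure(list(table = data.frame(rr2 = rr2, rr3 = rr3, ratio = ratio),
                 frac_outside = frac, cdf_points = cdf,
                 stable_range = stable_range),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "Risk stability screen 2 -> 3: %.1f%% outside [%.2f, %.2f] (n = %d)\n",
    100 * x$frac_outside, x$stable_range[1], x$stable_range[2],
    nrow(x$table)))
  invisible(x)
}
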