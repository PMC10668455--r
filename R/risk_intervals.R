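#' Build counting-process risk intervals with time-varying covariates
#'
#' Converts a cohort plus per-screen covariate values into (start, stop]
#' rows on the follow-up time scale (years since each woman's baseline
#' exam). Each woman enters at `entry_lag` after baseline; covariates are
#' piecewise constant, taking at time t the values from her latest screen at
#' or before t; interval boundaries fall at each screen time and at exit.
#' The final interval carries the woman's event indicator. Women whose exit
#' is at or before `entry_lag` contribute no rows.
#'
#' @param cohort a `"cohort"` object
#' @param covariate_source data.frame keyed by `woman_id` and `exam_time`
#'   with one column per covariate; must cover every (woman, screen) pair.
#' @param entry_lag delayed entry after the baseline exam, years (default
#'   0.5, i.e. the six-month lag that guards against prevalent disease)
#' @param entry_screen screen number (1-based) at which follow-up starts;
#'   the default 1 starts at baseline. With `entry_screen = k`, women with
#'   fewer than k screens are excluded and entry is the k-th screen time
#'   plus `entry_lag`.
#' @param freeze_at_entry if TRUE, covariates are held fixed at their
#'   entry-screen values for the whole of follow-up (the non-updated
#'   variant); otherwise they update at every screen.
#' @return data.frame of class `"risk_intervals"` with columns `woman_id`,
#'   `start`, `stop`, `event` and the covariate columns.
#' @export
build_risk_intervals <- function(cohort, covariate_source, entry_lag = 0.5,
                                 entry_screen = 1L, freeze_at_entry = FALSE) {
  s <- cohort$screens
  o <- cohort$outcomes
  cov_cols <- setdiff(names(covariate_source), c("woman_id", "exam_time"))
  if (!length(cov_cols)) stop("covariate_source has no covariate columns")
  key_s <- paste(s$woman_id, format(s$exam_time, digits = 15))
  key_c <- paste(as.character(covariate_source$woman_id),
                 format(covariate_source$exam_time, digits = 15))
  pos <- match(key_s, key_c)
  if (anyNA(pos))
    stop("contract error: covariate vector missing for woman_id ",
         s$woman_id[which(is.na(pos))[1]], " at exam_time ",
         s$exam_time[which(is.na(pos))[1]])
  covs <- covariate_source[pos, cov_cols, drop = FALSE]
  if (anyNA(covs))
    stop("contract error: missing covariate value for woman_id ",
         s$woman_id[which(rowSums(is.na(covs)) > 0)[1]])

  out <- vector("list", nrow(o))
  split_idx <- split(seq_len(nrow(s)), s$woman_id)
  for (w in seq_len(nrow(o))) {
    id <- o$woman_id[w]
    idx <- split_idx[[id]]
    if (length(idx) < entry_screen) next
    t0 <- s$exam_time[idx[1]]                       # baseline exam
    screen_fu <- s$exam_time[idx] - t0              # follow-up screen times
    exit_fu <- o$exit_time[w] - t0
    entry <- screen_fu[entry_screen] + entry_lag
    if (exit_fu <= entry) next
    if (freeze_at_entry) {
      cuts <- entry
      cov_at <- idx[entry_screen]
    } else {
      cuts <- sort(unique(c(entry, screen_fu[screen_fu > entry])))
      # covariate row: latest screen at or before each interval start
      cov_at <- idx[findInterval(cuts, screen_fu)]
    }
    keep <- cuts < exit_fu
    cuts <- cuts[keep]; cov_at <- cov_at[keep]
    stops <- c(cuts[-1], exit_fu)
    ev <- c(rep(0L, length(cuts) - 1L), as.integer(o$event[w]))
    out[[w]] <- data.frame(woman_id = id, start = cuts, stop = stops,
                           event = ev, covs[cov_at, , drop = FALSE],
                           row.names = NULL, check.names = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- cbind(data.frame(woman_id = character(0), start = numeric(0),
                            stop = numeric(0), event = integer(0)),
                 covs[0, , drop = FALSE])
  rownames(res) <- NULL
  class(res) <- c("risk_intervals", "data.frame")
  res
}

#' Write a risk-interval table to CSV
#' @param intervals a `"risk_intervals"` data.frame
#' @param path output path
#' @export
write_risk_intervals <- function(intervals, path) {
  utils::write.csv(as.data.frame(intervals), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
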