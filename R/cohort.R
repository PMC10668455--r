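#' Construct and validate a screening cohort table
#'
#' A cohort couples long-format screening records (one row per mammogram:
#' woman id, exam time in years since study start, age, BMI, BI-RADS density
#' 1--4) with one outcome record per woman (exit time, invasive-cancer event
#' indicator, censoring reason). Exam times are real-valued years; a date
#' column is converted upstream at read time.
#'
#' @param screens data.frame with columns `woman_id`, `exam_time`, `age`,
#'   `bmi`, `birads`. `bmi` and `birads` may be `NA`.
#' @param outcomes data.frame with columns `woman_id`, `exit_time`, `event`,
#'   `censor_reason`.
#' @return An object of class `"cohort"`: a list with elements `screens` and
#'   `outcomes`, rows sorted by (woman_id, exam_time).
#' @export
cohort_table <- function(screens, outcomes) {
  screens <- as.data.frame(screens)
  outcomes <- as.data.frame(outcomes)
  need_s <- c("woman_id", "exam_time", "age", "bmi", "birads")
  need_o <- c("woman_id", "exit_time", "event", "censor_reason")
  miss <- setdiff(need_s, names(screens))
  if (length(miss))
    stop("screens is missing columns: ", paste(miss, collapse = ", "))
  miss <- setdiff(need_o, names(outcomes))
  if (length(miss))
    stop("outcomes is missing columns: ", paste(miss, collapse = ", "))
  screens$woman_id <- as.character(screens$woman_id)
  outcomes$woman_id <- as.character(outcomes$woman_id)
  screens <- screens[order(screens$woman_id, screens$exam_time),
                     need_s, drop = FALSE]
  outcomes <- outcomes[order(outcomes$woman_id), need_o, drop = FALSE]
  rownames(screens) <- rownames(outcomes) <- NULL
  obj <- structure(list(screens = screens, outcomes = outcomes),
                   class = "cohort")
  validate_cohort(obj)
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Screening cohort: %d women, %d screens, %d events\n",
              length(unique(x$screens$woman_id)), nrow(x$screens),
              sum(x$outcomes$event)))
  invisible(x)
}

#' Number of women in a cohort
#' @param cohort a `"cohort"` object
#' @return integer count
#' @export
n_women <- function(cohort) length(unique(cohort$screens$woman_id))

validate_cohort <- function(x) {
  s <- x$screens
  o <- x$outcomes
  # integer readings are BI-RADS and must lie in 1..4; non-integer values
  # are continuous density outcomes (simulation with discretization off)
  # and are range-unrestricted
  bad <- s$birads[!is.na(s$birads)]
  if (length(bad) && all(bad == floor(bad)) && any(bad < 1 | bad > 4))
    stop("validation error: birads outside {1,2,3,4} for woman_id ",
         s$woman_id[match(TRUE, !is.na(s$birads) &
                            (s$birads < 1 | s$birads > 4))])
  if (anyDuplicated(s[, c("woman_id", "exam_time")]))
    stop("validation error: duplicate (woman_id, exam_time) for woman_id ",
         s$woman_id[which(duplicated(s[, c("woman_id", "exam_time")]))[1]])
  if (any(s$exam_time < 0))
    stop("validation error: negative exam_time for woman_id ",
         s$woman_id[which(s$exam_time < 0)[1]])
  # within-woman monotonicity of exam_time and age (rows already sorted)
  same <- s$woman_id[-1] == s$woman_id[-nrow(s)]
  if (nrow(s) > 1) {
    dt <- diff(s$exam_time)[same]
    da <- diff(s$age)[same]
    ids <- s$woman_id[-1][same]
    if (any(dt <= 0))
      stop("validation error: exam_time not strictly increasing for woman_id ",
           ids[which(dt <= 0)[1]])
    if (any(da <= 0))
      stop("validation error: age not strictly increasing for woman_id ",
           ids[which(da <= 0)[1]])
    if (any(abs(da - dt) > 0.1))
      stop("validation error: age increments inconsistent with exam_time ",
           "gaps (>0.1 yr) for woman_id ", ids[which(abs(da - dt) > 0.1)[1]])
  }
  sw <- unique(s$woman_id)
  if (anyDuplicated(o$woman_id))
    stop("validation error: multiple outcome rows for woman_id ",
         o$woman_id[which(duplicated(o$woman_id))[1]])
  if (!setequal(sw, o$woman_id))
    stop("validation error: outcomes do not match screened women (",
         paste(utils::head(c(setdiff(sw, o$woman_id),
                             setdiff(o$woman_id, sw)), 3), collapse = ", "),
         ")")
  if (!all(o$event %in% c(0, 1)))
    stop("validation error: event must be 0/1 for woman_id ",
         o$woman_id[which(!o$event %in% c(0, 1))[1]])
  first_exam <- tapply(s$exam_time, s$woman_id, min)[o$woman_id]
  if (any(o$exit_time <= first_exam))
    stop("validation error: exit_time not after first exam for woman_id ",
         o$woman_id[which(o$exit_time <= first_exam)[1]])
  if (any(o$event == 1 & o$censor_reason != "none"))
    stop("validation error: event=1 requires censor_reason 'none' ",
         "for woman_id ", o$woman_id[which(o$event == 1 &
                                             o$censor_reason != "none")[1]])
  invisible(x)
}

#' Read a screening cohort from CSV files
#'
#' Expects `screens.csv` with header `woman_id,exam_time,age,bmi,birads` and
#' `outcomes.csv` with header `woman_id,exit_time,event,censor_reason`.
#' Empty fields encode missing values. If the screens file carries an
#' `exam_date` column instead of `exam_time`, dates are converted to years
#' since the earliest date in the file (days / 365.25).
#'
#' @param screens_path,outcomes_path paths to the two CSV files
#' @return a validated [cohort_table()]
#' @export
read_cohort <- function(screens_path, outcomes_path) {
  s <- utils::read.csv(screens_path, stringsAsFactors = FALSE,
                       na.strings = "")
  o <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE,
                       na.strings = "")
  if (!"exam_time" %in% names(s) && "exam_date" %in% names(s)) {
    d <- as.Date(s$exam_date)
    s$exam_time <- as.numeric(d - min(d, na.rm = TRUE)) / 365.25
    s$exam_date <- NULL
  }
  for (col in c("exam_time", "age", "bmi", "birads")) {
    if (!col %in% names(s)) stop("screens file missing column ", col)
    v <- suppressWarnings(as.numeric(s[[col]]))
    bad <- which(!is.na(s[[col]]) & is.na(v))
    if (length(bad))
      stop("parse error in ", screens_path, " line ", bad[1] + 1,
           ": non-numeric ", col)
    s[[col]] <- v
  }
  for (col in c("exit_time", "event")) {
    if (!col %in% names(o)) stop("outcomes file missing column ", col)
    v <- suppressWarnings(as.numeric(o[[col]]))
    bad <- which(!is.na(o[[col]]) & is.na(v))
    if (length(bad))
      stop("parse error in ", outcomes_path, " line ", bad[1] + 1,
           ": non-numeric ", col)
    o[[col]] <- v
  }
  if (is.null(o$censor_reason)) o$censor_reason <- "none"
  o$censor_reason[is.na(o$censor_reason)] <- "none"
  cohort_table(s, o)
}

#' Write a cohort to CSV files
#'
#' Inverse of [read_cohort()]: `read_cohort` on the written files
#' reproduces the cohort.
#'
#' @param cohort a `"cohort"` object
#' @param screens_path,outcomes_path output paths
#' @return invisibly, the two paths
#' @export
write_cohort <- function(cohort, screens_path, outcomes_path) {
  utils::write.csv(cohort$screens, screens_path, row.names = FALSE,
                   na = "", quote = FALSE)
  utils::write.csv(cohort$outcomes, outcomes_path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(c(screens_path, outcomes_path))
}

#' Apply study eligibility filters
#'
#' Screens missing a BI-RADS reading are dropped first; each woman's baseline
#' is then her earliest remaining screen. Women whose baseline age falls
#' outside `[min_age, max_age]`, or with less than `min_followup` years
#' between baseline and exit, are removed entirely. The filter is idempotent.
#'
#' @param cohort a `"cohort"` object
#' @param min_age,max_age baseline age window in years (default 40--73)
#' @param min_followup minimum follow-up after baseline in years (default 0.5)
#' @return the filtered `"cohort"` (possibly empty)
#' @export
apply_eligibility <- function(cohort, min_age = 40, max_age = 73,
                              min_followup = 0.5) {
  s <- cohort$screens[!is.na(cohort$screens$birads), , drop = FALSE]
  o <- cohort$outcomes
  if (nrow(s) == 0L)
    return(structure(list(screens = s, outcomes = o[0, , drop = FALSE]),
                     class = "cohort"))
  base_idx <- !duplicated(s$woman_id)        # rows sorted by (id, time)
  base_age <- s$age[base_idx]
  base_time <- s$exam_time[base_idx]
  ids <- s$woman_id[base_idx]
  exit <- o$exit_time[match(ids, o$woman_id)]
  keep <- ids[base_age >= min_age & base_age <= max_age &
                (exit - base_time) >= min_followup]
  s <- s[s$woman_id %in% keep, , drop = FALSE]
  o <- o[o$woman_id %in% keep, , drop = FALSE]
  rownames(s) <- rownames(o) <- NULL
  structure(list(screens = s, outcomes = o), class = "cohort")
}

#' Winsorize BMI at fixed bounds
#'
#' Caps BMI below at `lo` and above at `hi` (defaults 15 and 35 kg/m²),
#' so that morbid obesity contributes the same adiposity-related risk as
#' obesity rather than being extrapolated.
#'
#' @param bmi numeric vector of BMI values, kg/m²; `NA` passed through
#' @param lo,hi winsorization bounds, kg/m²
#' @return capped BMI vector
#' @export
winsorize_bmi <- function(bmi, lo = 15, hi = 35) {
  if (any(!is.na(bmi) & bmi <= 0))
    stop("validation error: non-positive BMI")
  pmin(pmax(bmi, lo), hi)
}

#' Impute missing BMI
#'
#' Missing baseline BMI is replaced by the mean observed baseline BMI among
#' women whose baseline age falls in the same fixed-width age bin (bins of
#' `age_bin_width` years anchored at `min_age`). Missing follow-up BMI is
#' carried forward from the woman's most recent non-missing BMI. Women with
#' no observed BMI at all use their baseline bin mean at every screen. The
#' result has no missing BMI.
#'
#' @param cohort a `"cohort"` object
#' @param age_bin_width width of the baseline-age bins in years (default 5)
#' @param min_age left edge of the first bin (default 40)
#' @return the cohort with `bmi` fully observed
#' @export
impute_bmi <- function(cohort, age_bin_width = 5, min_age = 40) {
  s <- cohort$screens
  if (!anyNA(s$bmi)) return(cohort)
  base_idx <- which(!duplicated(s$woman_id))
  bin <- floor((s$age[base_idx] - min_age) / age_bin_width)
  bin_mean <- tapply(s$bmi[base_idx], bin, mean, na.rm = TRUE)
  # baseline imputation from bin means
  b_missing <- base_idx[is.na(s$bmi[base_idx])]
  if (length(b_missing)) {
    b_bin <- as.character(floor((s$age[b_missing] - min_age) /
                                  age_bin_width))
    m <- bin_mean[b_bin]
    if (anyNA(m) || any(is.nan(m)))
      stop("imputation error: no observed baseline BMI in age bin ",
           b_bin[which(is.na(m) | is.nan(m))[1]])
    s$bmi[b_missing] <- m
  }
  # LOCF within woman for follow-up screens
  locf <- function(v) {
    ok <- !is.na(v)
    idx <- cumsum(ok)
    out <- v
    out[idx > 0] <- v[ok][idx[idx > 0]]
    out
  }
  s$bmi <- stats::ave(s$bmi, s$woman_id, FUN = locf)
  cohort$screens <- s
  cohort
}
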