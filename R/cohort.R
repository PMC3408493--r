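#' Column layout of a conception cohort table
#'
#' A cohort is a plain \code{data.frame} with one row per child. Required
#' columns: \code{child_id}, \code{conception_date} (Date; derivable from
#' \code{last_menses}), \code{is_case} (0/1, sole autism), \code{sex_male}
#' (0/1). Optional columns used by the covariate coding and robustness
#' stages: \code{family_id}, \code{last_menses}, \code{mother_age},
#' \code{father_age}, \code{mother_educ}, \code{father_educ} (years),
#' \code{race} (one of \code{non_hispanic_white}, \code{hispanic_white},
#' \code{black}, \code{asian}, \code{other}), \code{medi_cal} (0/1),
#' \code{gestational_age} (weeks), \code{birth_weight} (grams),
#' \code{stratum_metro} (\code{metro}/\code{adjacent}),
#' \code{stratum_region} (\code{north}/\code{south}).
#'
#' @name cohort-schema
#' @keywords internal
NULL

race_levels <- function() {
  c("non_hispanic_white", "hispanic_white", "black", "asian", "other")
}

educ_levels <- function() c("lt12", "12to16", "gt16")

#' Derive the approximate conception date from the last menses
#'
#' The birth record carries the date of the mother's last menses; the
#' approximate conception date is obtained by adding a fortnight.
#'
#' @param last_menses a \code{Date} vector (or anything \code{as.Date}
#'   accepts). \code{NA} propagates.
#' @return a \code{Date} vector, \code{last_menses + 14} days.
#' @examples
#' derive_conception_date(as.Date("1994-10-24"))  # 1994-11-07
#' @export
derive_conception_date <- function(last_menses) {
  d <- as.Date(last_menses)
  d + 14L
}

#' Code analysis covariates from raw birth-record fields
#'
#' Applies the covariate codings used throughout the analysis: preterm =
#' gestational age < 37 weeks; low birth weight = birth weight < 2500 g;
#' mean parental age (mean of both parents' ages, or the mother's alone
#' when the father's is missing) dichotomised at >= 35; mean parental
#' education (same rule) binned as < 12, 12-16 (inclusive) or > 16 years;
#' race with non-Hispanic white as reference.
#'
#' @param records cohort data.frame (see \link{cohort-schema}). Every row
#'   must have at least one parental age; drop offending rows first with
#'   \code{\link{filter_cohort}}.
#' @return data.frame with columns \code{preterm}, \code{low_birth_weight}
#'   (NA when the measurement is missing), \code{parental_age_35plus},
#'   \code{educ_category} (factor \code{lt12}/\code{12to16}/\code{gt16}),
#'   \code{race} (factor, reference \code{non_hispanic_white}),
#'   \code{medi_cal}, \code{sex_male}.
#' @export
code_covariates <- function(records) {
  ma <- records$mother_age
  fa <- records$father_age
  if (is.null(ma)) ma <- rep(NA_real_, nrow(records))
  if (is.null(fa)) fa <- rep(NA_real_, nrow(records))
  both_missing <- is.na(ma) & is.na(fa)
  if (any(both_missing)) {
    stop(sum(both_missing),
         " record(s) missing both parental ages; drop them first ",
         "(see filter_cohort)")
  }
  if (any(ma > 80, na.rm = TRUE) || any(fa > 80, na.rm = TRUE) ||
      any(ma < 0, na.rm = TRUE) || any(fa < 0, na.rm = TRUE)) {
    stop("parental age outside plausible range (0, 80]")
  }
  ga <- records$gestational_age
  if (is.null(ga)) ga <- rep(NA_real_, nrow(records))
  if (any(ga <= 0, na.rm = TRUE) || any(ga > 50, na.rm = TRUE)) {
    stop("gestational_age outside plausible range (0, 50] weeks")
  }
  bw <- records$birth_weight
  if (is.null(bw)) bw <- rep(NA_real_, nrow(records))
  if (any(bw <= 0, na.rm = TRUE)) stop("birth_weight must be positive")

  mean_age <- rowMeans(cbind(ma, fa), na.rm = TRUE)
  me <- records$mother_educ
  fe <- records$father_educ
  if (is.null(me)) me <- rep(NA_real_, nrow(records))
  if (is.null(fe)) fe <- rep(NA_real_, nrow(records))
  mean_educ <- rowMeans(cbind(me, fe), na.rm = TRUE)
  mean_educ[is.na(me) & is.na(fe)] <- NA_real_
  educ <- rep(NA_character_, nrow(records))
  educ[mean_educ < 12] <- "lt12"
  educ[mean_educ >= 12 & mean_educ <= 16] <- "12to16"
  educ[mean_educ > 16] <- "gt16"

  data.frame(
    preterm            = as.integer(ga < 37),
    low_birth_weight   = as.integer(bw < 2500),
    parental_age_35plus = as.integer(mean_age >= 35),
    educ_category      = factor(educ, levels = educ_levels()),
    race = factor(as.character(records$race), levels = race_levels()),
    medi_cal           = as.integer(records$medi_cal),
    sex_male           = as.integer(records$sex_male),
    stringsAsFactors = FALSE
  )
}

#' Restrict a cohort to a conception-date interval and valid records
#'
#' Keeps records whose conception date lies in the half-open interval
#' \code{[start, end)}. Conception dates are derived from
#' \code{last_menses} where absent. Records with no derivable conception
#' date or with both parental ages missing are dropped; per-reason drop
#' counts are reported via \code{message} and attached as the
#' \code{"drop_log"} attribute.
#'
#' @param records cohort data.frame.
#' @param start,end \code{Date}; \code{start < end}.
#' @param quiet suppress the drop-count messages.
#' @return the filtered data.frame, with attribute \code{drop_log}.
#' @export
filter_cohort <- function(records, start, end, quiet = FALSE) {
  start <- as.Date(start); end <- as.Date(end)
  stopifnot(start < end)
  cd <- records$conception_date
  if (is.null(cd)) cd <- rep(as.Date(NA), nrow(records))
  cd <- as.Date(cd)
  if (!is.null(records$last_menses)) {
    need <- is.na(cd) & !is.na(records$last_menses)
    cd[need] <- derive_conception_date(records$last_menses[need])
  }
  records$conception_date <- cd

  bad_date <- is.na(cd)
  ma <- if (is.null(records$mother_age)) rep(NA_real_, nrow(records)) else records$mother_age
  fa <- if (is.null(records$father_age)) rep(NA_real_, nrow(records)) else records$father_age
  no_age <- is.na(ma) & is.na(fa)
  out_of_range <- !bad_date & (cd < start | cd >= end)
  keep <- !bad_date & !no_age & !out_of_range

  drop_log <- data.frame(
    reason = c("missing_or_invalid_conception_date",
               "missing_both_parental_ages",
               "outside_interval"),
    n = c(sum(bad_date), sum(no_age & !bad_date),
          sum(out_of_range & !(no_age & !bad_date))),
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    for (i in seq_len(nrow(drop_log))) {
      if (drop_log$n[i] > 0)
        message("filter_cohort: dropped ", drop_log$n[i], " record(s): ",
                drop_log$reason[i])
    }
  }
  out <- records[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("filter_cohort: no records remain")
  attr(out, "drop_log") <- drop_log
  out
}

#' Daily conception series for one section window
#'
#' Aggregates a cohort to one bin per calendar day over the half-open
#' section \code{[start, end)}; days with no conceptions appear with zero
#' counts. Records outside the section are ignored.
#'
#' @param records cohort data.frame with \code{conception_date} and
#'   \code{is_case}.
#' @param section a list or one-row data.frame with \code{start} and
#'   \code{end} (Date) and optionally \code{label}.
#' @return an object of class \code{daily_series}: list with \code{days}
#'   (Date), \code{totals}, \code{cases} (integer per day), \code{N},
#'   \code{C} (section totals) and \code{section}.
#' @export
build_daily_series <- function(records, section) {
  start <- as.Date(section$start); end <- as.Date(section$end)
  stopifnot(start < end)
  days <- seq(start, end - 1L, by = "day")
  cd <- as.Date(records$conception_date)
  sel <- !is.na(cd) & cd >= start & cd < end
  idx <- as.integer(cd[sel] - start) + 1L
  totals <- tabulate(idx, nbins = length(days))
  cases <- tabulate(idx[records$is_case[sel] == 1L], nbins = length(days))
  daily_series(days, totals, cases,
               label = if (!is.null(section$label)) as.character(section$label)
                       else paste(start, end, sep = "/"))
}

#' Construct a daily series object
#'
#' @param days contiguous, strictly increasing Date vector.
#' @param totals,cases nonnegative integer counts per day, \code{cases <=
#'   totals} elementwise.
#' @param label optional text label.
#' @return \code{daily_series} object (see \code{\link{build_daily_series}}).
#' @export
daily_series <- function(days, totals, cases, label = "") {
  days <- as.Date(days)
  totals <- as.integer(totals); cases <- as.integer(cases)
  stopifnot(length(days) == length(totals),
            length(days) == length(cases))
  if (length(days) > 1L && !all(diff(days) == 1L))
    stop("days must be contiguous and strictly increasing")
  if (any(totals < 0L) || any(cases < 0L)) stop("negative counts")
  if (any(cases > totals)) stop("cases exceed totals on some day")
  structure(list(days = days, totals = totals, cases = cases,
                 N = sum(totals), C = sum(cases), label = label),
            class = "daily_series")
}

#' @export
print.daily_series <- function(x, ...) {
  cat("Daily conception series", if (nzchar(x$label)) paste0("[", x$label, "]"),
      "\n  days:", length(x$days),
      paste0("(", format(x$days[1]), " .. ", format(x$days[length(x$days)]), ")"),
      "\n  conceptions N =", x$N, " cases C =", x$C, "\n")
  invisible(x)
}

#' Descriptive statistics of the study population by conception year
#'
#' One row per conception calendar year: live births, cases, and for each
#' coded covariate the count and the percentage of all live births that
#' year (integer-rounded), mirroring the usual cohort-description table.
#' Education and race reference categories (< 12 years; non-Hispanic
#' white) are omitted from the percentage columns, as is conventional.
#'
#' @param records cohort data.frame.
#' @return data.frame, one row per year.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) > 0L)
  cov <- code_covariates(records)
  year <- as.integer(format(as.Date(records$conception_date), "%Y"))
  counts <- list(
    medi_cal = cov$medi_cal == 1L,
    preterm = !is.na(cov$preterm) & cov$preterm == 1L,
    male = cov$sex_male == 1L,
    low_birth_weight = !is.na(cov$low_birth_weight) & cov$low_birth_weight == 1L,
    parental_age_35plus = cov$parental_age_35plus == 1L,
    educ_12to16 = !is.na(cov$educ_category) & cov$educ_category == "12to16",
    educ_gt16 = !is.na(cov$educ_category) & cov$educ_category == "gt16",
    hispanic_white = !is.na(cov$race) & cov$race == "hispanic_white",
    black = !is.na(cov$race) & cov$race == "black",
    asian = !is.na(cov$race) & cov$race == "asian",
    other_race = !is.na(cov$race) & cov$race == "other"
  )
  years <- sort(unique(year))
  out <- data.frame(year = years)
  out$live_births <- vapply(years, function(y) sum(year == y), integer(1))
  out$cases <- vapply(years, function(y)
    sum(records$is_case[year == y] == 1L), integer(1))
  for (nm in names(counts)) {
    n <- vapply(years, function(y) sum(counts[[nm]][year == y]), integer(1))
    out[[paste0(nm, "_n")]] <- n
    out[[paste0(nm, "_pct")]] <- as.integer(round(100 * n / out$live_births))
  }
  out
}
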