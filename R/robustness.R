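#' Cluster-period membership labels
#'
#' Codes each record 1 if conceived during the cluster period (both
#' printed endpoints inclusive) and 0 otherwise. All records must lie
#' within the cluster's section window (half-open).
#'
#' @param records cohort data.frame restricted to the cluster's section.
#' @param cluster list or one-row data.frame with \code{start} and
#'   \code{end} (inclusive cluster dates).
#' @param section list with \code{start}/\code{end} of the section the
#'   cluster was found in; a record outside it is an error.
#' @return integer vector of 0/1 labels.
#' @export
cluster_membership <- function(records, cluster, section) {
  cd <- as.Date(records$conception_date)
  ss <- as.Date(section$start); se <- as.Date(section$end)
  if (any(is.na(cd)) || any(cd < ss | cd >= se))
    stop("records outside the cluster's section window")
  cs <- as.Date(cluster$start); ce <- as.Date(cluster$end)
  as.integer(cd >= cs & cd <= ce)
}

wald_report <- function(fit, n) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  data.frame(term = names(est),
             or = exp(est),
             ci_lo = exp(est - 1.959964 * se),
             ci_hi = exp(est + 1.959964 * se),
             p = 2 * pnorm(-abs(z)),
             n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

drop_degenerate <- function(df, terms) {
  keep <- character(0)
  for (tm in terms) {
    v <- df[[tm]]
    nvals <- length(unique(v[!is.na(v)]))
    if (nvals < 2L) {
      warning("term ", tm, " is constant; dropped from the model")
    } else keep <- c(keep, tm)
  }
  keep
}

#' Cluster-composition logistic regression
#'
#' Predicts cluster-period membership from the coded autism risk factors
#' (sex, mean parental age >= 35, parental education with < 12 years as
#' reference, race/ethnicity with non-Hispanic white as reference, and
#' Medi-Cal insurance status), within one section window. A systematic
#' compositional difference of the cluster would show up as odds ratios
#' away from 1.
#'
#' @param records_in_section cohort rows of one section window.
#' @param labels 0/1 cluster membership from
#'   \code{\link{cluster_membership}}.
#' @return regression report data.frame: \code{term}, \code{or},
#'   \code{ci_lo}, \code{ci_hi}, \code{p}, \code{n}.
#' @export
composition_model <- function(records_in_section, labels) {
  stopifnot(length(labels) == nrow(records_in_section))
  if (length(unique(labels)) < 2L)
    stop("both membership classes must be present")
  cov <- code_covariates(records_in_section)
  cov$membership <- labels
  cc <- stats::complete.cases(cov)
  cov <- cov[cc, , drop = FALSE]
  terms <- drop_degenerate(cov, c("sex_male", "parental_age_35plus",
                                  "educ_category", "race", "medi_cal"))
  if (length(terms) == 0L) stop("no usable covariates")
  fit <- glm(stats::reformulate(terms, response = "membership"),
             data = cov, family = binomial())
  wald_report(fit, sum(cc))
}

#' Birth-outcome regressions on cluster status
#'
#' Regresses preterm birth and low birth weight separately on
#' cluster-period membership (logistic), to check whether detected
#' clusters differ in birth outcomes. Records missing the outcome
#' measurement are excluded from that outcome's model.
#'
#' @inheritParams composition_model
#' @return named list of regression reports (\code{preterm},
#'   \code{low_birth_weight}); an element is \code{NULL}, with a
#'   warning, when the outcome does not vary.
#' @export
outcome_models <- function(records_in_section, labels) {
  stopifnot(length(labels) == nrow(records_in_section))
  cov <- code_covariates(records_in_section)
  out <- list(preterm = NULL, low_birth_weight = NULL)
  for (nm in names(out)) {
    y <- cov[[nm]]
    ok <- !is.na(y)
    if (sum(ok) == 0L || length(unique(y[ok])) < 2L ||
        length(unique(labels[ok])) < 2L) {
      warning("outcome ", nm, " (or membership) does not vary; model skipped")
      next
    }
    d <- data.frame(y = y[ok], membership = labels[ok])
    fit <- glm(y ~ membership, data = d, family = binomial())
    out[[nm]] <- wald_report(fit, sum(ok))
  }
  out
}

#' Circular day-of-year distance between two dates
#'
#' Distance between the dates' day-of-year values on a 365-day circle,
#' ignoring the year: \code{min(|a - b|, 365 - |a - b|)}, with February
#' 29 mapped to February 28. Used to compare conception timing across
#' different years.
#'
#' @param d1,d2 Date vectors (recycled).
#' @return integer distance in days, in \code{[0, 182]}.
#' @examples
#' circular_day_distance(as.Date("1994-01-01"), as.Date("1996-12-31"))  # 1
#' @export
circular_day_distance <- function(d1, d2) {
  doy <- function(d) {
    d <- as.Date(d)
    lt <- as.POSIXlt(d)
    x <- lt$yday + 1L
    leap <- (lt$year + 1900L) %% 4L == 0L &
      ((lt$year + 1900L) %% 100L != 0L | (lt$year + 1900L) %% 400L == 0L)
    x[leap & x >= 60L] <- x[leap & x >= 60L] - 1L   # Feb 29 -> Feb 28
    x
  }
  a <- doy(d1); b <- doy(d2)
  d <- abs(a - b)
  pmin(d, 365L - d)
}

#' Assortative-conception sibling test
#'
#' For each timeframe t, compares the percentage of case-index sibling
#' pairs and control-index sibling pairs conceived within t circular
#' days of each other (day-of-year, independent of year), with a Pearson
#' chi-square test on the 2x2 table (case/control x within/not within).
#' Temporally consistent family planning among case families would show
#' up as a significantly higher case percentage at short timeframes.
#'
#' @param pairs data.frame from \code{\link{sibling_pairs}} (columns
#'   \code{index_case}, \code{index_date}, \code{sibling_date}; rows
#'   should already be restricted to index children conceived in a
#'   cluster period, per the study design). If an
#'   \code{index_in_cluster} column is present, rows with \code{TRUE}
#'   are used.
#' @param timeframes numeric vector of day windows t; fractional values
#'   are compared as \code{distance <= t} on the real line.
#' @param correct apply the continuity correction (default off).
#' @return data.frame: \code{timeframe}, \code{case_pct},
#'   \code{control_pct}, \code{chisq}, \code{p}, \code{n_case_pairs},
#'   \code{n_control_pairs}. Rows are \code{NA}-flagged when either side
#'   has no pairs.
#' @export
assortative_test <- function(pairs, timeframes = c(15, 22.5, 30, 45),
                             correct = FALSE) {
  if (!is.null(pairs$index_in_cluster) && !all(is.na(pairs$index_in_cluster)))
    pairs <- pairs[pairs$index_in_cluster %in% TRUE, , drop = FALSE]
  dist <- circular_day_distance(pairs$index_date, pairs$sibling_date)
  case <- pairs$index_case == 1L
  n_case <- sum(case); n_ctrl <- sum(!case)
  out <- lapply(timeframes, function(t) {
    within <- dist <= t
    if (n_case == 0L || n_ctrl == 0L) {
      warning("no pairs on one side; timeframe ", t, " undefined")
      return(data.frame(timeframe = t, case_pct = NA_real_,
                        control_pct = NA_real_, chisq = NA_real_,
                        p = NA_real_, n_case_pairs = n_case,
                        n_control_pairs = n_ctrl))
    }
    a <- sum(within & case); b <- sum(!within & case)
    cc <- sum(within & !case); d <- sum(!within & !case)
    tab <- matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE)
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    stat <- as.numeric(ct$statistic); pv <- ct$p.value
    if (!is.finite(stat)) { stat <- 0; pv <- 1 }   # no variation in 'within'
    data.frame(timeframe = t,
               case_pct = 100 * a / n_case,
               control_pct = 100 * cc / n_ctrl,
               chisq = stat, p = pv,
               n_case_pairs = n_case, n_control_pairs = n_ctrl)
  })
  do.call(rbind, out)
}

#' Gestational-age distributions and odds ratios by week
#'
#' Tabulates, per integer gestational week, the fraction of cases and
#' the fraction of all births, and the odds ratio of case status for
#' that week against the 40-week reference bin; also reports the overall
#' preterm (< 37 weeks) fractions among cases and among all births.
#'
#' @param records cohort data.frame with \code{gestational_age} present.
#' @param reference_week reference bin for the odds ratios.
#' @return list: \code{profile} (data.frame per week: \code{week},
#'   \code{n_cases}, \code{n_births}, \code{frac_cases},
#'   \code{frac_births}, \code{or}, \code{or_defined}),
#'   \code{preterm_case_frac}, \code{preterm_all_frac}.
#' @export
gestational_age_profile <- function(records, reference_week = 40L) {
  ga <- records$gestational_age
  ok <- !is.na(ga)
  stopifnot(any(ok))
  wk <- as.integer(floor(ga[ok]))
  case <- records$is_case[ok] == 1L
  weeks <- sort(unique(wk))
  # doubles: count products overflow 32-bit integers at cohort scale
  a_ref <- as.numeric(sum(case & wk == reference_week))   # cases at ref
  c_ref <- as.numeric(sum(!case & wk == reference_week))  # non-cases at ref
  prof <- do.call(rbind, lapply(weeks, function(w) {
    a <- as.numeric(sum(case & wk == w))
    cc <- as.numeric(sum(!case & wk == w))
    or_ok <- a_ref > 0 && c_ref > 0 && cc > 0 && w != reference_week
    or <- if (w == reference_week) 1
          else if (or_ok) (a * c_ref) / (cc * a_ref) else NA_real_
    data.frame(week = w, n_cases = a, n_births = a + cc,
               frac_cases = a / sum(case),
               frac_births = (a + cc) / length(wk),
               or = or, or_defined = w == reference_week || or_ok)
  }))
  if (any(!prof$or_defined))
    warning("odds ratio undefined for empty bin(s): week ",
            paste(prof$week[!prof$or_defined], collapse = ", "))
  list(profile = prof,
       preterm_case_frac = sum(case & wk < 37) / sum(case),
       preterm_all_frac = sum(wk < 37) / length(wk))
}
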