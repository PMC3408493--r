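# Calendar-year calibration of the generator defaults: live births and
# sole-autism case counts per conception year, 1992-2000 (2000 covers
# January-March only, 91 days). Daily conception means and baseline case
# probabilities are derived from these.
sim_year_table <- function() {
  data.frame(
    year = 1992:2000,
    births = c(525795L, 511918L, 477627L, 488756L, 483284L, 461626L,
               407297L, 405513L, 126679L),
    cases = c(310L, 488L, 728L, 1032L, 1180L, 1306L, 1280L, 1311L, 439L),
    days_covered = c(rep(365.25, 8), 91)
  )
}

default_clusters <- function() {
  data.frame(
    start = as.Date(c("1994-11-07", "1995-11-09", "1996-11-07")),
    end = as.Date(c("1994-12-02", "1995-12-07", "1996-12-06")),  # inclusive
    case_prob = c(82 / 35323, 109 / 38602, 134 / 41615)
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the California 1992-2000 birth cohort the analysis
#' targets: year-specific daily conception means and baseline case
#' probabilities derived from the published per-year birth and case
#' counts (the rising secular trend), and three implanted late-November
#' high-risk windows in 1994-1996 at the published in-window case rates.
#'
#' @param start,end series range (half-open), conceptions only.
#' @param daily_conceptions mean conceptions per day: a single number or
#'   a vector named by year. Default: published births per year / days.
#' @param baseline_case_prob probability a conception is a case outside
#'   any cluster: single number or vector named by year (encodes the
#'   trend). Default: published cases/births per year.
#' @param clusters data.frame with \code{start}, \code{end} (inclusive
#'   dates) and \code{case_prob}; \code{NULL} for no implanted clusters.
#' @param covariate_marginals list of marginal frequencies/parameters for
#'   the independent covariate draws (see defaults in the source).
#' @param sibling_fraction probability a family gets one linked sibling.
#' @param sibling_gap_days list \code{(mean, sd)} of the gamma
#'   inter-sibling conception spacing, in days.
#' @param sibling_mode \code{"independent"} (sibling day-of-year
#'   unrelated to the index child's) or \code{"assortative"} (sibling
#'   conceived a whole number of years away, within a few days of the
#'   index day-of-year).
#' @param strata_probs list: \code{metro} = P(metro stratum),
#'   \code{south} = P(south region).
#' @param cluster_covariate_or named list of odds ratios applied to
#'   binary covariates (\code{sex_male}, \code{medi_cal}) for in-cluster
#'   conceptions; a confounding hook for composition-model checks.
#' @param cluster_outcome_or named list of odds ratios applied to birth
#'   outcomes (\code{preterm}) for in-cluster conceptions.
#' @param cluster_stratum optional list \code{(field, value)} restricting
#'   the implanted risk elevation to one geographic stratum.
#' @param exact_n if \code{TRUE}, daily totals are a multinomial split of
#'   the (rounded) total expected conceptions instead of Poisson draws.
#' @param seasonal_amplitude optional within-year sinusoidal modulation
#'   of the daily conception mean (0 = uniform within year).
#' @param trend_mode how year-specific \code{baseline_case_prob} values
#'   become a daily risk: \code{"interpolate"} (default) treats them as
#'   mid-year anchors joined piecewise-linearly, giving the gradual
#'   secular trend real incidence data show; \code{"step"} holds each
#'   year's value constant, which puts artificial risk jumps at January 1
#'   that a day-resolution scan can pick up as spurious clusters.
#' @param seed integer seed; generation is deterministic given it.
#' @return validated \code{sim_config} object (a list).
#' @export
sim_config <- function(start = as.Date("1992-03-01"),
                       end = as.Date("2000-03-01"),
                       daily_conceptions = NULL,
                       baseline_case_prob = NULL,
                       clusters = default_clusters(),
                       covariate_marginals = list(),
                       sibling_fraction = 0.3,
                       sibling_gap_days = list(mean = 900, sd = 350),
                       sibling_mode = c("independent", "assortative"),
                       strata_probs = list(metro = 0.8, south = 0.67),
                       cluster_covariate_or = NULL,
                       cluster_outcome_or = NULL,
                       cluster_stratum = NULL,
                       exact_n = FALSE,
                       seasonal_amplitude = 0,
                       trend_mode = c("interpolate", "step"),
                       seed = 1L) {
  yt <- sim_year_table()
  if (is.null(daily_conceptions))
    daily_conceptions <- setNames(yt$births / yt$days_covered, yt$year)
  if (is.null(baseline_case_prob))
    baseline_case_prob <- setNames(yt$cases / yt$births, yt$year)
  marg <- list(male = 0.51, medi_cal = 0.41,
               race = c(non_hispanic_white = 0.36, hispanic_white = 0.45,
                        black = 0.07, asian = 0.10, other = 0.02),
               preterm_case = 0.11, preterm_control = 0.013,
               mother_age_mean = 27.5, mother_age_sd = 6,
               father_age_gap_mean = 2.5, father_age_gap_sd = 4,
               mother_age_missing = 0.005, father_age_missing = 0.09,
               educ_mean = 13.2, educ_sd = 2.8)
  marg[names(covariate_marginals)] <- covariate_marginals
  start <- as.Date(start); end <- as.Date(end)
  if (!is.null(clusters) && nrow(clusters) > 0) {
    # default implants cover 1994-1996; clusters wholly outside a narrower
    # series range are dropped, but straddling the boundary is an error
    inside <- as.Date(clusters$start) >= start & as.Date(clusters$end) < end
    outside <- as.Date(clusters$end) < start | as.Date(clusters$start) >= end
    if (any(!inside & !outside))
      stop("cluster interval straddles the series range; ",
           "clusters must lie within [start, end)")
    clusters <- clusters[inside, , drop = FALSE]
    if (nrow(clusters) == 0L) clusters <- NULL
  }
  cfg <- list(start = start, end = end,
              daily_conceptions = daily_conceptions,
              baseline_case_prob = baseline_case_prob,
              clusters = clusters, covariate_marginals = marg,
              sibling_fraction = sibling_fraction,
              sibling_gap_days = sibling_gap_days,
              sibling_mode = match.arg(sibling_mode),
              strata_probs = strata_probs,
              cluster_covariate_or = cluster_covariate_or,
              cluster_outcome_or = cluster_outcome_or,
              cluster_stratum = cluster_stratum,
              exact_n = exact_n,
              seasonal_amplitude = seasonal_amplitude,
              trend_mode = match.arg(trend_mode),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$baseline_case_prob, cfg$covariate_marginals$male,
             cfg$covariate_marginals$medi_cal,
             cfg$covariate_marginals$preterm_case,
             cfg$covariate_marginals$preterm_control,
             cfg$sibling_fraction, cfg$strata_probs$metro,
             cfg$strata_probs$south)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop("sim_config: probabilities must lie in [0, 1]")
  if (any(cfg$daily_conceptions <= 0))
    stop("sim_config: daily_conceptions must be positive")
  if (cfg$start >= cfg$end) stop("sim_config: start must precede end")
  if (!is.null(cfg$clusters) && nrow(cfg$clusters) > 0) {
    cl <- cfg$clusters
    if (any(cl$case_prob < 0) || any(cl$case_prob > 1))
      stop("sim_config: cluster case_prob must lie in [0, 1]")
    if (any(as.Date(cl$start) < cfg$start) || any(as.Date(cl$end) >= cfg$end))
      stop("sim_config: cluster intervals must lie within [start, end)")
  }
  invisible(cfg)
}

#' Read a generator configuration from a YAML file
#'
#' Keys mirror the arguments of \code{\link{sim_config}}; dates are
#' ISO-8601 strings, \code{clusters} a list of \code{start}/\code{end}/
#' \code{case_prob} mappings.
#'
#' @param path YAML file path.
#' @return \code{sim_config} object.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$clusters)) {
    y$clusters <- do.call(rbind, lapply(y$clusters, function(cl)
      data.frame(start = as.Date(cl$start), end = as.Date(cl$end),
                 case_prob = as.numeric(cl$case_prob))))
  }
  for (nm in c("start", "end")) if (!is.null(y[[nm]])) y[[nm]] <- as.Date(y[[nm]])
  for (nm in c("daily_conceptions", "baseline_case_prob"))
    if (!is.null(y[[nm]]) && length(y[[nm]]) > 1L) y[[nm]] <- unlist(y[[nm]])
  do.call(sim_config, y)
}

per_day_lookup <- function(values, years) {
  if (length(values) == 1L && is.null(names(values)))
    return(rep(as.numeric(values), length(years)))
  v <- values[as.character(years)]
  if (any(is.na(v)))
    stop("no value configured for year(s) ",
         paste(unique(years[is.na(v)]), collapse = ", "))
  as.numeric(v)
}

odds_shift <- function(p, or) p * or / (1 - p + p * or)

# Piecewise-linear daily values through mid-year anchors (year averages),
# clamped outside the anchored range.
interp_yearly <- function(values, days) {
  yrs <- as.integer(names(values))
  if (is.null(names(values)) || any(is.na(yrs)))
    stop("year-specific values must be named by year")
  anchors <- as.numeric(as.Date(sprintf("%d-07-01", yrs)))
  stats::approx(anchors, as.numeric(values), xout = as.numeric(days),
                rule = 2)$y
}

#' Generate a synthetic conception cohort
#'
#' Draws a daily conception process over \code{[start, end)} (Poisson
#' around the configured daily means, or an exact multinomial split),
#' labels each conception a case with the day's applicable probability
#' (implanted cluster windows override the baseline), and draws
#' covariates from the configured marginals. Deterministic given the
#' config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return cohort data.frame (see \link{cohort-schema}), one row per
#'   child, each child its own family.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  m <- config$covariate_marginals
  days <- seq(config$start, config$end - 1L, by = "day")
  years <- as.integer(format(days, "%Y"))
  mu <- per_day_lookup(config$daily_conceptions, years)
  if (config$seasonal_amplitude != 0) {
    doy <- as.integer(format(days, "%j"))
    mu <- mu * (1 + config$seasonal_amplitude * sin(2 * pi * doy / 365.25))
  }
  totals <- if (config$exact_n) {
    as.integer(rmultinom(1, round(sum(mu)), mu / sum(mu)))
  } else rpois(length(days), mu)

  p_base <- if (config$trend_mode == "interpolate" &&
                length(config$baseline_case_prob) > 1L) {
    interp_yearly(config$baseline_case_prob, days)
  } else per_day_lookup(config$baseline_case_prob, years)
  cluster_of_day <- integer(length(days))   # 0 = none
  if (!is.null(config$clusters) && nrow(config$clusters) > 0) {
    for (k in seq_len(nrow(config$clusters))) {
      sel <- days >= as.Date(config$clusters$start[k]) &
             days <= as.Date(config$clusters$end[k])
      cluster_of_day[sel] <- k
    }
  }

  day_idx <- rep.int(seq_along(days), totals)
  n <- length(day_idx)
  if (n == 0L) stop("generated an empty cohort; increase daily_conceptions")

  stratum_metro <- ifelse(runif(n) < config$strata_probs$metro,
                          "metro", "adjacent")
  stratum_region <- ifelse(runif(n) < config$strata_probs$south,
                           "south", "north")
  in_cluster <- cluster_of_day[day_idx] > 0L
  if (!is.null(config$cluster_stratum)) {
    sv <- if (config$cluster_stratum$field == "stratum_metro")
      stratum_metro else stratum_region
    in_cluster <- in_cluster & sv == config$cluster_stratum$value
  }
  p_case <- p_base[day_idx]
  if (any(in_cluster))
    p_case[in_cluster] <-
      config$clusters$case_prob[cluster_of_day[day_idx[in_cluster]]]
  is_case <- rbinom(n, 1L, p_case)

  hook_p <- function(p, name) {
    p <- rep(p, length.out = n)
    or <- config$cluster_covariate_or[[name]]
    if (!is.null(or)) p[in_cluster] <- odds_shift(p[in_cluster], or)
    p
  }
  sex_male <- rbinom(n, 1L, hook_p(m$male, "sex_male"))
  medi_cal <- rbinom(n, 1L, hook_p(m$medi_cal, "medi_cal"))
  race <- sample(names(m$race), n, replace = TRUE, prob = m$race)

  mother_age <- pmin(pmax(rnorm(n, m$mother_age_mean, m$mother_age_sd), 15), 50)
  father_age <- pmin(pmax(mother_age +
                            rnorm(n, m$father_age_gap_mean, m$father_age_gap_sd),
                          15), 70)
  mother_age[runif(n) < m$mother_age_missing] <- NA_real_
  father_age[runif(n) < m$father_age_missing] <- NA_real_
  mother_educ <- pmin(pmax(round(rnorm(n, m$educ_mean, m$educ_sd)), 6), 20)
  father_educ <- pmin(pmax(round(rnorm(n, m$educ_mean, m$educ_sd)), 6), 20)

  p_pre <- ifelse(is_case == 1L, m$preterm_case, m$preterm_control)
  or_pre <- config$cluster_outcome_or$preterm
  if (!is.null(or_pre)) p_pre[in_cluster] <- odds_shift(p_pre[in_cluster], or_pre)
  preterm <- rbinom(n, 1L, p_pre)
  ga_pre_weights <- c(1, 1, 2, 2, 3, 4, 5, 7, 9, 12, 15)   # weeks 26..36
  ga_term_weights <- exp(-((37:44 - 40)^2) / (2 * 1.3^2))
  gestational_age <- integer(n)
  gestational_age[preterm == 1L] <- sample(26:36, sum(preterm), replace = TRUE,
                                           prob = ga_pre_weights)
  gestational_age[preterm == 0L] <- sample(37:44, sum(preterm == 0L),
                                           replace = TRUE, prob = ga_term_weights)
  birth_weight <- pmax(round(rnorm(n, 3350 - 170 * (40 - gestational_age), 400)),
                       400)

  conception_date <- days[day_idx]
  data.frame(
    child_id = sprintf("c%08d", seq_len(n)),
    family_id = sprintf("f%08d", seq_len(n)),
    last_menses = conception_date - 14L,
    conception_date = conception_date,
    is_case = is_case, sex_male = sex_male,
    mother_age = mother_age, father_age = father_age,
    mother_educ = mother_educ, father_educ = father_educ,
    race = race, medi_cal = medi_cal,
    gestational_age = gestational_age, birth_weight = birth_weight,
    stratum_metro = stratum_metro, stratum_region = stratum_region,
    stringsAsFactors = FALSE
  )
}

#' Generate a signal-free daily series for permutation-test calibration
#'
#' Spreads \code{N} conceptions uniformly over \code{days} and assigns
#' the \code{C} case labels uniformly at random among the conceptions,
#' so there is no day effect by construction.
#'
#' @param days number of days.
#' @param N total conceptions; \code{C} total cases, \code{C <= N}.
#' @param seed integer seed.
#' @param start_date calendar date of the first day (cosmetic).
#' @return a \code{daily_series} with \code{sum(cases) == C} exactly.
#' @export
generate_null_series <- function(days, N, C, seed = 1L,
                                 start_date = as.Date("1994-03-01")) {
  stopifnot(days >= 1L, N >= 0L, C <= N, C >= 0L)
  set.seed(as.integer(seed))
  totals <- as.integer(rmultinom(1, N, rep(1 / days, days)))
  cases <- integer(days)
  if (C > 0L) {
    u <- sample.int(N, C)
    cum <- cumsum(totals)
    day_of_case <- findInterval(u - 0.5, c(0, cum))
    cases <- tabulate(day_of_case, nbins = days)
  }
  daily_series(seq(as.Date(start_date), by = "day", length.out = days),
               totals, cases, label = "null")
}

#' Add linked sibling records to a cohort
#'
#' For a configured fraction of families, draws one sibling conception
#' per family. In \code{"independent"} mode the sibling is offset by a
#' gamma-distributed spacing (random sign), making sibling day-of-year
#' independent of the index child's under the null. In
#' \code{"assortative"} mode the sibling is conceived a whole number of
#' years away, within a few days of the index child's day-of-year,
#' emulating temporally consistent family planning.
#'
#' @param records cohort data.frame (the index children).
#' @param config a \code{\link{sim_config}}; uses
#'   \code{sibling_fraction}, \code{sibling_gap_days},
#'   \code{sibling_mode} and \code{seed}.
#' @return data.frame of the new sibling records only (same columns;
#'   siblings are controls with the family's identifiers).
#' @export
generate_siblings <- function(records, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 77003L)
  pick <- runif(nrow(records)) < config$sibling_fraction
  idx <- which(pick)
  if (length(idx) == 0L) return(records[0, , drop = FALSE])
  index_date <- as.Date(records$conception_date[idx])
  nsib <- length(idx)
  if (config$sibling_mode == "assortative") {
    yshift <- sample(c(-3L, -2L, -1L, 1L, 2L, 3L), nsib, replace = TRUE)
    offset <- sample(-6:6, nsib, replace = TRUE)
    sib_date <- index_date + yshift * 365L + offset
  } else {
    gp <- config$sibling_gap_days
    shape <- (gp$mean / gp$sd)^2
    gap <- pmax(round(stats::rgamma(nsib, shape = shape,
                                    rate = shape / gp$mean)), 270)
    sgn <- sample(c(-1L, 1L), nsib, replace = TRUE)
    sib_date <- index_date + sgn * gap
  }
  sib_date <- pmin(pmax(sib_date, as.Date("1991-01-01")), as.Date("2005-12-31"))
  sib <- records[idx, , drop = FALSE]
  sib$child_id <- sprintf("s%08d", seq_len(nsib))
  sib$conception_date <- sib_date
  sib$last_menses <- sib_date - 14L
  sib$is_case <- 0L
  sib$sex_male <- rbinom(nsib, 1L, config$covariate_marginals$male)
  rownames(sib) <- NULL
  sib
}

#' Build sibling pairs for the assortative-conception test
#'
#' Joins index children to their generated siblings by family and flags
#' whether the index child was conceived during any detected cluster
#' period (both endpoints inclusive).
#'
#' @param records index cohort.
#' @param siblings sibling records from \code{\link{generate_siblings}}.
#' @param clusters optional data.frame with \code{start}/\code{end}
#'   cluster dates; when given, \code{index_in_cluster} is computed.
#' @return data.frame: \code{family_id}, \code{index_case},
#'   \code{index_date}, \code{sibling_date}, \code{index_in_cluster}.
#' @export
sibling_pairs <- function(records, siblings, clusters = NULL) {
  ix <- match(siblings$family_id, records$family_id)
  keep <- !is.na(ix)
  sib <- siblings[keep, , drop = FALSE]
  ix <- ix[keep]
  index_date <- as.Date(records$conception_date[ix])
  in_cl <- rep(NA, length(ix))
  if (!is.null(clusters) && nrow(clusters) > 0) {
    in_cl <- rep(FALSE, length(ix))
    for (k in seq_len(nrow(clusters)))
      in_cl <- in_cl | (index_date >= as.Date(clusters$start[k]) &
                        index_date <= as.Date(clusters$end[k]))
  }
  data.frame(family_id = sib$family_id,
             index_case = records$is_case[ix],
             index_date = index_date,
             sibling_date = as.Date(sib$conception_date),
             index_in_cluster = in_cl,
             stringsAsFactors = FALSE)
}
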