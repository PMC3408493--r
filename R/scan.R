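#' Expected cases in a candidate window under the null
#'
#' Under the Bernoulli null hypothesis the expected number of cases in a
#' window containing \code{n_z} of the section's \code{N} conceptions is
#' the window share of the section's \code{C} cases.
#'
#' @param n_z conceptions in the window.
#' @param C,N section case and conception totals.
#' @return \code{n_z * C / N}.
#' @examples
#' expected_count(35323, 1673, 1480000)  # 39.93
#' @export
expected_count <- function(n_z, C, N) {
  if (any(N == 0)) stop("N must be positive")
  if (any(n_z > N) || any(C > N)) stop("window/case totals exceed N")
  if (any(n_z < 0) || any(C < 0)) stop("negative counts")
  n_z * C / N
}

#' Relative risk of a candidate window
#'
#' Case rate inside the window divided by the case rate outside it,
#' within the window's section.
#'
#' @param c cases in the window.
#' @param n_z conceptions in the window, \code{0 < n_z < N}.
#' @param C,N section totals.
#' @return \code{(c/n_z) / ((C-c)/(N-n_z))}; \code{Inf} when all the
#'   section's cases fall in the window (\code{c == C > 0}); 0 when
#'   \code{c == 0 < C}.
#' @examples
#' relative_risk(82, 35323, 1673, 1480000)  # 2.11
#' @export
relative_risk <- function(c, n_z, C, N) {
  if (any(c > C) || any(n_z > N)) stop("window counts exceed section totals")
  if (any(n_z <= 0) || any(n_z >= N)) stop("require 0 < n_z < N")
  if (any(c < 0) || any(c > n_z)) stop("require 0 <= c <= n_z")
  inside <- c / n_z
  outside <- (C - c) / (N - n_z)
  out <- ifelse(c == 0 & C > 0, 0,
         ifelse(c == C & c > 0, Inf, inside / outside))
  out
}

xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Bernoulli scan log likelihood ratio of a candidate window
#'
#' One-sided (high-rate) Bernoulli likelihood-ratio statistic: the log of
#' the maximized likelihood with separate in-window and out-of-window
#' case probabilities over the maximized likelihood with a common
#' probability, or 0 when the window rate does not exceed the outside
#' rate. \code{0*log(0)} is taken as 0.
#'
#' @inheritParams relative_risk
#' @return nonnegative log likelihood ratio.
#' @export
bernoulli_llr <- function(c, n_z, C, N) {
  if (any(c > C) || any(n_z > N)) stop("window counts exceed section totals")
  if (any(n_z <= 0) || any(n_z >= N)) stop("require 0 < n_z < N")
  if (any(c < 0) || any(c > n_z)) stop("require 0 <= c <= n_z")
  co <- C - c; no <- N - n_z
  high <- c / n_z > co / no
  ll <- xlogy(c, c / n_z) + xlogy(n_z - c, 1 - c / n_z) +
    xlogy(co, co / no) + xlogy(no - co, 1 - co / no) -
    xlogy(C, C / N) - xlogy(N - C, 1 - C / N)
  ifelse(high, ll, 0)
}

null_cluster_result <- function(reps = NA_integer_) {
  data.frame(start = as.Date(NA), end = as.Date(NA),
             n = NA_real_, c = NA_real_, E = NA_real_, RR = NA_real_,
             LLR = 0, p = NA_real_, reps = reps)
}

#' Most likely temporal cluster of a daily series
#'
#' Enumerates every contiguous day window of length 1 to
#' \code{max_len_days} and returns the one maximizing the Bernoulli log
#' likelihood ratio (ties: earliest start, then shortest window), with
#' its expected count and relative risk. The Monte Carlo p-value is not
#' computed here (see \code{\link{monte_carlo_p}} and
#' \code{\link{scan_section}}).
#'
#' @param series a \code{daily_series}.
#' @param max_len_days maximum candidate window length in days.
#' @return one-row data.frame: \code{start}, \code{end} (both inclusive),
#'   \code{n}, \code{c}, \code{E}, \code{RR}, \code{LLR}, \code{p = NA},
#'   \code{reps = NA}. When the series has no cases, a null row with
#'   \code{LLR = 0} and \code{NA} dates.
#' @export
find_most_likely_cluster <- function(series, max_len_days = 90L) {
  stopifnot(inherits(series, "daily_series"))
  max_len_days <- as.integer(max_len_days)
  stopifnot(max_len_days >= 1L, max_len_days <= length(series$days))
  if (series$C == 0L) return(null_cluster_result())
  sc <- .scan_max_llr(series$totals, series$cases, max_len_days)
  if (!sc$found) return(null_cluster_result())
  start <- series$days[sc$start]
  end <- series$days[sc$start + sc$len - 1L]
  data.frame(
    start = start, end = end, n = sc$n, c = sc$c,
    E = expected_count(sc$n, series$C, series$N),
    RR = relative_risk(sc$c, sc$n, series$C, series$N),
    LLR = sc$llr, p = NA_real_, reps = NA_integer_
  )
}

#' Monte Carlo permutation p-value for an observed maximum LLR
#'
#' Conditions on the section totals N and C: each replicate redistributes
#' the C case labels uniformly at random among the N conceptions (keeping
#' the daily conception totals fixed) and rescans for the maximum LLR.
#' The p-value is \code{(1 + b) / (1 + reps)} where \code{b} replicates
#' meet or exceed the observed maximum.
#'
#' @param series a \code{daily_series}.
#' @param observed_llr maximum LLR observed on the real labels, from the
#'   same \code{max_len_days}.
#' @param reps number of permutation replicates.
#' @param seed integer seed; results are deterministic given it.
#' @param max_len_days maximum candidate window length in days.
#' @return p-value in \code{[1/(reps+1), 1]}.
#' @export
monte_carlo_p <- function(series, observed_llr, reps = 999L, seed = 1L,
                          max_len_days = 90L) {
  stopifnot(inherits(series, "daily_series"), reps >= 1L)
  set.seed(as.integer(seed))
  sims <- .scan_mc_max_llrs(series$totals, series$C, as.integer(reps),
                            as.integer(max_len_days))
  (1 + sum(sims >= observed_llr)) / (1 + reps)
}

#' Scan one section: most likely cluster plus its permutation p-value
#'
#' @inheritParams monte_carlo_p
#' @inheritParams find_most_likely_cluster
#' @return one-row data.frame as \code{\link{find_most_likely_cluster}},
#'   with \code{p} and \code{reps} filled in.
#' @export
scan_section <- function(series, max_len_days = 90L, reps = 999L, seed = 1L) {
  res <- find_most_likely_cluster(series, max_len_days)
  if (is.na(res$start)) { res$reps <- as.integer(reps); return(res) }
  res$p <- monte_carlo_p(series, res$LLR, reps = reps, seed = seed,
                         max_len_days = max_len_days)
  res$reps <- as.integer(reps)
  res
}
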