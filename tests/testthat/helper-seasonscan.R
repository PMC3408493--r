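# Builders and independent oracles shared across the test files.

# Minimal valid cohort rows; override any column via ...
toy_records <- function(n, conception_date, is_case = 0L, ...) {
  df <- data.frame(
    child_id = sprintf("c%04d", seq_len(n)),
    family_id = sprintf("f%04d", seq_len(n)),
    conception_date = rep(as.Date(conception_date), length.out = n),
    is_case = rep(as.integer(is_case), length.out = n),
    sex_male = 1L,
    mother_age = 28, father_age = 30,
    mother_educ = 12, father_educ = 14,
    race = "non_hispanic_white", medi_cal = 0L,
    gestational_age = 40, birth_weight = 3400,
    stratum_metro = "metro", stratum_region = "south",
    stringsAsFactors = FALSE
  )
  df$last_menses <- df$conception_date - 14L
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep(extra[[nm]], length.out = n)
  df
}

# Exhaustive enumeration oracle for the most likely cluster, written
# against the exported LLR formula only (never the compiled scan path).
# Same tie rule: earliest start, then shortest window.
brute_force_cluster <- function(series, max_len) {
  nd <- length(series$days)
  N <- series$N; C <- series$C
  ct <- cumsum(series$totals); cc <- cumsum(series$cases)
  best <- list(llr = 0, start = NA_integer_, len = NA_integer_,
               n = NA_real_, c = NA_real_)
  for (s in seq_len(nd)) {
    for (L in seq_len(min(max_len, nd - s + 1L))) {
      e <- s + L - 1L
      n <- ct[e] - if (s > 1L) ct[s - 1L] else 0L
      c <- cc[e] - if (s > 1L) cc[s - 1L] else 0L
      if (c == 0L || n == 0L || n >= N) next
      llr <- bernoulli_llr(c, n, C, N)
      if (llr > best$llr) best <- list(llr = llr, start = s, len = L,
                                       n = n, c = c)
    }
  }
  best
}

random_small_series <- function(seed, max_days = 50L, max_events = 500L) {
  set.seed(seed)
  nd <- sample(5:max_days, 1L)
  N <- sample(20:max_events, 1L)
  totals <- as.integer(rmultinom(1, N, rep(1 / nd, nd)))
  C <- sample.int(max(1L, N %/% 4L), 1L)
  u <- sample.int(N, C)
  day <- findInterval(u - 0.5, c(0, cumsum(totals)))
  daily_series(seq(as.Date("1994-03-01"), by = "day", length.out = nd),
               totals, tabulate(day, nbins = nd))
}

# Interval overlap Jaccard on inclusive date windows
jaccard_days <- function(s1, e1, s2, e2) {
  inter <- max(0, as.numeric(min(e1, e2) - max(s1, s2)) + 1)
  union <- as.numeric(max(e1, e2) - min(s1, s2)) + 1
  inter / union
}
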