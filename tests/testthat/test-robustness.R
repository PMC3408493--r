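sec94 <- list(start = as.Date("1992-03-01"), end = as.Date("1995-03-01"))
cl94 <- list(start = as.Date("1994-11-07"), end = as.Date("1994-12-02"))

test_that("cluster membership is inclusive of both printed endpoints", {
  r <- toy_records(4, c("1994-11-07", "1994-12-02", "1994-12-03",
                        "1994-11-06"))
  expect_equal(cluster_membership(r, cl94, sec94), c(1L, 1L, 0L, 0L))
  outside <- toy_records(1, "1995-03-01")
  expect_error(cluster_membership(outside, cl94, sec94), "section")
})

test_that("composition model equals the closed-form 2x2 odds ratio when a
           single covariate varies", {
  # deterministic counts: membership x medi_cal table (a,b,c,d)
  a <- 30L; b <- 120L; cc <- 40L; d <- 560L   # OR = (30*560)/(120*40) = 3.5
  r <- toy_records(a + b + cc + d, "1994-11-15")
  r$medi_cal <- rep(c(1L, 0L, 1L, 0L), c(a, b, cc, d))
  labels <- rep(c(1L, 1L, 0L, 0L), c(a, b, cc, d))
  rep1 <- suppressWarnings(composition_model(r, labels))
  expect_equal(rep1$or[rep1$term == "medi_cal"], (a * d) / (b * cc),
               tolerance = 1e-6)
  expect_true(rep1$ci_lo[rep1$term == "medi_cal"] <
                rep1$or[rep1$term == "medi_cal"])
  expect_true(rep1$ci_hi[rep1$term == "medi_cal"] >
                rep1$or[rep1$term == "medi_cal"])
  # constant covariates are dropped with warnings, not fit
  w <- capture_warnings(composition_model(r, labels))
  expect_true(any(grepl("constant", w)))
  expect_false(any(grepl("sex_male", rep1$term)))
  expect_error(composition_model(r, rep(1L, nrow(r))), "classes")
})

test_that("composition model finds no structure when covariates are
           independent of membership", {
  set.seed(71)
  n <- 20000L
  r <- toy_records(n, "1994-11-15")
  r$sex_male <- rbinom(n, 1, 0.51)
  r$medi_cal <- rbinom(n, 1, 0.41)
  r$mother_age <- rnorm(n, 28, 6)
  r$father_age <- rnorm(n, 30, 6)
  r$mother_educ <- r$father_educ <- sample(c(10, 13, 17), n, TRUE)
  r$race <- sample(c("non_hispanic_white", "hispanic_white", "black",
                     "asian", "other"), n, TRUE)
  labels <- rbinom(n, 1, 0.1)
  rep0 <- composition_model(r, labels)
  covers <- rep0$ci_lo <= 1 & rep0$ci_hi >= 1
  terms <- rep0$term != "(Intercept)"
  expect_gte(sum(covers[terms]), sum(terms) - 1L)  # ~95% coverage per term
  expect_true(all(rep0$or[terms] > 0.8 & rep0$or[terms] < 1.25))
})

test_that("outcome models recover membership effects and skip degenerate
           outcomes", {
  set.seed(72)
  n <- 40000L
  r <- toy_records(n, "1994-11-15")
  labels <- rbinom(n, 1, 0.12)
  r$gestational_age <- ifelse(rbinom(n, 1, 0.05) == 1L, 34, 40)  # independent
  r$birth_weight <- ifelse(rbinom(n, 1, 0.05) == 1L, 2300, 3400)
  out <- outcome_models(r, labels)
  expect_true(out$preterm$ci_lo[out$preterm$term == "membership"] <= 1)
  expect_true(out$preterm$ci_hi[out$preterm$term == "membership"] >= 1)
  expect_equal(unique(out$preterm$n), n)
  # no variation in the outcome -> skipped with a warning
  r2 <- toy_records(100, "1994-11-15")
  r2$gestational_age <- 40
  r2$birth_weight <- 3400
  w2 <- capture_warnings(out2 <- outcome_models(r2, rbinom(100, 1, 0.5)))
  expect_true(all(grepl("skipped", w2)))
  expect_length(w2, 2L)   # both outcomes degenerate
  expect_null(out2$preterm)
  expect_null(out2$low_birth_weight)
})

test_that("circular day-of-year distance wraps the year and maps Feb 29", {
  expect_equal(circular_day_distance(as.Date("1994-01-01"),
                                     as.Date("1996-12-31")), 1L)
  expect_equal(circular_day_distance(as.Date("1994-11-15"),
                                     as.Date("1995-11-15")), 0L)
  expect_equal(circular_day_distance(as.Date("1994-03-01"),
                                     as.Date("1994-09-01")), 181L)
  expect_equal(circular_day_distance(as.Date("1996-02-29"),
                                     as.Date("1995-02-28")), 0L)
  # post-leap-day dates keep their non-leap day-of-year
  expect_equal(circular_day_distance(as.Date("1996-03-01"),
                                     as.Date("1995-03-01")), 0L)
  set.seed(73)
  d1 <- as.Date("1991-01-01") + sample.int(5000, 100)
  d2 <- as.Date("1991-01-01") + sample.int(5000, 100)
  expect_identical(circular_day_distance(d1, d2),
                   circular_day_distance(d2, d1))
  expect_true(all(circular_day_distance(d1, d2) <= 182L))
  expect_true(all(circular_day_distance(d1, d1) == 0L))
})

test_that("assortative test is exact on constructed tables and monotone in
           the timeframe", {
  # identical within-proportions on both sides -> statistic 0, p = 1
  dates <- as.Date("1994-11-15")
  prs <- data.frame(
    family_id = sprintf("f%03d", 1:40),
    index_case = rep(c(1L, 0L), each = 20),
    index_date = rep(dates, 40),
    sibling_date = rep(c(dates + 5, dates + 100), 20)  # half within t=15
  )
  tab <- assortative_test(prs, timeframes = 15)
  expect_equal(tab$case_pct, 50)
  expect_equal(tab$control_pct, 50)
  expect_equal(tab$chisq, 0)
  expect_equal(tab$p, 1)
  # nesting: within-t percentages nondecreasing in t, on random pairs
  set.seed(74)
  prs2 <- data.frame(
    family_id = sprintf("f%04d", 1:600),
    index_case = rbinom(600, 1, 0.5),
    index_date = as.Date("1994-01-01") + sample.int(3000, 600, TRUE),
    sibling_date = as.Date("1994-01-01") + sample.int(3000, 600, TRUE)
  )
  tab2 <- assortative_test(prs2)
  expect_equal(tab2$timeframe, c(15, 22.5, 30, 45))
  expect_true(all(diff(tab2$case_pct) >= 0))
  expect_true(all(diff(tab2$control_pct) >= 0))
  # one empty side is flagged, not an error
  expect_warning(tab3 <- assortative_test(prs2[prs2$index_case == 1L, ],
                                          timeframes = 15), "undefined")
  expect_true(is.na(tab3$p))
})

test_that("gestational-age profile reproduces closed-form odds ratios and
           the generator's preterm fractions", {
  # identical case/control week distributions -> all ORs 1
  r <- toy_records(330, "1994-06-01",
                   is_case = rep(c(1L, 0L), c(30, 300)))
  r$gestational_age <- c(rep(c(34, 38, 40), each = 10),
                         rep(c(34, 38, 40), each = 100))
  prof <- gestational_age_profile(r)$profile
  expect_true(all(abs(prof$or - 1) < 1e-12))
  # closed-form 2x2 check: (10*195)/(90*5) = 4.33
  r2 <- toy_records(300, "1994-06-01",
                    is_case = rep(c(1L, 0L, 1L, 0L), c(10, 90, 5, 195)))
  r2$gestational_age <- rep(c(30, 30, 40, 40), c(10, 90, 5, 195))
  p2 <- gestational_age_profile(r2)$profile
  expect_equal(p2$or[p2$week == 30], (10 * 195) / (90 * 5), tolerance = 1e-12)
  # generator marginals: 11% of cases, 1.3% of all births preterm
  cfg <- sim_config(start = as.Date("1994-03-01"), end = as.Date("1996-03-01"),
                    daily_conceptions = 1300, baseline_case_prob = 0.05,
                    clusters = NULL, seed = 75)
  coh <- generate_cohort(cfg)
  expect_no_warning(gp <- gestational_age_profile(coh))
  expect_true(all(is.finite(gp$profile$or[gp$profile$or_defined])))
  expect_lt(abs(100 * gp$preterm_case_frac - 11), 0.5)
  expect_lt(abs(100 * gp$preterm_all_frac -
                  (0.05 * 11 + 0.95 * 1.3)), 0.5)
})
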