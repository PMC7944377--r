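test_that("calibration without frailty recovers the analytic band hazard", {
  lt <- flat_lifetable(0.9)
  sched <- calibrate_hazards(lt, c(man = 0, woman = 0), seed = 3)
  # closed form: per-year hazard -ln(0.9)/5
  h_true <- -log(0.9) / 5
  expect_equal(exp(sched$lambda), rep(h_true, 18), tolerance = 0.06)
  # the calibration contract itself: implied band survival within tol
  expect_true(all(abs(exp(-5 * exp(sched$lambda)) - 0.9) <= 5e-3))
})

test_that("frailty calibration is self-consistent and Jensen-shifted", {
  lt <- flat_lifetable(0.5)
  beta <- c(man = log(2), woman = log(2))
  sched_f <- calibrate_hazards(lt, beta, seed = 5)
  sched_0 <- calibrate_hazards(lt, c(man = 0, woman = 0), seed = 5)

  lam_f <- sched_f$lambda[sched_f$band_start == 50 & sched_f$sex == "man"]
  lam_0 <- sched_0$lambda[sched_0$band_start == 50 & sched_0$sex == "man"]

  # Jensen: with frailty, the baseline hazard needed for the same marginal
  # band survival is strictly smaller
  expect_lt(lam_f, lam_0)

  # quadrature oracle over the standard-normal U for the first band
  marg <- integrate(function(u) exp(-5 * exp(lam_f + log(2) * u)) * dnorm(u),
                    -Inf, Inf)$value
  expect_equal(marg, 0.5, tolerance = 2 * 5e-3)

  # independent re-simulation reproduces band survival 0.5
  re <- random_effect_params(1, 0.01, 0.001)
  co <- draw_cohort(100000, 0, re, seed = 77)
  d <- sample_death_age(co, sched_f, seed = 78)
  expect_equal(mean(d >= 55), 0.5, tolerance = 0.012)
})

test_that("death-age sampling matches exponential and piecewise closed forms", {
  re <- random_effect_params(1, 0.01, 0.001)
  co <- draw_cohort(100000, 0.5, re, seed = 41)

  # constant hazard 0.1/yr: median death time 50 + ln(2)/0.1
  d <- sample_death_age(co, flat_schedule(0.1), seed = 42)
  expect_equal(median(d), 50 + log(2) / 0.1, tolerance = 0.15)

  # zero hazard: everyone administratively censored at 95
  d0 <- sample_death_age(co, flat_schedule(1e-12), seed = 43)
  expect_true(all(d0 == 95))

  # two-band schedule: survival at band boundaries matches exp(-int h)
  sched2 <- flat_schedule(c(0.05, 0.15, rep(0.001, 7)))
  d2 <- sample_death_age(co, sched2, seed = 44)
  expect_equal(mean(d2 >= 55), exp(-0.25), tolerance = 0.01)
  expect_equal(mean(d2 >= 60), exp(-0.25 - 0.75), tolerance = 0.01)

  # KS test of death ages within [50, 60) against the analytic conditional
  # piecewise-exponential distribution, alpha = 0.01
  S <- function(t) ifelse(t <= 55, exp(-0.05 * (t - 50)),
                          exp(-0.25) * exp(-0.15 * (t - 55)))
  cdf <- function(t) (1 - S(t)) / (1 - S(60))
  ks <- suppressWarnings(ks.test(d2[d2 < 60], cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("calibrated schedules reproduce lifetable band survival on independent seeds", {
  lt <- synthetic_lifetable()
  tol <- 5e-3
  sched <- calibrate_hazards(lt, c(man = log(2), woman = log(2)),
                             calib_n = 2e5, tol = tol, seed = 51)
  re <- random_effect_params(1, 0.01, 0.001)
  co <- draw_cohort(400000, 0.5, re, seed = 52)
  d <- sample_death_age(co, sched, seed = 53)
  for (sx in c(0L, 1L)) {
    s5 <- lt$s5[lt$sex == if (sx == 1L) "woman" else "man"]
    bands <- seq(50, 90, 5)
    for (bi in seq_along(bands)) {
      alive <- co$sex == sx & d > bands[bi] | (co$sex == sx & bands[bi] == 50)
      surv <- mean(d[alive] >= bands[bi] + 5)
      expect_lt(abs(surv - s5[bi]), 2 * tol)
    }
  }
})

test_that("positive frailty drives survivor mean U down with age", {
  lt <- synthetic_lifetable()
  sched <- calibrate_hazards(lt, c(man = log(2), woman = 0), seed = 61)
  re <- random_effect_params(1, 0.01, 0.001)
  co <- draw_cohort(100000, 0, re, seed = 62) # men only
  d <- sample_death_age(co, sched, seed = 63)
  mean_u <- sapply(c(60, 70, 80, 90), function(a) mean(co$u[d > a]))
  expect_true(all(diff(mean_u) < 0))
  expect_lt(mean_u[4], -1) # strong selection by age 90
})

test_that("marginal mortality is invariant across scenario frailty structures", {
  lt <- synthetic_lifetable()
  re <- random_effect_params(1, 0.01, 0.001)
  cm <- sapply(list(c(man = 0, woman = 0),
                    c(man = log(2), woman = log(2)),
                    c(man = log(3.5), woman = 0)), function(b) {
    sched <- calibrate_hazards(lt, b, seed = 71)
    co <- draw_cohort(100000, 0.51, re, seed = 72)
    d <- sample_death_age(co, sched, seed = 73)
    mean(d < 95)
  })
  expect_lt(max(cm) - min(cm), 0.005)
})

test_that("survival summaries follow the censoring-at-45 convention", {
  # degenerate: all die at exactly 70
  s <- survival_summary(rep(70, 100), rep(0L, 100))
  expect_equal(s$median[s$sex == "man"], 20)
  expect_equal(s$q25[s$sex == "man"], 20)
  expect_equal(s$q75[s$sex == "man"], 20)
  expect_equal(s$cum_mortality_95[s$sex == "man"], 1)
  expect_true(s$median_identified[s$sex == "man"])

  # half die at 60, half censored: type-7 midpoint gives 27.5, flagged as
  # unidentified because cumulative mortality does not exceed 50%
  d <- c(rep(60, 50), rep(95, 50))
  s2 <- survival_summary(d, rep(1L, 100))
  w <- s2[s2$sex == "woman", ]
  expect_equal(w$median, 27.5)
  expect_false(w$median_identified)
  expect_equal(w$q25, 10)
  expect_equal(w$cum_mortality_95, 0.5)
})

test_that("hazard schedules round-trip through CSV", {
  sched <- flat_schedule(0.1, c(man = log(2), woman = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_hazard_schedule(sched, path)
  back <- read_hazard_schedule(path)
  expect_equal(back$lambda, sched$lambda, tolerance = 1e-10)
  expect_equal(back$beta_u, sched$beta_u, tolerance = 1e-12)
})

test_that("calibration rejects invalid inputs", {
  lt <- synthetic_lifetable()
  expect_error(calibrate_hazards(lt, c(man = 0, woman = 0), calib_n = 100),
               "calib_n")
  expect_error(calibrate_hazards(lt, c(man = 0, woman = 0), tol = 0.5),
               "tol")
  expect_error(calibrate_hazards(lt, c(man = 0)), "named")
})
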