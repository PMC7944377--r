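test_that("cognition evaluation matches the quadratic closed form", {
  gc <- growth_params(gamma0 = 0.3, gamma1 = -0.1, gamma2 = -0.001,
                      delta_u = -0.1)
  base <- manual_cohort()
  expect_equal(cognition_at(0, base, gc), 0.3)

  # a 1-SD higher U lowers cognition at age 50 by exactly delta_u
  expect_equal(cognition_at(0, manual_cohort(u = 1), gc) -
                 cognition_at(0, manual_cohort(u = 0), gc), -0.1)

  # direct polynomial evaluation at t = 10 with gamma = (0, -0.1, -0.001)
  gc2 <- growth_params(0, -0.1, -0.001, delta_u = -0.1)
  expect_equal(cognition_at(10, base, gc2), -0.1 * 10 - 0.001 * 100)

  expect_error(cognition_at(46, base, gc), "follow-up")
})

test_that("crossing times match linear and quadratic closed forms", {
  # C(t) = 1 - 0.1 t, cutoff 0: crossing at exactly t = 10
  gc_lin <- growth_params(1, -0.1, 0, delta_u = -0.1)
  expect_equal(crossing_time(manual_cohort(), gc_lin, 0), 10)

  # increasing linear trajectory never crosses
  gc_up <- growth_params(1, 0.05, 0, delta_u = -0.1)
  expect_true(is.na(crossing_time(manual_cohort(), gc_up, 0)))

  # concave quadratic: C(t) = 1 + 0.02 t - 0.004 t^2; the downward root of
  # the quadratic formula
  gc_q <- growth_params(1, 0.02, -0.004, delta_u = -0.1)
  root <- (-0.02 - sqrt(0.02^2 + 4 * 0.004 * 1)) / (2 * -0.004)
  expect_equal(crossing_time(manual_cohort(), gc_q, 0), root,
               tolerance = 1e-10)

  # precondition: must start above the cutoff
  expect_error(crossing_time(manual_cohort(), gc_lin, 2), "above the cutoff")
})

test_that("crossing times agree with a fine grid-search oracle", {
  set.seed(91)
  n <- 1000
  co <- manual_cohort(u = rnorm(n), b0 = rnorm(n, 0, 0.5),
                      b1 = rnorm(n, 0, 0.05), b2 = rnorm(n, 0, 0.004))
  gc <- growth_params(0.5, -0.02, -0.001, delta_u = -0.1)
  theta <- -0.8
  keep <- cognition_at(0, co, gc) > theta
  co <- co[keep, ]
  t_closed <- crossing_time(co, gc, theta)

  # brute-force oracle: evaluate each trajectory on a 0.001-year grid and
  # find the first strictly-below point
  grid <- seq(0, 45, by = 0.001)
  icpt <- gc$gamma0 + gc$delta_u * co$u + co$b0
  lin <- gc$gamma1 + co$b1
  quad <- gc$gamma2 + co$b2
  t_grid <- vapply(seq_len(nrow(co)), function(i) {
    j <- which(icpt[i] + lin[i] * grid + quad[i] * grid^2 < theta)[1]
    if (is.na(j)) NA_real_ else grid[j]
  }, 0)

  expect_identical(is.na(t_closed), is.na(t_grid))
  both <- !is.na(t_closed)
  # the exact root lies within one grid step below the first below-point
  expect_true(all(t_closed[both] <= t_grid[both] + 1e-12))
  expect_true(all(t_closed[both] >= t_grid[both] - 0.001))
})

test_that("shock times follow the piecewise-exponential closed form", {
  gc0 <- 0
  none <- dementia_params(-3, 0, gamma0 = gc0)
  expect_true(all(is.na(sample_shock_time(1000, none, seed = 1))))

  # overwhelming hazard: essentially everyone shocked in the first band
  flood <- dementia_params(-3, 10, gamma0 = gc0)
  ts <- sample_shock_time(10000, flood, seed = 2)
  expect_true(all(!is.na(ts)))
  expect_gt(mean(ts < 5), 0.999)

  # constant 0.02/yr: cumulative incidence by 45 years = 1 - exp(-0.9)
  p2 <- dementia_params(-3, 0.02, gamma0 = gc0)
  ts2 <- sample_shock_time(200000, p2, seed = 3)
  expect_equal(mean(!is.na(ts2)), 1 - exp(-0.02 * 45), tolerance = 0.005)
})

test_that("onset takes the earlier channel and records its cause", {
  # crossing at t = 10, shocks off: onset 60 by crossing
  gc_lin <- growth_params(1, -0.1, 0, delta_u = -0.1)
  p0 <- dementia_params(-1e-9, 0, gamma0 = 1)
  on <- onset_age(manual_cohort(), gc_lin,
                  dementia_params(0, 0, gamma0 = 1), seed = 4)
  expect_equal(on$onset_age, 60)
  expect_identical(on$cause, "crossing")

  # shock flood beats a late crossing
  on2 <- onset_age(manual_cohort(), gc_lin,
                   dementia_params(0, 10, gamma0 = 1), seed = 5)
  expect_lt(on2$onset_age, 60)
  expect_identical(on2$cause, "shock")

  # no crossing, no shock: no onset
  gc_up <- growth_params(1, 0.05, 0, delta_u = -0.1)
  on3 <- onset_age(manual_cohort(), gc_up,
                   dementia_params(0, 0, gamma0 = 1), seed = 6)
  expect_true(is.na(on3$onset_age))
  expect_true(is.na(on3$cause))
})

test_that("the dementia model is structurally free of sex/gender terms", {
  # sharp-null contract: no function in the onset machinery may read sex
  for (f in list(cognition_at, crossing_time, sample_shock_time, onset_age,
                 screen_baseline)) {
    src <- paste(deparse(body(f)), collapse = "\n")
    expect_false(grepl("sex", src, fixed = TRUE))
  }
})

test_that("crossing time is monotone in U (harmful U crosses earlier)", {
  gc <- growth_params(0, -0.02, -0.001, delta_u = -0.1)
  u_grid <- seq(-3, 3, by = 0.25)
  co <- manual_cohort(u = u_grid)
  tc <- crossing_time(co, gc, -2.5)
  tc[is.na(tc)] <- Inf # never crossing sorts after any finite time
  # lower u -> higher cognition -> weakly later crossing
  expect_true(all(diff(tc) <= 0))
})

test_that("baseline screening enforces a dementia-free cohort", {
  re <- normalized_re_params(-0.1)
  gc <- growth_params(0, -0.02, -0.001, delta_u = -0.1)
  co <- draw_cohort(50000, 0.5, re, seed = 7)

  # far-below cutoff: untouched
  s <- screen_baseline(co, gc, re, -10, seed = 8)
  expect_identical(attr(s, "redraws"), 0L)
  expect_equal(s$b0, co$b0)

  # cutoff at the 1st percentile of C(0) ~ N(0, 1): ~1% redraw rate
  s2 <- screen_baseline(co, gc, re, qnorm(0.01), seed = 9)
  rate <- attr(s2, "redraws") / nrow(co)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.02)
  expect_true(all(cognition_at(0, s2, gc) > qnorm(0.01)))

  # cutoff at or above the marginal mean is invalid
  expect_error(screen_baseline(co, gc, re, 0.5, seed = 10), "theta")
})

test_that("dementia calibration recovers self-generated band rates", {
  lt <- synthetic_lifetable()
  sched <- calibrate_hazards(lt, c(man = 0, woman = 0), seed = 101)
  gc <- growth_params()
  re <- normalized_re_params(-0.1)

  # synthetic truth: a cutoff and constant shock hazard generate a target
  # rate table by direct simulation
  theta_true <- -3.6
  shock_true <- rep(0.004, 9)
  p_true <- dementia_params(theta_true, shock_true)
  co <- draw_cohort(200000, 0, re, seed = 102)
  co <- screen_baseline(co, gc, re, theta_true, seed = 103)
  d <- sample_death_age(co, sched, seed = 104)
  on <- onset_age(co, gc, p_true, seed = 105)
  onset_t <- on$onset_age - 50
  death_t <- pmin(d, 95) - 50
  case <- !is.na(onset_t) & on$onset_age < d & on$onset_age < 95
  exit_t <- pmin(ifelse(is.na(onset_t), Inf, onset_t), death_t)
  tal <- cbind(iteration = 1L,
               selsurv:::.tally_bands(co$sex, exit_t, onset_t, case))
  truth_rates <- incidence_table(tal)
  targets <- data.frame(band_start = truth_rates$band_start,
                        rate_per_1000py = truth_rates$rate_per_1000py)

  fit <- suppressWarnings(
    calibrate_dementia(targets, gc, re, sched, tol_rel = 0.2, seed = 106))
  # every band reproduced within the stated relative tolerance
  expect_true(all(abs(fit$report$rel_error) <= 0.2))
  # recovered cutoff in the neighbourhood of the truth
  expect_lt(abs(fit$dementia$theta - theta_true), 0.5)
})

test_that("dementia calibration responds monotonically to the targets", {
  lt <- synthetic_lifetable()
  sched <- calibrate_hazards(lt, c(man = 0, woman = 0), seed = 111)
  gc <- growth_params()
  re <- normalized_re_params(-0.1)
  tr <- synthetic_target_rates()

  fit1 <- calibrate_dementia(tr, gc, re, sched, seed = 112)
  tr2 <- tr
  tr2$rate_per_1000py <- 2 * tr2$rate_per_1000py
  fit2 <- suppressWarnings(
    calibrate_dementia(tr2, gc, re, sched, seed = 112))
  # doubling all targets raises (makes less negative) the cutoff
  expect_gt(fit2$dementia$theta, fit1$dementia$theta)

  # all-zero targets are infeasible
  tr0 <- tr
  tr0$rate_per_1000py <- 0
  expect_error(calibrate_dementia(tr0, gc, re, sched, seed = 113),
               "all zero")
})
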