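#' Fixed effects of the cognitive growth curve
#'
#' Cognition is modelled on a standardised scale (SD of cognition at age 50
#' equals 1) as a person-specific quadratic in `t`, years since age 50:
#' \deqn{C(t) = (\gamma_0 + \delta_u u + b_0) + (\gamma_1 + b_1) t +
#'   (\gamma_2 + b_2) t^2.}
#' `delta_u` is the effect of a 1-SD increase in the selection
#' characteristic U on cognition at age 50: -0.1 in moderate scenarios,
#' -0.5 in large ones (harmful).
#'
#' @param gamma0 intercept (mean cognition at age 50; default 0).
#' @param gamma1 mean linear slope per year (negative: decline).
#' @param gamma2 mean quadratic coefficient per year^2 (negative:
#'   accelerating decline).
#' @param delta_u effect of U on cognition at age 50, in SD units.
#' @return an object of class `growth_params`.
#' @export
growth_params <- function(gamma0 = 0, gamma1 = -0.0187, gamma2 = -0.00119,
                          delta_u = -0.1) {
  stopifnot(is.finite(c(gamma0, gamma1, gamma2, delta_u)))
  if (abs(delta_u) >= 1)
    stop("|delta_u| must be below 1 so the baseline SD can normalise to 1",
         call. = FALSE)
  structure(list(gamma0 = gamma0, gamma1 = gamma1, gamma2 = gamma2,
                 delta_u = delta_u), class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf(
    "Growth curve: gamma=(%g, %g, %g), delta_u=%g\n",
    x$gamma0, x$gamma1, x$gamma2, x$delta_u))
  invisible(x)
}

#' Random-effect parameters normalised to unit baseline cognition SD
#'
#' The marginal variance of cognition at age 50 is
#' `delta_u^2 + sigma0^2`; fixing it at 1 keeps `delta_u` interpretable in
#' SD units, so `sigma0 = sqrt(1 - delta_u^2)`.
#'
#' @param delta_u effect of U on cognition at age 50.
#' @param sigma1 SD of the random linear slope (per year).
#' @param sigma2 SD of the random quadratic slope (per year^2).
#' @param rho01 intercept-slope correlation.
#' @return a [random_effect_params()] object.
#' @export
normalized_re_params <- function(delta_u = -0.1, sigma1 = 0.0104,
                                 sigma2 = 0.00026, rho01 = 0.745) {
  random_effect_params(sqrt(1 - delta_u^2), sigma1, sigma2, rho01)
}

#' Dementia onset parameters
#'
#' @param theta age-constant dementia cutoff on the cognition scale; onset
#'   by the trajectory channel occurs when cognition first falls below
#'   `theta`. Must lie below the marginal mean cognition at age 50 so a
#'   dementia-free baseline is enforceable.
#' @param shock_hazard per-band per-year hazard of a dementia-triggering
#'   shock (e.g. a serious stroke); a named or plain numeric vector of
#'   length 9 for bands 50,55,...,90, or a scalar recycled to all bands.
#' @param gamma0 marginal mean cognition at age 50 used for the cutoff
#'   validity check.
#' @return an object of class `dementia_params`.
#' @export
dementia_params <- function(theta, shock_hazard = 0, gamma0 = 0) {
  stopifnot(is.finite(theta))
  if (theta >= gamma0)
    stop("theta must lie below the marginal mean cognition at age 50",
         call. = FALSE)
  if (length(shock_hazard) == 1L) shock_hazard <- rep(shock_hazard, 9L)
  if (length(shock_hazard) != 9L || any(shock_hazard < 0) ||
      any(!is.finite(shock_hazard)))
    stop("shock_hazard must be 9 nonnegative per-band hazards",
         call. = FALSE)
  structure(list(theta = theta,
                 shock_hazard = stats::setNames(shock_hazard,
                                                as.character(.bands))),
            class = "dementia_params")
}

#' @export
print.dementia_params <- function(x, ...) {
  cat(sprintf("Dementia cutoff theta = %.4f\n", x$theta))
  cat("Per-band shock hazards (/yr):\n")
  print(round(x$shock_hazard, 5))
  invisible(x)
}

#' Evaluate person-specific cognition at time t
#'
#' @param t years since age 50, scalar or one value per person, in
#'   `[0, 45]`.
#' @param cohort a [draw_cohort()] cohort (one or more rows).
#' @param gc a [growth_params()] object.
#' @return numeric vector of cognition values.
#' @export
cognition_at <- function(t, cohort, gc) {
  stopifnot(inherits(gc, "growth_params"))
  if (any(t < 0 | t > 45))
    stop("t must lie within the follow-up window [0, 45]", call. = FALSE)
  (gc$gamma0 + gc$delta_u * cohort$u + cohort$b0) +
    (gc$gamma1 + cohort$b1) * t +
    (gc$gamma2 + cohort$b2) * t^2
}

#' Earliest downward crossing of the dementia cutoff
#'
#' Solves, per person, for the smallest `t` in `(0, 45]` at which the
#' quadratic trajectory falls below `theta`, using closed-form root logic
#' (with the linear and constant degenerate cases handled exactly). A
#' tangency that touches the cutoff without going below it is not a
#' crossing. All persons must be above the cutoff at `t = 0`.
#'
#' @param cohort a cohort (one or more rows).
#' @param gc a [growth_params()] object.
#' @param theta the dementia cutoff.
#' @return numeric vector: crossing time in years since 50, or `NA` when
#'   the trajectory never falls below `theta` within follow-up.
#' @export
crossing_time <- function(cohort, gc, theta) {
  a <- gc$gamma2 + cohort$b2
  b <- gc$gamma1 + cohort$b1
  cc <- (gc$gamma0 + gc$delta_u * cohort$u + cohort$b0) - theta
  if (any(cc <= 0))
    stop("crossing_time requires cognition above the cutoff at t = 0 ",
         "(screen the cohort first)", call. = FALSE)
  n <- length(cc)
  t_cross <- rep(NA_real_, n)

  lin <- abs(a) < 1e-14
  # linear: c + b t = 0, crossing only if slope negative
  li <- which(lin & b < 0)
  t_cross[li] <- -cc[li] / b[li]

  qi <- which(!lin)
  if (length(qi)) {
    aq <- a[qi]; bq <- b[qi]; cq <- cc[qi]
    disc <- bq^2 - 4 * aq * cq
    has <- disc > 0 # tangency (disc == 0) never goes strictly below
    root <- rep(NA_real_, length(qi))
    sq <- sqrt(pmax(disc, 0))
    # concave (a < 0): C - theta > 0 at t=0 lies between the roots; the
    # later root is the downward crossing.
    dn <- has & aq < 0
    root[dn] <- (-bq[dn] - sq[dn]) / (2 * aq[dn])
    # convex (a > 0): C - theta < 0 strictly between the roots; the first
    # root is the crossing if it is ahead of t=0.
    up <- has & aq > 0
    r1 <- (-bq[up] - sq[up]) / (2 * aq[up]) # smaller root when a > 0
    r1[r1 <= 0] <- NA_real_
    root[up] <- r1
    t_cross[qi] <- root
  }
  t_cross[!is.na(t_cross) & (t_cross <= 0 | t_cross > 45)] <- NA_real_
  t_cross
}

#' Sample dementia-triggering shock times
#'
#' Shocks follow a piecewise-exponential process over the nine age bands
#' with per-band hazards `params$shock_hazard`, independent of U, sex and
#' cognition — the shock channel carries no sex/gender or selection signal,
#' preserving the sharp null.
#'
#' @param n number of persons.
#' @param params a [dementia_params()] object.
#' @param seed integer seed.
#' @return numeric vector: shock time in years since 50, or `NA` if no
#'   shock occurs before age 95.
#' @export
sample_shock_time <- function(n, params, seed) {
  stopifnot(inherits(params, "dementia_params"))
  E <- with_seed(seed, stats::rexp(n))
  t_shock <- rep(NA_real_, n)
  cumH <- 0
  done <- rep(FALSE, n)
  for (bi in seq_along(.bands)) {
    h <- params$shock_hazard[bi]
    if (h > 0) {
      H_next <- cumH + 5 * h
      hit <- !done & (E <= H_next)
      t_shock[hit] <- (.bands[bi] - 50) + (E[hit] - cumH) / h
      done <- done | hit
      cumH <- H_next
    }
  }
  t_shock
}

#' Dementia onset age by the earlier of crossing and shock
#'
#' Onset is `50 + min(crossing time, shock time)`; a tie resolves to the
#' crossing channel. Onset is absorbing: later cognition values never
#' rescind it.
#'
#' @param cohort a screened cohort.
#' @param gc growth parameters.
#' @param params dementia parameters.
#' @param seed integer seed for the shock channel.
#' @return a `data.frame` with columns `onset_age` (`NA` if none) and
#'   `cause` (`"crossing"`, `"shock"`, or `NA`).
#' @export
onset_age <- function(cohort, gc, params, seed) {
  t_cross <- crossing_time(cohort, gc, params$theta)
  t_shock <- sample_shock_time(nrow(cohort), params, seed)
  t_on <- pmin(t_cross, t_shock, na.rm = TRUE)
  cause <- ifelse(is.na(t_on), NA_character_,
                  ifelse(!is.na(t_cross) & t_cross <= t_on, "crossing",
                         "shock"))
  data.frame(onset_age = 50 + t_on, cause = cause,
             stringsAsFactors = FALSE)
}

#' Enforce a dementia-free baseline by rejection sampling of b0
#'
#' Individuals whose cognition at age 50 is at or below the cutoff have
#' their random intercept `b0` redrawn (from its marginal normal) until the
#' whole cohort starts above the threshold. The number of redraws is
#' recorded in the `redraws` attribute. A rejection rate above 50% signals
#' a cutoff too close to the mean and raises an error.
#'
#' @param cohort a cohort.
#' @param gc growth parameters.
#' @param re_params the [random_effect_params()] used to draw the cohort
#'   (supplies the marginal SD of `b0`).
#' @param theta the dementia cutoff.
#' @param seed integer seed.
#' @return the cohort with all members above the cutoff at baseline.
#' @export
screen_baseline <- function(cohort, gc, re_params, theta, seed) {
  stopifnot(inherits(cohort, "cohort"), inherits(gc, "growth_params"),
            inherits(re_params, "re_params"))
  if (theta >= gc$gamma0)
    stop("theta must lie below the marginal mean cognition at age 50",
         call. = FALSE)
  c0 <- cognition_at(0, cohort, gc)
  bad <- which(c0 <= theta)
  if (length(bad) / nrow(cohort) > 0.5)
    stop(sprintf(
      "baseline rejection rate %.1f%% exceeds 50%%: theta too high",
      100 * length(bad) / nrow(cohort)), call. = FALSE)
  redraws <- 0L
  if (length(bad)) {
    with_seed(seed, {
      while (length(bad)) {
        redraws <- redraws + length(bad)
        cohort$b0[bad] <- re_params$sigma0 * stats::rnorm(length(bad))
        c0 <- cognition_at(0, cohort[bad, ], gc)
        bad <- bad[c0 <= theta]
      }
    })
  }
  attr(cohort, "redraws") <- redraws
  cohort
}

# time alive within each band, given total alive-time `end` (years since 50):
# overlap of [0, end) with [t0, t0+5)
.band_overlap <- function(end, t0) pmax(0, pmin(end, t0 + 5) - t0)

#' Calibrate the dementia cutoff and shock hazards to men's target rates
#'
#' Two-stage search against a table of men's age-band dementia incidence
#' rates (the calibration reference; women's incidence is emergent under
#' the sharp null). Stage (i) bisects the cutoff `theta` so that men's
#' simulated cumulative dementia incidence by age 95 (deaths competing)
#' matches the cumulative incidence implied by the target hazards. Stage
#' (ii) walks the bands in age order and sets a nonnegative per-band shock
#' hazard to close any remaining gap where crossing-driven incidence
#' undershoots the target band rate; bands that already overshoot get shock
#' hazard 0 and a flag in the report. Published incidence rates are a guide
#' rather than a strict criterion, hence the relative tolerance.
#'
#' @param target_rates `data.frame` with columns `band_start` and
#'   `rate_per_1000py`: men's incidence per 1000 person-years per band.
#' @param gc growth parameters (fixed effects and `delta_u`; `theta` is the
#'   free parameter being calibrated).
#' @param re_params random-effect parameters.
#' @param schedule calibrated [calibrate_hazards()] mortality schedule (the
#'   men's hazards are used).
#' @param tol_rel relative tolerance per band (at least 0.1).
#' @param calib_n size of the male calibration sample.
#' @param seed integer seed.
#' @return a list with elements `growth` (the input `gc`), `dementia` (a
#'   [dementia_params()]), and `report` (a `data.frame` with columns
#'   `band_start`, `target`, `achieved`, `rel_error`, `shock_hazard`,
#'   `flagged`).
#' @export
calibrate_dementia <- function(target_rates, gc, re_params, schedule,
                               tol_rel = 0.2, calib_n = 1e5, seed = 1L) {
  stopifnot(inherits(gc, "growth_params"), inherits(re_params, "re_params"),
            inherits(schedule, "hazard_schedule"))
  if (!all(c("band_start", "rate_per_1000py") %in% names(target_rates)))
    stop("target_rates needs columns band_start, rate_per_1000py",
         call. = FALSE)
  tr <- target_rates[order(target_rates$band_start), ]
  if (!identical(as.integer(tr$band_start), .bands))
    stop("target_rates must cover bands 50,55,...,90", call. = FALSE)
  rate <- tr$rate_per_1000py
  if (any(rate < 0)) stop("target rates must be nonnegative", call. = FALSE)
  if (all(rate == 0))
    stop("target rates are all zero: cutoff calibration is infeasible",
         call. = FALSE)
  if (is.unsorted(rate)) # guide data should rise with age
    warning("target rates are not monotone nondecreasing in age",
            call. = FALSE)
  if (tol_rel < 0.1)
    stop("tol_rel must be at least 0.1", call. = FALSE)

  # male calibration sample with death ages under the men's schedule
  men <- draw_cohort(calib_n, p_female = 0,
                     re_params = re_params,
                     seed = seed_stream(seed, "dementia-calib-cohort"))
  death <- sample_death_age(men, schedule,
                            seed_stream(seed, "dementia-calib-death"))
  alive_t <- pmin(death, 95) - 50 # years alive in follow-up

  # target-implied cumulative incidence by 95 with death competing:
  # P(onset before min(death, 95)) = 1 - exp(-sum_b h_b * time alive in b)
  h_target <- rate / 1000
  Hsum <- numeric(calib_n)
  for (bi in seq_along(.bands))
    Hsum <- Hsum + h_target[bi] * .band_overlap(alive_t, .bands[bi] - 50)
  target_ci <- mean(1 - exp(-Hsum))

  # stage (i): bisection on theta; crossing fraction is evaluated on the
  # sample conditioned on a dementia-free baseline. The initial aim sits
  # at the lower edge of the tolerance interval, (1 - tol_rel) * implied
  # cumulative incidence, because the shock channel of stage (ii) can only
  # add incidence on top of the crossing channel. When the crossing
  # channel still overshoots some band (its natural age profile is
  # steeper than the targets), the aim is lowered and both stages re-run.
  c0 <- cognition_at(0, men, gc)
  frac_cross <- function(theta) {
    keep <- c0 > theta
    tc <- crossing_time(men[keep, ], gc, theta)
    mean(!is.na(tc) & tc < alive_t[keep])
  }
  solve_theta <- function(aim) {
    lo <- gc$gamma0 - 15
    hi <- gc$gamma0 - 1e-6
    if (frac_cross(lo) > aim)
      stop("cutoff calibration cannot bracket the target from below",
           call. = FALSE)
    for (step in seq_len(80)) {
      mid <- (lo + hi) / 2
      f <- frac_cross(mid)
      if (abs(f - aim) <= 0.005 * aim) return(mid)
      if (f < aim) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }

  # independent exponential draws per band: the onset sampler is memoryless
  # across bands, so each band's shock channel needs its own draw
  E_shock <- with_seed(seed_stream(seed, "dementia-calib-shock"),
                       matrix(stats::rexp(calib_n * length(.bands)),
                              calib_n, length(.bands)))

  # stage (ii): screened sample, then sequential per-band shock hazards
  fill_shocks <- function(theta) {
    men_s <- screen_baseline(men, gc, re_params, theta,
                             seed_stream(seed, "dementia-calib-screen"))
    tc <- crossing_time(men_s, gc, theta)
    shock <- numeric(length(.bands))
    achieved <- numeric(length(.bands))
    at_risk <- rep(TRUE, calib_n)
    for (bi in seq_along(.bands)) {
      t0 <- .bands[bi] - 50
      idx <- which(at_risk & alive_t > t0)
      end <- pmin(alive_t[idx], t0 + 5)
      cross_in <- !is.na(tc[idx]) & tc[idx] >= t0 & tc[idx] < end
      # band rate (/yr) for a given shock hazard s, using fixed exponential
      # draws so the bisection sees a monotone deterministic function
      band_rate <- function(s) {
        t_sh <- if (s > 0) t0 + E_shock[idx, bi] / s
                else rep(Inf, length(idx))
        t_on <- pmin(ifelse(cross_in, tc[idx], Inf), t_sh)
        case <- t_on < end
        py <- pmin(t_on, end) - t0
        sum(case) / sum(py)
      }
      target_b <- h_target[bi]
      r0 <- band_rate(0)
      s_b <- 0
      if (target_b > 0 && r0 < target_b) {
        s_lo <- 0; s_hi <- 2
        for (step in seq_len(100)) {
          s_mid <- (s_lo + s_hi) / 2
          r <- band_rate(s_mid)
          if (abs(r - target_b) <= 0.005 * target_b) break
          if (r < target_b) s_lo <- s_mid else s_hi <- s_mid
        }
        s_b <- s_mid
      }
      shock[bi] <- s_b
      achieved[bi] <- band_rate(s_b)
      # remove this band's onsets from the at-risk pool
      t_sh <- if (s_b > 0) t0 + E_shock[idx, bi] / s_b
              else rep(Inf, length(idx))
      t_on <- pmin(ifelse(cross_in, tc[idx], Inf), t_sh)
      at_risk[idx[t_on < end]] <- FALSE
    }
    rel_err <- ifelse(h_target > 0, achieved / h_target - 1,
                      ifelse(achieved > 0, Inf, 0))
    list(theta = theta, shock = shock, achieved = achieved,
         rel_err = rel_err)
  }

  aim <- (1 - tol_rel) * target_ci
  best <- NULL
  for (attempt in seq_len(6)) {
    fit <- fill_shocks(solve_theta(aim))
    if (is.null(best) || max(abs(fit$rel_err)) < max(abs(best$rel_err)))
      best <- fit
    if (all(fit$rel_err <= tol_rel)) break
    aim <- aim * 0.85 # crossing channel too steep for these targets
  }
  theta <- best$theta
  rel_err <- best$rel_err
  flagged <- abs(rel_err) > tol_rel
  if (any(abs(rel_err) > 2 * tol_rel))
    stop(sprintf(
      "dementia calibration failed: band(s) %s off target by more than %.0f%%",
      paste(.bands[abs(rel_err) > 2 * tol_rel], collapse = ", "),
      200 * tol_rel), call. = FALSE)
  if (any(flagged))
    warning("dementia calibration overshoots target in band(s): ",
            paste(.bands[flagged], collapse = ", "), call. = FALSE)
  report <- data.frame(band_start = .bands, target = rate,
                       achieved = 1000 * best$achieved, rel_error = rel_err,
                       shock_hazard = best$shock, flagged = flagged)
  list(growth = gc,
       dementia = dementia_params(theta, best$shock, gamma0 = gc$gamma0),
       report = report)
}
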