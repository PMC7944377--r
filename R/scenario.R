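#' Configure a selective-survival causal scenario
#'
#' Three causal structures are supported, all generated under the sharp
#' null of no sex/gender effect on dementia:
#' \itemize{
#'   \item `no_selection`: U influences cognition only, never survival.
#'   \item `homogeneous`: U raises the mortality hazard equally for men
#'     and women.
#'   \item `heterogeneous`: U raises the mortality hazard for men only
#'     (U-by-sex interaction).
#' }
#' Effect sizes follow the published pairing: moderate = hazard ratio 2.0
#' per SD of U and -0.1 SD cognition per SD of U; large = hazard ratio 3.5
#' and -0.5 SD. The cognition effect `delta_u` applies in every scenario.
#'
#' @param scenario one of `"no_selection"`, `"homogeneous"`,
#'   `"heterogeneous"`.
#' @param effect_size `"moderate"` or `"large"`.
#' @param n cohort size per iteration.
#' @param p_female proportion of women.
#' @param n_iterations Monte-Carlo iterations (fresh cohort each).
#' @param master_seed master seed; every substream derives from it.
#' @param lifetable a [lifetable()]; default [synthetic_lifetable()].
#' @param target_rates men's incidence-rate targets; default
#'   [synthetic_target_rates()].
#' @param gamma1,gamma2 growth-curve fixed slopes (see [growth_params()]).
#' @param sigma1,sigma2,rho01 random-effect parameters (see
#'   [normalized_re_params()]).
#' @param calib_n calibration sample size.
#' @param tol lifetable calibration tolerance (band survival probability).
#' @param tol_rel dementia calibration relative tolerance.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("no_selection", "homogeneous",
                                         "heterogeneous"),
                            effect_size = c("moderate", "large"),
                            n = 100000, p_female = 0.51,
                            n_iterations = 1000, master_seed = 1L,
                            lifetable = synthetic_lifetable(),
                            target_rates = synthetic_target_rates(),
                            gamma1 = -0.0187, gamma2 = -0.00119,
                            sigma1 = 0.0104, sigma2 = 0.00026, rho01 = 0.745,
                            calib_n = 1e5, tol = 5e-3, tol_rel = 0.2) {
  scenario <- match.arg(scenario)
  effect_size <- match.arg(effect_size)
  beta <- if (effect_size == "moderate") log(2.0) else log(3.5)
  delta_u <- if (effect_size == "moderate") -0.1 else -0.5
  beta_u <- switch(scenario,
    no_selection  = c(man = 0, woman = 0),
    homogeneous   = c(man = beta, woman = beta),
    heterogeneous = c(man = beta, woman = 0))
  structure(list(
    scenario = scenario, effect_size = effect_size,
    beta_u = beta_u, delta_u = delta_u,
    n = as.integer(n), p_female = p_female,
    n_iterations = as.integer(n_iterations),
    master_seed = as.integer(master_seed),
    lifetable = lifetable, target_rates = target_rates,
    gamma1 = gamma1, gamma2 = gamma2,
    sigma1 = sigma1, sigma2 = sigma2, rho01 = rho01,
    calib_n = calib_n, tol = tol, tol_rel = tol_rel,
    follow_up = c(50, 95)), class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario '%s' (%s effects): beta_u(man)=%.3f beta_u(woman)=%.3f delta_u=%.2f\n",
    x$scenario, x$effect_size, x$beta_u[["man"]], x$beta_u[["woman"]],
    x$delta_u))
  cat(sprintf("n=%d, p_female=%.2f, iterations=%d, master_seed=%d\n",
              x$n, x$p_female, x$n_iterations, x$master_seed))
  invisible(x)
}

#' Growth and random-effect parameters implied by a configuration
#' @param config a [scenario_config()].
#' @return list with `gc` and `re_params`.
#' @keywords internal
.config_params <- function(config) {
  list(gc = growth_params(gamma0 = 0, gamma1 = config$gamma1,
                          gamma2 = config$gamma2, delta_u = config$delta_u),
       re_params = normalized_re_params(config$delta_u, config$sigma1,
                                        config$sigma2, config$rho01))
}

#' Run both calibrations for a scenario
#'
#' Calibrates the mortality schedule under the scenario's `beta_u`
#' structure (so lifetable survival holds marginally in every scenario),
#' then calibrates the dementia cutoff and shock hazards against the men's
#' target rates under that schedule. Calibration draws its own seed
#' substreams, so changing `n_iterations` never perturbs it.
#'
#' @param config a [scenario_config()].
#' @return list with `schedule`, `growth`, `re_params`, `dementia`,
#'   `report`.
#' @export
calibrate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- .config_params(config)
  sched <- calibrate_hazards(config$lifetable, config$beta_u,
                             calib_n = config$calib_n, tol = config$tol,
                             seed = seed_stream(config$master_seed,
                                                "calibration-mortality"))
  dem <- calibrate_dementia(config$target_rates, p$gc, p$re_params, sched,
                            tol_rel = config$tol_rel,
                            calib_n = config$calib_n,
                            seed = seed_stream(config$master_seed,
                                               "calibration-dementia"))
  list(schedule = sched, growth = p$gc, re_params = p$re_params,
       dementia = dem$dementia, report = dem$report)
}

# tally person-years and incident cases into 5-year bands.
# exit_t / onset_t are years since 50; case marks countable incident onsets.
.tally_bands <- function(sex, exit_t, onset_t, case) {
  out <- vector("list", length(.bands))
  for (bi in seq_along(.bands)) {
    t0 <- .bands[bi] - 50
    py <- .band_overlap(exit_t, t0)
    in_band <- case & !is.na(onset_t) & onset_t >= t0 & onset_t < t0 + 5
    out[[bi]] <- data.frame(
      band_start = .bands[bi],
      sex = c("man", "woman"),
      cases = c(sum(in_band & sex == 0L), sum(in_band & sex == 1L)),
      person_years = c(sum(py[sex == 0L]), sum(py[sex == 1L])))
  }
  do.call(rbind, out)
}

#' Simulate one cohort iteration and tally cases and person-years
#'
#' Draws a fresh cohort, enforces the dementia-free baseline, samples death
#' ages and dementia onsets, and tallies incident cases and person-years
#' at risk into 5-year bands. A person's at-risk time ends at
#' `min(onset, death, 95)` (exact continuous time, half-open bands); an
#' incident case is credited to the band containing the onset age only
#' when onset precedes both death and age 95. Death ages are drawn
#' independently of onset (dementia does not feed back into mortality).
#'
#' @param config a [scenario_config()].
#' @param calib a [calibrate_scenario()] result.
#' @param iteration_seed integer seed for this iteration.
#' @param keep_detail if `TRUE`, also return the cohort and event times.
#' @return a list with `tally` (band x sex cases/person-years),
#'   `survival` (per-sex [survival_summary()]), and, when requested,
#'   `detail` (cohort with death/onset columns).
#' @export
run_iteration <- function(config, calib, iteration_seed,
                          keep_detail = FALSE) {
  co <- draw_cohort(config$n, config$p_female, calib$re_params,
                    seed = seed_stream(iteration_seed, "cohort"))
  co <- screen_baseline(co, calib$growth, calib$re_params,
                        calib$dementia$theta,
                        seed = seed_stream(iteration_seed, "screen"))
  death <- sample_death_age(co, calib$schedule,
                            seed = seed_stream(iteration_seed, "mortality"))
  on <- onset_age(co, calib$growth, calib$dementia,
                  seed = seed_stream(iteration_seed, "shocks"))
  onset_t <- on$onset_age - 50
  death_t <- pmin(death, 95) - 50
  case <- !is.na(onset_t) & (on$onset_age < death) & (on$onset_age < 95)
  exit_t <- pmin(ifelse(is.na(onset_t), Inf, onset_t), death_t)
  tally <- .tally_bands(co$sex, exit_t, onset_t, case)
  out <- list(tally = tally, survival = survival_summary(death, co$sex))
  if (keep_detail) {
    co$death_age <- death
    co$onset_age <- on$onset_age
    co$onset_cause <- on$cause
    out$detail <- co
  }
  out
}

#' Run a full scenario: calibrate once, then iterate
#'
#' Executes both calibrations, then simulates `n_iterations` independent
#' cohorts (fresh sample generation per iteration, seeds split from the
#' master seed). Survivor-U summaries at ages 50, 55, ..., 95 are recorded
#' for the first iteration's cohort, matching the published practice of
#' displaying U distributions for one simulated cohort.
#'
#' @param config a [scenario_config()].
#' @param progress print a dot every 25 iterations.
#' @return an object of class `scenario_result`: list with `config`,
#'   `calib` (schedule, growth, dementia, calibration report), `tallies`
#'   (all iterations, long format), `survival` (per-iteration per-sex),
#'   and `u_summary` (first-iteration survivor-U by age and sex).
#' @export
run_scenario <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  calib <- calibrate_scenario(config)
  tallies <- vector("list", config$n_iterations)
  surv <- vector("list", config$n_iterations)
  u_sum <- NULL
  for (it in seq_len(config$n_iterations)) {
    it_seed <- seed_stream(config$master_seed, "iteration", it)
    res <- run_iteration(config, calib, it_seed, keep_detail = it == 1L)
    tallies[[it]] <- cbind(iteration = it, res$tally)
    surv[[it]] <- cbind(iteration = it, res$survival)
    if (it == 1L) {
      ages <- seq(50, 95, 5)
      u_sum <- do.call(rbind, lapply(ages, function(a) {
        # alive at 95 means surviving the whole follow-up (death_age == 95
        # flags administrative censoring)
        alive <- if (a >= 95) res$detail$death_age >= 95
                 else res$detail$death_age > a
        cbind(age = a, u_summary_by_sex(res$detail, alive_mask = alive))
      }))
    }
    if (progress && it %% 25L == 0L) cat(".")
  }
  if (progress) cat("\n")
  structure(list(config = config, calib = calib,
                 tallies = do.call(rbind, tallies),
                 survival = do.call(rbind, surv),
                 u_summary = u_sum),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$config)
  cat(sprintf("%d iterations tallied over %d bands\n",
              x$config$n_iterations, length(.bands)))
  invisible(x)
}

#' Write scenario outputs to a directory
#'
#' Emits `tallies.csv`, `survival_summary.csv`, `u_summary.csv`,
#' `hazard_schedule.csv`, `calibration_report.csv` and a `manifest.json`
#' run manifest (configuration echo, seeds, package version).
#'
#' @param result a [run_scenario()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario_result <- function(result, dir) {
  stopifnot(inherits(result, "scenario_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$tallies, file.path(dir, "tallies.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$survival, file.path(dir, "survival_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(result$u_summary, file.path(dir, "u_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  write_hazard_schedule(result$calib$schedule,
                        file.path(dir, "hazard_schedule.csv"))
  utils::write.csv(result$calib$report,
                   file.path(dir, "calibration_report.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- result$config
  manifest <- list(
    scenario = cfg$scenario, effect_size = cfg$effect_size,
    n = cfg$n, p_female = cfg$p_female, n_iterations = cfg$n_iterations,
    master_seed = cfg$master_seed,
    beta_u = as.list(cfg$beta_u), delta_u = cfg$delta_u,
    gamma = c(0, cfg$gamma1, cfg$gamma2),
    sigma = c(sqrt(1 - cfg$delta_u^2), cfg$sigma1, cfg$sigma2),
    rho01 = cfg$rho01, theta = result$calib$dementia$theta,
    config_checksum = config_checksum(cfg),
    package_version = as.character(utils::packageVersion("selsurv")))
  writeLines(.to_json(manifest), file.path(dir, "manifest.json"))
  invisible(dir)
}

# minimal JSON writer for the run manifest (scalars, vectors, named lists)
.to_json <- function(x) {
  esc <- function(s) gsub('"', '\\\\"', s)
  render <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)))
        paste0("{", paste0('"', esc(names(v)), '": ',
                           vapply(v, render, ""), collapse = ", "), "}")
      else paste0("[", paste0(vapply(v, render, ""), collapse = ", "), "]")
    } else if (length(v) > 1) {
      paste0("[", paste0(vapply(v, function(e) render(e), ""),
                         collapse = ", "), "]")
    } else if (is.character(v)) paste0('"', esc(v), '"')
    else if (is.na(v)) "null"
    else format(v, digits = 15)
  }
  render(x)
}

#' Deterministic checksum of a configuration
#'
#' A small FNV-style hash of the deparsed configuration (lifetable and
#' target tables included), used in run manifests so byte-identical runs
#' can be recognised.
#'
#' @param config a [scenario_config()].
#' @return character hex digest.
#' @export
config_checksum <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "\n")
  h <- 216613626
  m <- 2147483647 # keep the rolling hash in 32-bit integer range
  for (ch in utf8ToInt(s)) h <- ((h * 16777) %% m + ch) %% m
  sprintf("%08x", as.integer(h))
}

#' Write a scenario configuration to a YAML file
#'
#' The lifetable and target-rate tables are written as CSV files next to
#' the YAML file and referenced by path, so the configuration is fully
#' self-contained and round-trips through [read_scenario_config()].
#'
#' @param config a [scenario_config()].
#' @param path output YAML file; companion CSVs are placed alongside it.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  dir <- dirname(path)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lt_path <- file.path(dir, "lifetable.csv")
  tr_path <- file.path(dir, "target_rates.csv")
  write_lifetable(config$lifetable, lt_path)
  utils::write.csv(config$target_rates, tr_path, row.names = FALSE,
                   quote = FALSE)
  y <- list(scenario = config$scenario, effect_size = config$effect_size,
            n = config$n, p_female = config$p_female,
            n_iterations = config$n_iterations,
            master_seed = config$master_seed,
            lifetable = lt_path, target_rates = tr_path,
            gamma1 = config$gamma1, gamma2 = config$gamma2,
            sigma1 = config$sigma1, sigma2 = config$sigma2,
            rho01 = config$rho01, calib_n = config$calib_n,
            tol = config$tol, tol_rel = config$tol_rel)
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a scenario configuration from a YAML file
#'
#' Recognised keys: `scenario`, `effect_size`, `n`, `p_female`,
#' `n_iterations`, `master_seed`, `lifetable` (CSV path), `target_rates`
#' (CSV path), and any of the numeric tuning parameters of
#' [scenario_config()].
#'
#' @param path YAML file.
#' @return a [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[names(y) %in% c("scenario", "effect_size", "n", "p_female",
                            "n_iterations", "master_seed", "gamma1",
                            "gamma2", "sigma1", "sigma2", "rho01",
                            "calib_n", "tol", "tol_rel")]
  if (!is.null(y$lifetable)) args$lifetable <- load_lifetable(y$lifetable)
  if (!is.null(y$target_rates))
    args$target_rates <- utils::read.csv(y$target_rates)
  do.call(scenario_config, args)
}
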