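#' Women-vs-men incidence rate ratio for one band tally
#'
#' The IRR is `(cases_w / py_w) / (cases_m / py_m)`. It is undefined
#' (returned as `NA` with a reason attribute) when either sex has zero
#' cases or zero person-years; such iterations are excluded from
#' aggregation (no continuity correction, which would bias the mean-log
#' estimator).
#'
#' @param tally a two-row `data.frame` (one band, both sexes) with columns
#'   `sex`, `cases`, `person_years`.
#' @return the IRR, or `NA` with attribute `reason`.
#' @export
band_irr <- function(tally) {
  m <- tally[tally$sex == "man", ]
  w <- tally[tally$sex == "woman", ]
  if (nrow(m) != 1L || nrow(w) != 1L)
    stop("tally must contain exactly one row per sex", call. = FALSE)
  if (m$person_years <= 0 || w$person_years <= 0)
    return(structure(NA_real_, reason = "zero person-years"))
  if (m$cases == 0L || w$cases == 0L)
    return(structure(NA_real_, reason = "zero cases"))
  (w$cases / w$person_years) / (m$cases / m$person_years)
}

# per-iteration, per-band IRRs from a long tallies table
.irr_by_iteration <- function(tallies) {
  wide <- merge(
    tallies[tallies$sex == "man",
            c("iteration", "band_start", "cases", "person_years")],
    tallies[tallies$sex == "woman",
            c("iteration", "band_start", "cases", "person_years")],
    by = c("iteration", "band_start"), suffixes = c("_m", "_w"))
  ok <- wide$person_years_m > 0 & wide$person_years_w > 0 &
    wide$cases_m > 0 & wide$cases_w > 0
  wide$irr <- ifelse(ok,
    (wide$cases_w / wide$person_years_w) /
      (wide$cases_m / wide$person_years_m), NA_real_)
  wide
}

#' Aggregate per-iteration IRRs for one band
#'
#' The point estimate is the exponentiated mean of the per-iteration log
#' IRRs (the published estimator); the default 95% interval is the
#' empirical 2.5th/97.5th percentile of the per-iteration IRR
#' distribution, with a normal-theory interval on the log scale available
#' as an option. Undefined IRRs are dropped and counted.
#'
#' @param irrs numeric vector of per-iteration IRRs (may contain `NA`).
#' @param ci `"percentile"` (default) or `"normal"`.
#' @return a one-row `data.frame`: `point`, `ci_low`, `ci_high`, `n_used`,
#'   `n_excluded`.
#' @export
aggregate_irr <- function(irrs, ci = c("percentile", "normal")) {
  ci <- match.arg(ci)
  x <- irrs[!is.na(irrs)]
  if (length(x) == 0L)
    stop("no defined IRRs to aggregate", call. = FALSE)
  lx <- log(x)
  point <- exp(mean(lx))
  if (ci == "percentile") {
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
  } else {
    se <- if (length(x) > 1L) stats::sd(lx) else 0
    q <- exp(mean(lx) + c(-1, 1) * 1.96 * se)
  }
  data.frame(point = point, ci_low = q[1], ci_high = q[2],
             n_used = length(x), n_excluded = sum(is.na(irrs)))
}

#' Per-band IRR summary across iterations
#'
#' @param tallies long tallies table from [run_scenario()] (columns
#'   `iteration`, `band_start`, `sex`, `cases`, `person_years`).
#' @param ci interval type, see [aggregate_irr()].
#' @return a `data.frame` with one row per band: `band_start`, `point`,
#'   `ci_low`, `ci_high`, `n_used`, `n_excluded`.
#' @export
irr_summary <- function(tallies, ci = "percentile") {
  wide <- .irr_by_iteration(tallies)
  out <- do.call(rbind, lapply(split(wide, wide$band_start), function(g) {
    if (all(is.na(g$irr)))
      return(data.frame(band_start = g$band_start[1], point = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_used = 0L, n_excluded = sum(is.na(g$irr))))
    cbind(band_start = g$band_start[1], aggregate_irr(g$irr, ci))
  }))
  rownames(out) <- NULL
  out[order(out$band_start), ]
}

#' Bias report against the sharp-null truth
#'
#' Under the sharp null the true women-vs-men IRR is 1.00 in every band,
#' so any departure of the aggregated estimate from 1 is selective
#' survival bias. Bands whose interval excludes 1 are flagged.
#'
#' @param summaries an [irr_summary()] table.
#' @param truth the true IRR (1.0 under the sharp null).
#' @return the table with added `bias` (= point - truth) and `flagged`
#'   columns.
#' @export
bias_report <- function(summaries, truth = 1.0) {
  summaries$bias <- summaries$point - truth
  summaries$flagged <- !is.na(summaries$ci_low) &
    (summaries$ci_low > truth | summaries$ci_high < truth)
  summaries
}

#' Mean age-band incidence rates per 1000 person-years
#'
#' Calibration diagnostic: per band and sex, `1000 * cases / person_years`
#' within each iteration, averaged over iterations with nonzero
#' person-years.
#'
#' @param tallies long tallies table.
#' @return `data.frame` with `band_start`, `sex`, `rate_per_1000py`.
#' @export
incidence_table <- function(tallies) {
  t2 <- tallies[tallies$person_years > 0, ]
  rate <- 1000 * t2$cases / t2$person_years
  agg <- stats::aggregate(rate,
                          by = list(band_start = t2$band_start,
                                    sex = t2$sex),
                          FUN = mean)
  names(agg)[3] <- "rate_per_1000py"
  agg[order(agg$band_start, agg$sex), ]
}

#' Forest plot of aggregated IRRs (published-figure style)
#'
#' @param summaries an [irr_summary()] table (optionally with a `label`
#'   column distinguishing scenarios).
#' @param min_band lowest band to display (default 80, the published
#'   figure's range).
#' @return a ggplot object.
#' @export
plot_irr_forest <- function(summaries, min_band = 80) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- summaries[summaries$band_start >= min_band, ]
  d$band <- sprintf("%d-%d", d$band_start, d$band_start + 4)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = band, y = point)) +
    ggplot2::geom_hline(yintercept = 1, linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = ci_low,
                                          ymax = ci_high),
                             position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(x = "Age band (years)",
                  y = "IRR, women vs men (exp mean log)") +
    ggplot2::theme_minimal()
  if ("label" %in% names(d))
    p <- p + ggplot2::aes(colour = label)
  p
}

#' Box-plot-style summary of survivor U by age and sex
#'
#' @param u_summary the `u_summary` table of a [run_scenario()] result.
#' @return a ggplot object.
#' @export
plot_u_by_age <- function(u_summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- u_summary[u_summary$n > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = factor(age), colour = sex)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_pointrange(ggplot2::aes(y = q50, ymin = q25,
                                          ymax = q75),
                             position = ggplot2::position_dodge(0.5)) +
    ggplot2::labs(x = "Age (years)", y = "Survivor U (median, IQR)") +
    ggplot2::theme_minimal()
}
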