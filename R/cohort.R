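#' Random-effect parameters for the cognitive growth curve
#'
#' Specifies the person-level deviations of the quadratic cognition
#' trajectory: random intercept `b0`, random linear slope `b1` and random
#' quadratic slope `b2`, with correlation `rho01` between intercept and
#' linear slope. The quadratic slope is independent of the other two: the
#' causal diagram links baseline cognitive level with rate of change, and no
#' correlation involving the quadratic term is part of the model.
#'
#' @param sigma0,sigma1,sigma2 nonnegative SDs of `b0`, `b1`, `b2`.
#'   Units: `sigma0` is in SD-of-cognition-at-age-50 units; `sigma1` in
#'   cognition units per year; `sigma2` per year squared.
#' @param rho01 correlation between `b0` and `b1`, in `[-1, 1]`.
#' @return an object of class `re_params`.
#' @examples
#' random_effect_params(0.99, 0.03, 0.002, rho01 = 0.3)
#' @export
random_effect_params <- function(sigma0, sigma1, sigma2, rho01 = 0) {
  stopifnot(length(sigma0) == 1, length(sigma1) == 1, length(sigma2) == 1,
            length(rho01) == 1)
  if (any(c(sigma0, sigma1, sigma2) < 0) ||
      !all(is.finite(c(sigma0, sigma1, sigma2, rho01))))
    stop("random-effect SDs must be finite and nonnegative", call. = FALSE)
  if (abs(rho01) > 1)
    stop("rho01 must lie in [-1, 1]", call. = FALSE)
  # 3x3 covariance: [s0^2, r*s0*s1, 0; r*s0*s1, s1^2, 0; 0, 0, s2^2]
  cov <- diag(c(sigma0, sigma1, sigma2)^2)
  cov[1, 2] <- cov[2, 1] <- rho01 * sigma0 * sigma1
  if (min(eigen(cov, symmetric = TRUE, only.values = TRUE)$values) < -1e-12)
    stop("implied random-effect covariance is not positive semidefinite",
         call. = FALSE)
  structure(list(sigma0 = sigma0, sigma1 = sigma1, sigma2 = sigma2,
                 rho01 = rho01, cov = cov),
            class = "re_params")
}

#' @export
print.re_params <- function(x, ...) {
  cat(sprintf(
    "Random-effect parameters: sigma0=%.4g sigma1=%.4g sigma2=%.4g rho01=%.3g\n",
    x$sigma0, x$sigma1, x$sigma2, x$rho01))
  invisible(x)
}

#' Draw a baseline cohort of 50-year-olds
#'
#' Generates `n` individuals aged exactly 50, dementia-free screening aside
#' (see [screen_baseline()]). Sex/gender is assigned by a deterministic
#' count split — exactly `round(n * p_female)` women after a seeded shuffle —
#' so that a 51% female cohort of 100 000 contains exactly 51 000 women. The
#' selection characteristic `u` is standard normal and independent of sex at
#' baseline; random effects `(b0, b1)` are drawn from a bivariate normal
#' with correlation `rho01`, and `b2` independently.
#'
#' @param n cohort size (positive integer).
#' @param p_female proportion of women in `[0, 1]`.
#' @param re_params a [random_effect_params()] object.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return a `data.frame` of class `cohort` with columns
#'   `id`, `sex` (woman = 1, man = 0), `u`, `b0`, `b1`, `b2`.
#' @examples
#' co <- draw_cohort(1000, 0.51, random_effect_params(1, 0.03, 0.002, 0.3),
#'                   seed = 1)
#' sum(co$sex) # exactly 510
#' @export
draw_cohort <- function(n, p_female = 0.51, re_params, seed) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a positive integer", call. = FALSE)
  if (p_female < 0 || p_female > 1)
    stop("p_female must lie in [0, 1]", call. = FALSE)
  if (!inherits(re_params, "re_params"))
    stop("re_params must be created with random_effect_params()",
         call. = FALSE)
  n <- as.integer(n)
  n_women <- as.integer(round(n * p_female))
  with_seed(seed, {
    sex <- sample(c(rep(1L, n_women), rep(0L, n - n_women)))
    u <- stats::rnorm(n)
    z0 <- stats::rnorm(n)
    z1 <- stats::rnorm(n)
    b0 <- re_params$sigma0 * z0
    b1 <- re_params$sigma1 * (re_params$rho01 * z0 +
                                sqrt(1 - re_params$rho01^2) * z1)
    b2 <- re_params$sigma2 * stats::rnorm(n)
    structure(
      data.frame(id = seq_len(n), sex = sex, u = u, b0 = b0, b1 = b1,
                 b2 = b2),
      class = c("cohort", "data.frame"))
  })
}

#' Summarise the selection characteristic U by sex among survivors
#'
#' Returns the per-sex mean, SD and quartiles of `u` restricted to
#' individuals flagged alive, mirroring box plots of U by age and
#' sex/gender. A sex with no survivors gets an empty (all-`NA`) row and a
#' warning rather than an error; a singleton group reports `sd = NA`.
#'
#' @param cohort a [draw_cohort()] cohort.
#' @param alive_mask logical vector of length `nrow(cohort)`; defaults to
#'   everyone alive (baseline).
#' @return a `data.frame` with columns `sex` (`"man"`, `"woman"`), `n`,
#'   `mean`, `sd`, `q25`, `q50`, `q75`.
#' @export
u_summary_by_sex <- function(cohort, alive_mask = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(alive_mask)) alive_mask <- rep(TRUE, nrow(cohort))
  if (length(alive_mask) != nrow(cohort))
    stop("alive_mask must have one entry per cohort member", call. = FALSE)
  if (!any(alive_mask))
    warning("no survivors in mask; returning empty summary", call. = FALSE)
  rows <- lapply(c(man = 0L, woman = 1L), function(s) {
    uu <- cohort$u[alive_mask & cohort$sex == s]
    if (length(uu) == 0L)
      return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                        q25 = NA_real_, q50 = NA_real_, q75 = NA_real_))
    q <- stats::quantile(uu, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(uu), mean = mean(uu),
               sd = if (length(uu) > 1L) stats::sd(uu) else NA_real_,
               q25 = q[1], q50 = q[2], q75 = q[3])
  })
  out <- cbind(sex = c("man", "woman"), do.call(rbind, rows))
  rownames(out) <- NULL
  if (any(out$n == 0L) && any(alive_mask))
    warning("one sex has no survivors in mask; row flagged empty",
            call. = FALSE)
  out
}

#' Write a cohort to CSV
#'
#' @param cohort a cohort.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(cohort[c("id", "sex", "u", "b0", "b1", "b2")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
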