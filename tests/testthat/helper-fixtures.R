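# shared helpers for building small in-code fixtures

# flat lifetable: the same band survival everywhere, both sexes
flat_lifetable <- function(s5) {
  bands <- seq(50, 90, 5)
  lifetable(rep(bands, 2), rep(c("man", "woman"), each = length(bands)),
            rep(s5, 2 * length(bands)))
}

# hazard schedule with given per-year hazards (recycled across bands), no
# frailty unless beta_u supplied
flat_schedule <- function(hazard, beta_u = c(man = 0, woman = 0)) {
  bands <- seq(50, 90, 5)
  lam <- log(rep(hazard, length.out = length(bands)))
  sched <- rbind(
    data.frame(band_start = bands, sex = "man", lambda = lam,
               beta_u = beta_u[["man"]]),
    data.frame(band_start = bands, sex = "woman", lambda = lam,
               beta_u = beta_u[["woman"]]))
  sched <- sched[order(sched$band_start, sched$sex), ]
  rownames(sched) <- NULL
  class(sched) <- c("hazard_schedule", "data.frame")
  sched
}

# cohort with explicitly chosen columns (for closed-form trajectory tests)
manual_cohort <- function(u = 0, b0 = 0, b1 = 0, b2 = 0) {
  n <- max(length(u), length(b0), length(b1), length(b2))
  structure(
    data.frame(id = seq_len(n), sex = rep(0L, n), u = rep_len(u, n),
               b0 = rep_len(b0, n), b1 = rep_len(b1, n),
               b2 = rep_len(b2, n)),
    class = c("cohort", "data.frame"))
}

# long tallies table from explicit per-iteration counts
manual_tallies <- function(band_start, cases_m, py_m, cases_w, py_w,
                           iteration = seq_along(cases_m)) {
  do.call(rbind, lapply(seq_along(iteration), function(i) {
    data.frame(iteration = iteration[i], band_start = band_start,
               sex = c("man", "woman"), cases = c(cases_m[i], cases_w[i]),
               person_years = c(py_m[i], py_w[i]))
  }))
}
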