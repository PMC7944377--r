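#' Derive a named random-number substream seed
#'
#' All stochastic routines in selsurv draw their seeds from a single master
#' seed through named substreams, so that (a) two runs with the same master
#' seed are bit-identical and (b) changing, say, the number of Monte-Carlo
#' iterations never perturbs the calibration draws. The derivation is a
#' simple multiplicative hash over the stream name combined with the master
#' seed and an integer index; all arithmetic stays below 2^53 so the result
#' is exact in double precision and fits a 32-bit integer seed.
#'
#' @param master integer master seed.
#' @param name character stream name, e.g. `"calibration-mortality"`.
#' @param index nonnegative integer sub-index (e.g. iteration number).
#' @return a positive integer seed suitable for [set.seed()].
#' @export
seed_stream <- function(master, name, index = 0L) {
  stopifnot(length(master) == 1L, is.finite(master),
            is.character(name), length(name) == 1L,
            length(index) == 1L, index >= 0)
  m <- 2147483629 # largest prime below 2^31
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% m
  s <- abs(as.double(master)) %% m
  out <- (s * 48271 + h * 1103 + as.double(index) * 7919 + 12345) %% m
  as.integer(out + 1)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state, so
#' seeded package internals never disturb the user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}
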