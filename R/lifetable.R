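.bands <- seq(50L, 90L, 5L)
.sexes <- c("man", "woman")

#' Construct and validate a lifetable of 5-year band survival
#'
#' A lifetable here is a long table of conditional survival probabilities
#' `s5`: the probability of surviving a 5-year age band given alive at its
#' start, by sex, for the nine half-open bands `[50,55), ..., [90,95)`.
#'
#' @param band_start integer vector of band starts (years).
#' @param sex character vector, `"man"` or `"woman"`.
#' @param s5 conditional band survival probabilities in `(0, 1]`.
#' @return a `data.frame` of class `lifetable`, sorted by band then sex.
#' @export
lifetable <- function(band_start, sex, s5) {
  lt <- data.frame(band_start = as.integer(band_start),
                   sex = as.character(sex), s5 = as.numeric(s5))
  need <- expand.grid(band_start = .bands, sex = .sexes,
                      stringsAsFactors = FALSE)
  key <- paste(lt$band_start, lt$sex)
  need_key <- paste(need$band_start, need$sex)
  missing <- setdiff(need_key, key)
  if (length(missing))
    stop("lifetable is missing band,sex rows: ",
         paste(sub(" ", ",", missing), collapse = "; "), call. = FALSE)
  extra <- setdiff(key, need_key)
  if (length(extra) || anyDuplicated(key))
    stop("lifetable has unexpected or duplicated rows", call. = FALSE)
  if (any(!is.finite(lt$s5)) || any(lt$s5 <= 0) || any(lt$s5 > 1))
    stop("s5 values must lie in (0, 1]", call. = FALSE)
  lt <- lt[order(lt$band_start, lt$sex), ]
  rownames(lt) <- NULL
  class(lt) <- c("lifetable", "data.frame")
  lt
}

#' Load a lifetable from CSV
#'
#' Expects a header `band_start,sex,s5` with sex coded `man`/`woman`, bands
#' 50 to 90 by 5, both sexes present for every band.
#'
#' @param path CSV file path.
#' @return a validated [lifetable()].
#' @export
load_lifetable <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("band_start", "sex", "s5") %in% names(x)))
    stop("lifetable file must have columns band_start,sex,s5", call. = FALSE)
  lifetable(x$band_start, x$sex, x$s5)
}

#' Write a lifetable to CSV
#' @param lt a lifetable.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_lifetable <- function(lt, path) {
  stopifnot(inherits(lt, "lifetable"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# look up s5 for one sex, ordered by band
.lt_sex <- function(lt, sex) {
  x <- lt[lt$sex == sex, ]
  x[order(x$band_start), "s5"]
}
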