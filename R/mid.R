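#' Construct a mass-isotopologue distribution (MID)
#'
#' A MID records the fractional abundances of the mass shifts m0..mn of a
#' metabolite pool, where mi carries i heavy (13C) atoms. Fractions must be
#' nonnegative and are renormalised to sum exactly to 1.
#'
#' @param fractions Numeric vector of length `n_carbons + 1`, nonnegative,
#'   summing to 1 within `1e-6` before exact renormalisation.
#' @param metabolite_id Short metabolite name, e.g. `"Ru5P"`.
#' @param n_carbons Number of carbon atoms; defaults to
#'   `length(fractions) - 1`.
#' @return An object of class `"mid"`: a list with elements `metabolite_id`,
#'   `n_carbons` and `fractions` (named `m0`, `m1`, ...).
#' @examples
#' mid(c(0.5, 0, 0.5), "G6P", n_carbons = 2)
#' @export
mid <- function(fractions, metabolite_id = NA_character_,
                n_carbons = length(fractions) - 1L) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1L)
  n_carbons <- as.integer(n_carbons)
  if (length(fractions) != n_carbons + 1L) {
    stop("`fractions` must have length n_carbons + 1 (", n_carbons + 1L,
         "), got ", length(fractions), call. = FALSE)
  }
  if (any(fractions < 0)) {
    stop("MID fractions must be nonnegative (metabolite ",
         metabolite_id, ")", call. = FALSE)
  }
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6) {
    stop("MID fractions must sum to 1 (got ", format(s),
         "); use normalize_to_mid() for raw intensities", call. = FALSE)
  }
  fractions <- fractions / s
  names(fractions) <- paste0("m", 0:n_carbons)
  structure(
    list(metabolite_id = metabolite_id, n_carbons = n_carbons,
         fractions = fractions),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, digits = 4, ...) {
  cat("MID", if (!is.na(x$metabolite_id)) paste0("(", x$metabolite_id, ")"),
      "-", x$n_carbons, "carbons\n")
  print(round(x$fractions, digits))
  invisible(x)
}

#' Normalise raw isotopologue intensities to a MID
#'
#' Divides nonnegative ion-count intensities by their sum so the result is a
#' valid fractional distribution. Idempotent on already-normalised input.
#'
#' @param raw_intensities Nonnegative numeric vector (per mass shift m0..mn)
#'   with at least one strictly positive entry.
#' @param metabolite_id Optional metabolite name, carried through and used in
#'   error messages.
#' @return A [mid()] object.
#' @examples
#' normalize_to_mid(c(2, 1, 1))   # -> 0.5, 0.25, 0.25
#' @export
normalize_to_mid <- function(raw_intensities, metabolite_id = NA_character_) {
  stopifnot(is.numeric(raw_intensities))
  key <- if (is.na(metabolite_id)) "sample" else metabolite_id
  if (any(raw_intensities < 0)) {
    stop("negative intensity in ", key, call. = FALSE)
  }
  s <- sum(raw_intensities)
  if (s <= 0) {
    stop("all-zero intensity vector for ", key, call. = FALSE)
  }
  mid(raw_intensities / s, metabolite_id = metabolite_id)
}

#' Mean (fractional) 13C enrichment of a MID
#'
#' The average number of labelled carbons per molecule divided by the number
#' of carbon positions: `sum(i * fraction_i) / n_carbons`, in `[0, 1]`. This
#' is the summary used to check that treatment groups reached the same
#' isotopic steady-state enrichment.
#'
#' @param x A [mid()] object, or a bare fraction vector.
#' @return A single number in `[0, 1]`.
#' @examples
#' mean_enrichment(mid(c(0.5, 0, 0.5), n_carbons = 2))  # 0.5
#' @export
mean_enrichment <- function(x) {
  if (inherits(x, "mid")) {
    f <- x$fractions
    n <- x$n_carbons
  } else {
    f <- x / sum(x)
    n <- length(x) - 1L
  }
  if (n == 0L) return(0)
  sum((seq_along(f) - 1) * f) / n
}
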