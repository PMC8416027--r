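#' Natural-abundance correction matrix for 13C
#'
#' Builds the lower-triangular matrix that maps a theoretical (tracer-only)
#' MID to the MID measured in the presence of naturally occurring 13C.
#' Entry `(i, j)` (0-based mass shifts) is the probability that a molecule
#' with `j` tracer labels acquires `i - j` extra mass units from natural
#' abundance among its `n - j` unlabelled carbons:
#' `choose(n - j, i - j) * p^(i - j) * (1 - p)^(n - i)`.
#' Each column is a binomial probability vector summing to 1.
#'
#' @param n_carbons Number of carbon atoms (>= 1).
#' @param p13C Natural 13C abundance fraction, `0 <= p13C < 0.5`
#'   (default 0.0107, the standard terrestrial value).
#' @return An object of class `"correction_matrix"`: a list with
#'   `n_carbons`, `p13C` and the `(n+1) x (n+1)` matrix `entries`.
#' @examples
#' natural_abundance_matrix(2, 0.0107)
#' @export
natural_abundance_matrix <- function(n_carbons, p13C = 0.0107) {
  n_carbons <- as.integer(n_carbons)
  if (n_carbons < 1L) stop("n_carbons must be >= 1", call. = FALSE)
  if (!is.numeric(p13C) || p13C < 0 || p13C >= 0.5) {
    stop("p13C must satisfy 0 <= p13C < 0.5, got ", format(p13C),
         call. = FALSE)
  }
  n <- n_carbons
  m <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    k <- 0:(n - j)                       # extra mass from natural abundance
    m[j + 1L + k, j + 1L] <- stats::dbinom(k, size = n - j, prob = p13C)
  }
  dimnames(m) <- list(paste0("m", 0:n), paste0("m", 0:n))
  structure(list(n_carbons = n, p13C = p13C, entries = m),
            class = "correction_matrix")
}

#' Forward-apply a correction matrix to a theoretical MID
#'
#' Computes the MID that would be measured for a given tracer-only MID under
#' natural 13C abundance: `entries %*% fractions`.
#'
#' @param x A [mid()] object (the theoretical MID).
#' @param matrix A [natural_abundance_matrix()] object of matching size.
#' @return A [mid()] object (the predicted measured MID).
#' @export
apply_correction_matrix <- function(x, matrix) {
  stopifnot(inherits(x, "mid"), inherits(matrix, "correction_matrix"))
  if (x$n_carbons != matrix$n_carbons) {
    stop("matrix n_carbons (", matrix$n_carbons,
         ") does not match metabolite (", x$n_carbons, ")", call. = FALSE)
  }
  mid(as.numeric(matrix$entries %*% x$fractions),
      metabolite_id = x$metabolite_id, n_carbons = x$n_carbons)
}

#' Correct a measured MID for natural 13C abundance
#'
#' Recovers the tracer-only MID from a measured one by solving
#' `entries %*% x = measured` as a nonnegatively constrained least-squares
#' problem (rather than direct inversion, so measurement noise cannot
#' produce negative fractions), clamping fractions below `1e-12` to zero
#' and renormalising. With `p13C = 0` the output equals the input.
#'
#' @param measured A [mid()] object as measured.
#' @param matrix A [natural_abundance_matrix()] object of matching size.
#' @return A [mid()] object, the corrected distribution.
#' @examples
#' cm <- natural_abundance_matrix(2, 0.0107)
#' obs <- apply_correction_matrix(mid(c(0.5, 0, 0.5)), cm)
#' correct_mid(obs, cm)   # recovers c(0.5, 0, 0.5)
#' @export
correct_mid <- function(measured, matrix) {
  stopifnot(inherits(measured, "mid"), inherits(matrix, "correction_matrix"))
  if (measured$n_carbons != matrix$n_carbons) {
    stop("matrix n_carbons (", matrix$n_carbons,
         ") does not match metabolite (", measured$n_carbons, ")",
         call. = FALSE)
  }
  a <- matrix$entries
  # cannot be singular for p13C < 0.5 (unit lower-triangular up to scaling),
  # but guard against a degenerate hand-built matrix
  if (abs(prod(diag(a))) < 1e-12) {
    stop("correction matrix is singular or ill-conditioned", call. = FALSE)
  }
  x <- pracma::lsqnonneg(a, as.numeric(measured$fractions))$x
  x[x < 1e-12] <- 0
  if (sum(x) <= 0) {
    stop("correction produced an all-zero MID for ",
         measured$metabolite_id, call. = FALSE)
  }
  mid(x / sum(x), metabolite_id = measured$metabolite_id,
      n_carbons = measured$n_carbons)
}
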