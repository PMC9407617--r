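# Wavelet leaders. The leader at scale j, position k is the supremum of
# coefficient magnitudes over every dyadic interval at scales <= j whose
# time support lies inside the 3-neighborhood of the interval (j, k):
# lambda(j, k-1) U lambda(j, k) U lambda(j, k+1). Leaders, not raw
# coefficients, make negative-moment structure functions well-behaved and
# tie the formalism to pointwise Holder regularity.

#' Compute wavelet leaders
#'
#' Positions at scale `j` are identified with dyadic intervals
#' \eqn{\lambda(j,k) = [(k-1)2^j, k 2^j)} (1-based `k`). The nested
#' supremum is computed by a pairwise max-pool recursion over scales
#' (\eqn{O(n)} total), followed by a 3-neighborhood max at each scale.
#' Positions whose neighborhood extends past the available coefficients
#' are dropped, as are trailing positions at scale `j` whose finer-scale
#' children are incomplete.
#'
#' @param coeffs an `mf_wavelet_coeffs` from [mf_dwt()], or a plain list of
#'   per-scale coefficient vectors (finest first).
#' @return an object of class `mf_leaders`: list with `leaders` (per-scale
#'   vectors), `n_j` (counts after boundary trimming).
#' @export
#' @examples
#' d <- list(c(1, 3, 2, 5, 1, 1, 1, 1), c(4, 1, 1, 1))
#' compute_leaders(d)$leaders
compute_leaders <- function(coeffs) {
  details <- if (inherits(coeffs, "mf_wavelet_coeffs")) coeffs$details
             else coeffs
  stopifnot(is.list(details), length(details) >= 1)
  J <- length(details)
  if (any(lengths(details) == 0)) {
    stop("empty coefficient array at scale ",
         which(lengths(details) == 0)[1])
  }

  # nested sup over all dyadic intervals inside lambda(j, k)
  M <- vector("list", J)
  M[[1]] <- abs(details[[1]])
  if (J > 1) {
    for (j in 2:J) {
      prev <- M[[j - 1]]
      n_here <- min(length(details[[j]]), length(prev) %/% 2)
      if (n_here < 1) {
        stop("no complete coefficient nesting at scale ", j,
             " (series too short)")
      }
      k <- seq_len(n_here)
      M[[j]] <- pmax(abs(details[[j]])[k], prev[2 * k - 1], prev[2 * k])
    }
  }

  leaders <- vector("list", J)
  for (j in seq_len(J)) {
    m <- M[[j]]
    n <- length(m)
    if (n < 3) {
      stop("fewer than 3 nested positions at scale ", j,
           "; no leaders survive boundary trimming")
    }
    leaders[[j]] <- pmax(m[1:(n - 2)], m[2:(n - 1)], m[3:n])
  }
  structure(list(leaders = leaders, n_j = lengths(leaders)),
            class = "mf_leaders")
}

#' @export
print.mf_leaders <- function(x, ...) {
  cat(sprintf("<mf_leaders> %d scales, n_j = %s\n",
              length(x$leaders), paste(x$n_j, collapse = ", ")))
  invisible(x)
}
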