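# Real-cepstrum front-end. The real cepstrum is the inverse DFT of the
# log-magnitude spectrum; low quefrencies carry the spectral envelope, and
# harmonic structure shows up as peaks at multiples of the pitch period.

#' Real cepstrum of a signal
#'
#' Computes \eqn{\hat r(n) = \mathrm{IDFT}[\ln |S(k)|]} where \eqn{S} is the
#' DFT of the (zero-padded) signal. The magnitude spectrum is floored at
#' `max|S| * 10^(floor_db/20)` so the log is always finite; the inverse
#' transform of a real, even log-magnitude is real and even-symmetric, and
#' the imaginary residue (checked to be below `1e-8` relative) is discarded.
#'
#' The quefrency-0 coefficient equals the mean log-magnitude, so scaling the
#' signal by `a > 0` shifts only that coefficient, by `log(a)` (see
#' [cepstrum_scaling_check()]).
#'
#' @param x an [signal()] object or numeric vector.
#' @param n_fft transform length; even, at least the signal length (the
#'   signal is zero-padded up). Default: next power of two.
#' @param floor_db relative magnitude floor in dB (< 0).
#' @return an object of class `mf_cepstrum` with fields `coefficients`
#'   (length `n_fft`), `n_fft`, `sample_rate`, `id`, `group`, `episode`.
#' @export
#' @examples
#' # an echo at lag 100 puts a cepstral peak at quefrency 100
#' s <- c(1, rep(0, 99), 0.5, rep(0, 411))
#' cep <- real_cepstrum(s, n_fft = 1024)
#' which.max(cep$coefficients[2:512]) # 100
real_cepstrum <- function(x, n_fft = NULL, floor_db = -120) {
  samples <- as_samples(x)
  if (anyNA(samples) || !all(is.finite(samples))) {
    stop("signal contains NA or non-finite values")
  }
  if (all(samples == 0)) {
    stop("all-zero signal: log-magnitude spectrum undefined")
  }
  if (!(floor_db < 0)) stop("floor_db must be negative")
  n <- length(samples)
  n_fft <- as.integer(n_fft %||% next_pow2(n))
  if (n_fft < n) stop("n_fft (", n_fft, ") must be >= signal length (", n, ")")
  if (n_fft %% 2 != 0) stop("n_fft must be even")

  S <- fft(c(samples, rep(0, n_fft - n)))
  mag <- Mod(S)
  mag <- pmax(mag, max(mag) * 10^(floor_db / 20))
  cep <- fft(log(mag), inverse = TRUE) / n_fft
  im_res <- max(abs(Im(cep))) / max(abs(Re(cep)), 1e-300)
  if (im_res > 1e-8) {
    stop("unexpected imaginary residue in real cepstrum: ", format(im_res))
  }
  meta <- if (inherits(x, "mf_signal")) x else
    list(sample_rate = NA_real_, id = "series",
         group = NA_character_, episode = NA_character_)
  structure(
    list(coefficients = Re(cep), n_fft = n_fft, n_keep = n_fft,
         floor_db = floor_db, sample_rate = meta$sample_rate,
         id = meta$id, group = meta$group, episode = meta$episode),
    class = "mf_cepstrum"
  )
}

#' @export
print.mf_cepstrum <- function(x, ...) {
  cat(sprintf("<mf_cepstrum '%s'> %d coefficients (n_fft=%d)\n",
              x$id, length(x$coefficients), x$n_fft))
  invisible(x)
}

#' Truncate a cepstrum to its low-quefrency prefix
#'
#' Keeps quefrencies `0 .. n_keep - 1`, the envelope region the multifractal
#' stage consumes. The default of 1000 points is the representation length
#' used throughout the package.
#'
#' @param cep an `mf_cepstrum`.
#' @param n_keep retained length; `2 <= n_keep <= n_fft/2` (beyond the
#'   half-length the even symmetry only repeats information). Truncating
#'   an already-truncated cepstrum to the same length is a no-op.
#' @return an `mf_cepstrum` of length `n_keep`; metadata preserved.
#' @export
truncate_cepstrum <- function(cep, n_keep = 1000) {
  stopifnot(inherits(cep, "mf_cepstrum"))
  n <- length(cep$coefficients)
  n_keep <- as.integer(n_keep)
  if (n_keep < 2 || n_keep > min(n, cep$n_fft / 2)) {
    stop("n_keep must be in [2, ", floor(min(n, cep$n_fft / 2)),
         "]; got ", n_keep)
  }
  cep$coefficients <- cep$coefficients[seq_len(n_keep)]
  cep$n_keep <- n_keep
  cep
}

#' Verify the amplitude-scaling law of the real cepstrum
#'
#' For `a > 0`, the cepstrum of `a * s` equals the cepstrum of `s` except at
#' quefrency 0, which shifts by `log(a)`. This holds exactly (up to floating
#' point) because the log-magnitude gains a constant `log(a)` whose inverse
#' DFT is concentrated at quefrency 0.
#'
#' @param x an [signal()] object or numeric vector.
#' @param a positive scale factor.
#' @param n_fft,floor_db passed to [real_cepstrum()].
#' @param tol relative tolerance.
#' @return `TRUE` if the law holds within `tol`, else `FALSE`.
#' @export
cepstrum_scaling_check <- function(x, a, n_fft = NULL, floor_db = -120,
                                   tol = 1e-9) {
  if (!(a > 0)) stop("a must be positive")
  samples <- as_samples(x)
  c0 <- real_cepstrum(samples, n_fft = n_fft, floor_db = floor_db)$coefficients
  c1 <- real_cepstrum(a * samples, n_fft = n_fft,
                      floor_db = floor_db)$coefficients
  scale <- max(abs(c0), 1)
  shift_ok <- abs((c1[1] - c0[1]) - log(a)) <= tol * max(abs(log(a)), 1)
  rest_ok <- max(abs(c1[-1] - c0[-1])) <= tol * scale
  isTRUE(shift_ok && rest_ok)
}

#' Write cepstrum coefficients as CSV
#'
#' Columns `quefrency_index` (0-based) and `value`.
#'
#' @param cep an `mf_cepstrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cepstrum_csv <- function(cep, path) {
  stopifnot(inherits(cep, "mf_cepstrum"))
  df <- data.frame(quefrency_index = seq_along(cep$coefficients) - 1L,
                   value = cep$coefficients)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
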