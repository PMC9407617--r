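# Discrete wavelet transform stage. Biorthogonal analysis filters are
# hard-coded (symmetric, compactly supported); the decomposition wavelet of
# bior3.3 has 3 vanishing moments, enough to annihilate quadratic trends.
# Coefficients are kept under the L1 normalization (2^-j prefactor), the
# convention under which fBm(H) leaders scale as 2^{jH} and c1 = +H.

# analysis (decomposition) filter pairs; low-pass DC gain sqrt(2)
BIOR_FILTERS <- list(
  bior2.2 = list(
    dec_lo = c(0, -0.1767766952966369, 0.3535533905932738, 1.0606601717798212,
               0.3535533905932738, -0.1767766952966369),
    dec_hi = c(0, 0.3535533905932738, -0.7071067811865476, 0.3535533905932738,
               0, 0),
    vanishing_moments = 2L
  ),
  bior3.3 = list(
    dec_lo = c(0.06629126073623884, -0.19887378220871652, -0.15467960838455727,
               0.9943689110435825, 0.9943689110435825, -0.15467960838455727,
               -0.19887378220871652, 0.06629126073623884),
    dec_hi = c(0, 0, -0.1767766952966369, 0.5303300858899107,
               -0.5303300858899107, 0.1767766952966369, 0, 0),
    vanishing_moments = 3L
  ),
  bior4.4 = list(
    dec_lo = c(0, 0.03782845550726404, -0.02384946501955684,
               -0.11062440441843718, 0.37740285561283066, 0.852698679008894,
               0.37740285561283066, -0.11062440441843718,
               -0.02384946501955684, 0.03782845550726404),
    dec_hi = c(0, -0.06453888262869706, 0.04068941760916406,
               0.4180922732216172, -0.7884856164055829, 0.4180922732216172,
               0.04068941760916406, -0.06453888262869706, 0, 0),
    vanishing_moments = 4L
  )
)

#' Available biorthogonal analysis wavelets
#'
#' @return character vector of supported mother-wavelet names.
#' @export
mf_wavelets <- function() names(BIOR_FILTERS)

wavelet_filters <- function(name) {
  f <- BIOR_FILTERS[[name]]
  if (is.null(f)) {
    stop("unknown wavelet '", name, "'; available: ",
         paste(mf_wavelets(), collapse = ", "))
  }
  f
}

# fractional integration of order gamma in the Fourier domain:
# multiply DFT coefficients by |k|^-gamma (DC untouched). Raises every
# Holder exponent by gamma; used when leaders need minimal regularity.
fractional_integration <- function(x, gamma) {
  if (gamma == 0) return(x)
  n <- length(x)
  X <- fft(x)
  k <- c(0, seq_len(n - 1))
  k <- pmin(k, n - k) # symmetric frequency index
  g <- c(1, (k[-1])^(-gamma))
  Re(fft(X * g, inverse = TRUE)) / n
}

# leaders surviving at scale j2 for a series of length n: valid convolution
# keeps n - L + 1 points, decimation keeps every other starting at the
# first, nesting trims to half the finer scale, boundary trimming drops 2
leader_count_at <- function(n, j2, filter_len) {
  cnt <- n
  nest <- Inf
  for (j in seq_len(j2)) {
    if (cnt < filter_len) return(0L)
    cnt <- ceiling((cnt - filter_len + 1) / 2)
    nest <- min(cnt, floor(nest / 2))
    if (nest < 1) return(0L)
  }
  max(0L, as.integer(min(cnt, nest)) - 2L)
}

# minimum series length so that scale j2 keeps >= min_leaders leaders
min_series_length <- function(j2, filter_len, min_leaders = 8L) {
  lo <- 2^j2
  hi <- lo
  while (leader_count_at(hi, j2, filter_len) < min_leaders) hi <- hi * 2L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (leader_count_at(mid, j2, filter_len) >= min_leaders) hi <- mid
    else lo <- mid + 1L
  }
  as.integer(hi)
}

#' Discrete wavelet transform for leaders analysis
#'
#' Pyramidal analysis with the configured biorthogonal filter pair, keeping
#' only coefficients whose filter support lies fully inside the data (so no
#' boundary-affected coefficients enter later stages), dyadically decimated.
#' Output detail coefficients carry the L1 normalization: the raw pyramid
#' output at octave `j` is multiplied by \eqn{2^{-j/2}}, giving coefficients
#' that scale as \eqn{2^{jh}} around a point of Hölder regularity `h`.
#'
#' If `config$gamint > 0`, fractional integration of that order is applied
#' in the Fourier domain before the transform.
#'
#' @param x an [signal()], `mf_cepstrum` or numeric vector.
#' @param config an [mf_config()]; scales `1..config$j2` are computed.
#' @return an object of class `mf_wavelet_coeffs`: list with `details`
#'   (list of per-scale coefficient vectors), `n_j`, `wavelet`,
#'   `normalization = "L1"`.
#' @export
mf_dwt <- function(x, config = mf_config()) {
  series <- as_samples(x)
  filt <- wavelet_filters(config$wavelet)
  L <- length(filt$dec_lo)
  min_len <- min_series_length(config$j2, L)
  if (length(series) < min_len) {
    stop("series of length ", length(series), " too short for j2 = ",
         config$j2, " (minimum ", min_len, " samples)")
  }
  if (config$gamint > 0) {
    series <- fractional_integration(series, config$gamint)
  }
  details <- vector("list", config$j2)
  approx <- series
  for (j in seq_len(config$j2)) {
    d <- conv_valid(approx, filt$dec_hi)
    approx <- conv_valid(approx, filt$dec_lo)
    d <- d[seq(1, length(d), by = 2)]
    approx <- approx[seq(1, length(approx), by = 2)]
    details[[j]] <- d * 2^(-j / 2)
  }
  structure(
    list(details = details, n_j = lengths(details),
         wavelet = config$wavelet, normalization = "L1",
         gamint = config$gamint),
    class = "mf_wavelet_coeffs"
  )
}

#' @export
print.mf_wavelet_coeffs <- function(x, ...) {
  cat(sprintf("<mf_wavelet_coeffs> %s, %d scales, n_j = %s\n",
              x$wavelet, length(x$details),
              paste(x$n_j, collapse = ", ")))
  invisible(x)
}
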