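# Multifractal formalism: structure functions of leaders, scaling
# exponents by log-log regression across octaves, the Legendre singularity
# spectrum, and the leader log-cumulants c1..c3.

#' Multifractal analysis configuration
#'
#' Defaults encode the analysis settings used throughout: a biorthogonal
#' mother wavelet, three fitted octaves (`j1 = 1 .. j2 = 3`, suited to
#' ~1000-point cepstra), and moments `q` from -5 to +5 in steps of 0.5.
#' For long synthetic validation paths, [validation_scales()] gives a more
#' appropriate octave range.
#'
#' @param wavelet mother wavelet name; see [mf_wavelets()].
#' @param j1,j2 finest and coarsest fitted octave, `1 <= j1 < j2`.
#' @param q ordered moment grid, symmetric about 0. `q = 0` is kept in
#'   \eqn{\zeta(q)} reporting but excluded from the Legendre transform.
#' @param weighting `"uniform"` (default) or `"by_count"` (regression
#'   weights proportional to the per-scale coefficient counts).
#' @param gamint fractional integration order, >= 0.
#' @return an object of class `mf_config`.
#' @export
mf_config <- function(wavelet = "bior3.3", j1 = 1L, j2 = 3L,
                      q = seq(-5, 5, by = 0.5),
                      weighting = c("uniform", "by_count"),
                      gamint = 0) {
  weighting <- match.arg(weighting)
  wavelet_filters(wavelet) # validates the name
  j1 <- as.integer(j1); j2 <- as.integer(j2)
  if (!(j1 >= 1 && j1 < j2)) stop("need 1 <= j1 < j2; got ", j1, ", ", j2)
  q <- sort(unique(as.numeric(q)))
  if (max(abs(q + rev(q))) > 1e-12) stop("q grid must be symmetric about 0")
  if (gamint < 0) stop("gamint must be >= 0")
  structure(list(wavelet = wavelet, j1 = j1, j2 = j2, q = q,
                 weighting = weighting, gamint = gamint),
            class = "mf_config")
}

#' @export
print.mf_config <- function(x, ...) {
  cat(sprintf(
    "<mf_config> wavelet=%s, octaves %d..%d, q in [%g, %g] (%d values), %s weights, gamint=%g\n",
    x$wavelet, x$j1, x$j2, min(x$q), max(x$q), length(x$q), x$weighting,
    x$gamint))
  invisible(x)
}

#' Octave range suited to long validation paths
#'
#' For synthetic processes of dyadic length `n`, fine octaves (j <= 3)
#' show leader bias (curvature of `log2 S(q, j)` against `j`, worst for
#' negative `q`), and the very coarsest octaves have too few leaders.
#' The range `j1 = 4, j2 = log2(n) - 4` avoids both.
#'
#' @param n series length (power of two, >= 2^9).
#' @return integer vector `c(j1, j2)`.
#' @export
validation_scales <- function(n) {
  stopifnot(is_pow2(n), n >= 2^9)
  c(4L, as.integer(log2(n)) - 4L)
}

#' Structure functions of wavelet leaders
#'
#' \eqn{S(q, j) = n_j^{-1} \sum_k L(j,k)^q}, computed in log space
#' (log-sum-exp) so that large \eqn{|q|} neither overflows nor underflows.
#' \eqn{S(0, j) = 1} exactly.
#'
#' @param leaders an `mf_leaders` from [compute_leaders()].
#' @param config an [mf_config()] providing the `q` grid.
#' @return an object of class `mf_structure_functions`: `q`, `log2_S`
#'   (matrix, q by scale), `S`, `n_j`.
#' @export
structure_functions <- function(leaders, config = mf_config()) {
  stopifnot(inherits(leaders, "mf_leaders"))
  J <- length(leaders$leaders)
  q <- config$q
  if (any(vapply(leaders$leaders, function(l) any(l <= 0), logical(1)))) {
    stop("zero or negative leaders found; negative moments diverge. ",
         "Consider fractional integration (gamint > 0) or check the input.")
  }
  log2S <- matrix(NA_real_, nrow = length(q), ncol = J,
                  dimnames = list(q = format(q), j = seq_len(J)))
  for (j in seq_len(J)) {
    ll <- log(leaders$leaders[[j]])
    for (iq in seq_along(q)) {
      if (q[iq] == 0) {
        log2S[iq, j] <- 0
      } else {
        z <- q[iq] * ll
        m <- max(z)
        log2S[iq, j] <- (m + log(mean(exp(z - m)))) / log(2)
      }
    }
  }
  structure(list(q = q, log2_S = log2S, S = 2^log2S, n_j = leaders$n_j),
            class = "mf_structure_functions")
}

# regression weights per config over scales j1..j2
fit_weights <- function(config, n_j) {
  js <- config$j1:config$j2
  u <- if (config$weighting == "by_count") as.numeric(n_j[js])
       else rep(1, length(js))
  list(js = js, w = slope_weights(js, u), v = intercept_weights(js, u), u = u)
}

#' Scaling exponents by weighted log-log regression
#'
#' \eqn{\zeta(q)} is the slope of \eqn{\log_2 S(q, j)} against octave `j`
#' over `config$j1 .. config$j2`, by weighted least squares. The weights
#' `w_j` are the classical slope-extracting regression weights
#' (\eqn{\sum_j w_j = 0}, \eqn{\sum_j j\, w_j = 1}), uniform or
#' proportional to the per-scale counts. \eqn{\zeta(0) = 0} always.
#'
#' @param sf an `mf_structure_functions`.
#' @param config an [mf_config()].
#' @return an object of class `mf_scaling_exponents`: `q`, `zeta`,
#'   `weights`, `residual_rms` (per-q RMS of the fit residuals).
#' @export
scaling_exponents <- function(sf, config = mf_config()) {
  stopifnot(inherits(sf, "mf_structure_functions"))
  J <- ncol(sf$log2_S)
  if (config$j2 > J) {
    stop("structure functions only reach scale ", J,
         " but config requests j2 = ", config$j2)
  }
  if (any(sf$n_j[config$j1:config$j2] < 8)) {
    stop("fewer than 8 leaders at some fitted scale; series too short ",
         "for j2 = ", config$j2)
  }
  fw <- fit_weights(config, sf$n_j)
  Y <- sf$log2_S[, fw$js, drop = FALSE]
  zeta <- as.numeric(Y %*% fw$w)
  inter <- as.numeric(Y %*% fw$v)
  fitted <- outer(zeta, fw$js) + inter
  resid <- Y - fitted
  structure(list(q = sf$q, zeta = zeta, j1 = config$j1, j2 = config$j2,
                 weights = fw$w,
                 residual_rms = sqrt(rowMeans(resid^2))),
            class = "mf_scaling_exponents")
}

# least concave majorant of points (x, y) on an increasing grid, by upper
# convex hull; returns repaired y. Finite-sample zeta(q) can violate the
# concavity the Legendre transform presumes.
concave_majorant <- function(x, y) {
  n <- length(x)
  hull <- grDevices::chull(c(x, x[n], x[1]),
                           c(y, min(y) - 1, min(y) - 1))
  hull <- sort(setdiff(hull, c(n + 1L, n + 2L)))
  stats::approx(x[hull], y[hull], xout = x)$y
}

#' Legendre singularity spectrum
#'
#' Parametric evaluation of \eqn{D(h) = \inf_{q \ne 0} (1 + qh - \zeta(q))}
#' on the moment grid: \eqn{h(q) = d\zeta/dq} by central differences
#' (second-order one-sided at the grid ends, exact for quadratic
#' \eqn{\zeta}), and \eqn{D(q) = 1 + q\,h(q) - \zeta(q)}, with `q = 0`
#' excluded. If \eqn{\zeta} violates concavity beyond `tol`, it is first
#' projected onto its least concave majorant (recorded in the result).
#'
#' The spectrum width `max(h) - min(h)` measures multifractality strength:
#' 0 for a monofractal (linear \eqn{\zeta}), increasingly positive with
#' cepstral/process complexity.
#'
#' @param zeta an `mf_scaling_exponents`.
#' @param config an [mf_config()] (for the q grid bookkeeping; may be NULL).
#' @param tol concavity tolerance on second differences.
#' @return an object of class `mf_spectrum`: `q` (without 0), `h`, `D`,
#'   `width`, `h_peak`, `repaired`.
#' @export
legendre_spectrum <- function(zeta, config = NULL, tol = 1e-6) {
  stopifnot(inherits(zeta, "mf_scaling_exponents"))
  q <- zeta$q
  z <- zeta$zeta
  if (!all(is.finite(z))) stop("non-finite scaling exponents")
  d2 <- diff(z, differences = 2)
  repaired <- FALSE
  if (any(d2 > tol)) {
    z <- concave_majorant(q, z)
    repaired <- TRUE
  }
  n <- length(q)
  h <- numeric(n)
  # second-order accurate derivative on a uniform grid
  dq <- q[2] - q[1]
  h[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) / (2 * dq)
  h[1] <- (-3 * z[1] + 4 * z[2] - z[3]) / (2 * dq)
  h[n] <- (3 * z[n] - 4 * z[n - 1] + z[n - 2]) / (2 * dq)
  keep <- q != 0
  qk <- q[keep]; hk <- h[keep]
  D <- 1 + qk * hk - z[keep]
  structure(list(q = qk, h = hk, D = D,
                 width = max(hk) - min(hk),
                 h_peak = hk[which.max(D)],
                 repaired = repaired),
            class = "mf_spectrum")
}

#' Leader log-cumulants
#'
#' For each octave `j`, the sample cumulants of \eqn{\ln L(j,\cdot)}:
#' \eqn{C(j,1)} the mean, \eqn{C(j,2)} the (biased) variance, \eqn{C(j,3)}
#' the third central moment. Under multifractal scaling
#' \eqn{C(j,p) = c_{0,p} + c_p \ln 2^j}, so
#' \eqn{c_p = \log_2(e) \times} slope of \eqn{C(j,p)} against `j`, with the
#' same regression weights as [scaling_exponents()]. They expand
#' \eqn{\zeta(q) = \sum_p c_p q^p / p!}: `c1` locates the spectrum peak
#' (`= H` for fBm), `c2 <= 0` its curvature (`= 0` for monofractals,
#' \eqn{-\lambda^2} for the MRW), `c3` its asymmetry.
#'
#' @param leaders an `mf_leaders`.
#' @param config an [mf_config()].
#' @return an object of class `mf_log_cumulants`: `c1`, `c2`, `c3`,
#'   `intercepts` (\eqn{c_{0,p}}), `C` (matrix of per-scale cumulants,
#'   3 by J).
#' @export
log_cumulants <- function(leaders, config = mf_config()) {
  stopifnot(inherits(leaders, "mf_leaders"))
  J <- length(leaders$leaders)
  if (config$j2 > J) stop("leaders only reach scale ", J)
  if (any(vapply(leaders$leaders, function(l) any(l <= 0), logical(1)))) {
    stop("zero leaders; log-cumulants undefined (consider gamint > 0)")
  }
  C <- matrix(NA_real_, nrow = 3, ncol = J,
              dimnames = list(p = 1:3, j = seq_len(J)))
  for (j in seq_len(J)) {
    y <- log(leaders$leaders[[j]])
    m <- mean(y)
    C[1, j] <- m
    C[2, j] <- mean((y - m)^2)
    C[3, j] <- mean((y - m)^3)
  }
  fw <- fit_weights(config, leaders$n_j)
  slopes <- as.numeric(C[, fw$js, drop = FALSE] %*% fw$w)
  inters <- as.numeric(C[, fw$js, drop = FALSE] %*% fw$v)
  cp <- log2(exp(1)) * slopes
  structure(list(c1 = cp[1], c2 = cp[2], c3 = cp[3],
                 intercepts = inters, C = C,
                 j1 = config$j1, j2 = config$j2),
            class = "mf_log_cumulants")
}

#' Full multifractal wavelet-leaders analysis of one series
#'
#' Composes [mf_dwt()], [compute_leaders()], [structure_functions()],
#' [scaling_exponents()], [legendre_spectrum()] and [log_cumulants()],
#' annotating any stage error with the stage name. The per-signal scalar
#' descriptors used downstream are the spectrum `width`, `h_peak`,
#' `mean_D` (mean of \eqn{D} over the q grid, the per-signal summary
#' entering the one-sided group test) and `c1`, `c2`, `c3`.
#'
#' @param x an [signal()], `mf_cepstrum` or numeric vector.
#' @param config an [mf_config()].
#' @return an object of class `mf_result` with components `id`, `group`,
#'   `episode`, `config`, `zeta` (`mf_scaling_exponents`), `spectrum`
#'   (`mf_spectrum`), `cumulants` (`mf_log_cumulants`), `mean_D`,
#'   `diagnostics` (`n_j`, fit residual RMS, concavity repair flag).
#' @export
#' @examples
#' x <- generate_fbm(synthetic_spec("fbm", n = 4096, hurst = 0.7, seed = 3))
#' res <- mf_analyze(x, mf_config(j1 = 2, j2 = 6))
#' res$cumulants$c1 # close to 0.7
mf_analyze <- function(x, config = mf_config()) {
  stopifnot(inherits(config, "mf_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  coeffs <- stage("dwt", mf_dwt(x, config))
  leaders <- stage("leaders", compute_leaders(coeffs))
  sf <- stage("structure_functions", structure_functions(leaders, config))
  zeta <- stage("scaling_exponents", scaling_exponents(sf, config))
  spec <- stage("legendre_spectrum", legendre_spectrum(zeta))
  cum <- stage("log_cumulants", log_cumulants(leaders, config))
  meta <- if (inherits(x, c("mf_signal", "mf_cepstrum"))) x else
    list(id = "series", group = NA_character_, episode = NA_character_)
  structure(
    list(id = meta$id, group = meta$group, episode = meta$episode,
         config = config, zeta = zeta, spectrum = spec, cumulants = cum,
         mean_D = mean(spec$D),
         diagnostics = list(n_j = leaders$n_j,
                            residual_rms = zeta$residual_rms,
                            concavity_repaired = spec$repaired)),
    class = "mf_result"
  )
}

#' @export
print.mf_result <- function(x, ...) {
  cat(sprintf("<mf_result '%s'> group=%s episode=%s\n", x$id, x$group,
              x$episode))
  cat(sprintf("  width = %.4f, h_peak = %.4f, mean D = %.4f\n",
              x$spectrum$width, x$spectrum$h_peak, x$mean_D))
  cat(sprintf("  c1 = %.4f, c2 = %.4f, c3 = %.4f\n",
              x$cumulants$c1, x$cumulants$c2, x$cumulants$c3))
  invisible(x)
}

# serializable form of an mf_result
mf_result_to_list <- function(res) {
  list(
    id = res$id, group = res$group, episode = res$episode,
    config = list(wavelet = res$config$wavelet, j1 = res$config$j1,
                  j2 = res$config$j2, q = res$config$q,
                  weighting = res$config$weighting,
                  gamint = res$config$gamint),
    zeta = list(q = res$zeta$q, zeta = res$zeta$zeta),
    spectrum = list(q = res$spectrum$q, h = res$spectrum$h,
                    D = res$spectrum$D, width = res$spectrum$width,
                    h_peak = res$spectrum$h_peak),
    cumulants = list(c1 = res$cumulants$c1, c2 = res$cumulants$c2,
                     c3 = res$cumulants$c3),
    mean_D = res$mean_D,
    diagnostics = res$diagnostics
  )
}

#' Write one analysis result as JSON
#'
#' @param res an `mf_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mf_result <- function(res, path) {
  stopifnot(inherits(res, "mf_result"))
  jsonlite::write_json(mf_result_to_list(res), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
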