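# Synthetic generators with known multifractal ground truth. These stand in
# for private clinical corpora: fBm is the canonical monofractal
# (zeta(q) = qH), the multifractal random walk the canonical multifractal
# (c2 = -lambda2), the binomial cascade has closed-form partition exponents,
# and the cry-like generator exercises the cepstral front-end.

#' Specify a synthetic signal
#'
#' @param kind one of `"fbm"`, `"mrw"`, `"binomial_cascade"`, `"cry_like"`.
#' @param n number of samples. Must be a power of two (>= 256) for the
#'   stochastic processes; for `binomial_cascade` it is derived from `levels`
#'   and must not be given.
#' @param seed integer RNG seed; identical specs reproduce identical series
#'   bit for bit.
#' @param ... process parameters:
#'   * `fbm`: `hurst` in (0, 1).
#'   * `mrw`: `hurst` in (0, 1), `lambda2` (intermittency \eqn{\lambda^2})
#'     in `[0, 0.15]`.
#'   * `binomial_cascade`: `m0` in (0, 1), `levels` (<= 20).
#'   * `cry_like`: `f0` (fundamental, Hz, 200-800), `n_harmonics`,
#'     `jitter` (per-cycle relative f0 jitter), `noise_snr_db`
#'     (`Inf` disables noise), `sample_rate` (Hz), `duration` (s).
#' @return an object of class `mf_synth_spec`.
#' @seealso [generate_signal()], [cohort_spec()]
#' @export
synthetic_spec <- function(kind = c("fbm", "mrw", "binomial_cascade", "cry_like"),
                           n = NULL, seed = 1L, ...) {
  kind <- match.arg(kind)
  params <- list(...)
  defaults <- switch(kind,
    fbm = list(hurst = 0.7),
    mrw = list(hurst = 0.5, lambda2 = 0.05),
    binomial_cascade = list(m0 = 0.25, levels = 12L),
    cry_like = list(f0 = 450, n_harmonics = 10L, jitter = 0.01,
                    noise_snr_db = 30, sample_rate = 44100, duration = 0.25)
  )
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown)) stop("unknown parameter(s) for ", kind, ": ",
                            paste(unknown, collapse = ", "))
  params <- utils::modifyList(defaults, params)

  if (kind == "binomial_cascade") {
    if (!is.null(n)) stop("for binomial_cascade, n is 2^levels; do not set n")
    n <- 2^params$levels
  }
  if (kind == "cry_like") {
    if (!is.null(n)) stop("for cry_like, n is duration * sample_rate; do not set n")
    n <- round(params$duration * params$sample_rate)
  }
  if (kind %in% c("fbm", "mrw")) {
    if (is.null(n)) n <- 2^14
    if (!is_pow2(n)) stop("n must be a power of two for ", kind)
    if (n < 2^8) stop("n >= 256 required for stochastic processes; got ", n)
  }
  structure(list(kind = kind, n = as.integer(n), params = params,
                 seed = as.integer(seed)),
            class = "mf_synth_spec")
}

#' @export
print.mf_synth_spec <- function(x, ...) {
  p <- paste(names(x$params), vapply(x$params, format, ""), sep = "=",
             collapse = ", ")
  cat(sprintf("<mf_synth_spec %s> n=%d, seed=%d, %s\n", x$kind, x$n, x$seed, p))
  invisible(x)
}

#' Generate a synthetic signal from its spec
#'
#' Dispatches to [generate_fbm()], [generate_mrw()],
#' [generate_binomial_cascade()] or [generate_cry_like()].
#'
#' @param spec an [synthetic_spec()].
#' @param id,group,episode labels attached to the result.
#' @return an [signal()] object.
#' @export
generate_signal <- function(spec, id = NULL, group = NA_character_,
                            episode = NA_character_) {
  stopifnot(inherits(spec, "mf_synth_spec"))
  id <- id %||% sprintf("%s_seed%d", spec$kind, spec$seed)
  switch(spec$kind,
    fbm = generate_fbm(spec, id = id, group = group, episode = episode),
    mrw = generate_mrw(spec, id = id, group = group, episode = episode),
    binomial_cascade = generate_binomial_cascade(spec, id = id, group = group,
                                                 episode = episode),
    cry_like = generate_cry_like(spec, id = id, group = group,
                                 episode = episode)
  )
}

# stationary Gaussian series with autocovariance acov[1..(n+1)] = r(0..n),
# via circulant embedding of size 2n. Exact in distribution when the
# embedding is nonnegative definite.
circulant_gaussian <- function(acov, n, label = "covariance") {
  stopifnot(length(acov) == n + 1)
  circ <- c(acov, rev(acov[2:n]))
  lam <- Re(fft(circ))
  if (min(lam) < -1e-8 * max(lam)) {
    stop("circulant embedding of the ", label,
         " is not nonnegative definite (min eigenvalue ",
         format(min(lam)), "); cannot simulate exactly")
  }
  lam <- pmax(lam, 0)
  m <- 2L * n
  W <- complex(length.out = m)
  W[1] <- sqrt(lam[1] / m) * rnorm(1)
  W[n + 1] <- sqrt(lam[n + 1] / m) * rnorm(1)
  V1 <- rnorm(n - 1)
  V2 <- rnorm(n - 1)
  W[2:n] <- sqrt(lam[2:n] / (2 * m)) * complex(real = V1, imaginary = V2)
  W[m:(n + 2)] <- Conj(W[2:n])
  Re(fft(W))[1:n]
}

# fGn autocovariance gamma(k) = 1/2 (|k+1|^2H - 2|k|^2H + |k-1|^2H)
fgn_acov <- function(n, H) {
  k <- 0:n
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# fractional Gaussian noise; unit-variance increments of fBm(H)
generate_fgn <- function(n, H, seed) {
  with_local_seed(seed, circulant_gaussian(fgn_acov(n, H), n, "fGn autocovariance"))
}

#' Fractional Brownian motion by circulant embedding
#'
#' Exact-in-distribution fBm path: cumulative sum of fractional Gaussian
#' noise simulated by circulant (Davies-Harte) embedding of its
#' autocovariance \eqn{\gamma(k) = \frac{1}{2}(|k+1|^{2H} - 2|k|^{2H} +
#' |k-1|^{2H})}. fBm with Hurst exponent \eqn{H} is the canonical
#' monofractal: \eqn{\zeta(q) = qH}, \eqn{c_1 = H}, \eqn{c_2 = c_3 = 0}.
#'
#' @param spec an [synthetic_spec()] of kind `"fbm"`.
#' @param id,group,episode labels attached to the result.
#' @return an [signal()] object of length `spec$n`.
#' @export
#' @examples
#' x <- generate_fbm(synthetic_spec("fbm", n = 1024, hurst = 0.7, seed = 1))
generate_fbm <- function(spec, id = spec$kind, group = NA_character_,
                         episode = NA_character_) {
  stopifnot(inherits(spec, "mf_synth_spec"), spec$kind == "fbm")
  H <- spec$params$hurst
  if (!(H > 0 && H < 1)) stop("hurst must be in (0, 1); got ", H)
  x <- cumsum(generate_fgn(spec$n, H, spec$seed))
  signal(x, id = id, group = group, episode = episode)
}

#' Multifractal random walk
#'
#' Path with increments \eqn{\epsilon_k e^{\omega_k}} where \eqn{\epsilon}
#' is fractional Gaussian noise with Hurst exponent \eqn{H} and
#' \eqn{\omega} is a Gaussian log-correlated field with covariance
#' \eqn{\lambda^2 \ln(L/(|\Delta|+1))} truncated at the integral scale
#' \eqn{L = n}, with mean \eqn{-\lambda^2 \ln L} so that
#' \eqn{E[e^{2\omega}] = 1}. The MRW is the canonical multifractal:
#' \eqn{c_1 = H + \lambda^2}, \eqn{c_2 = -\lambda^2}.
#'
#' @param spec an [synthetic_spec()] of kind `"mrw"`.
#' @param id,group,episode labels attached to the result.
#' @return an [signal()] object of length `spec$n`.
#' @export
generate_mrw <- function(spec, id = spec$kind, group = NA_character_,
                         episode = NA_character_) {
  stopifnot(inherits(spec, "mf_synth_spec"), spec$kind == "mrw")
  H <- spec$params$hurst
  lambda2 <- spec$params$lambda2
  if (!(H > 0 && H < 1)) stop("hurst must be in (0, 1); got ", H)
  if (!(lambda2 >= 0 && lambda2 <= 0.15)) {
    stop("lambda2 must be in [0, 0.15]; got ", lambda2)
  }
  n <- spec$n
  eps <- generate_fgn(n, H, spec$seed)
  if (lambda2 == 0) {
    # degenerate case: plain fBm increments
    return(signal(cumsum(eps), id = id, group = group, episode = episode))
  }
  k <- 0:n
  r <- lambda2 * pmax(0, log(n / (k + 1)))
  # independent draw for the volatility field: offset the seed stream
  om <- with_local_seed(spec$seed + 1500450271 %% 2^30,
                        circulant_gaussian(r, n, "MRW log-volatility covariance"))
  om <- om - lambda2 * log(n) # E[exp(2 omega)] = 1
  signal(cumsum(eps * exp(om)), id = id, group = group, episode = episode)
}

#' Deterministic binomial multiplicative cascade
#'
#' The dyadic measure obtained by `levels` refinements, each sending a
#' fraction `m0` of the mass to the left half and `1 - m0` to the right,
#' normalized to unit total mass. Its partition exponents are closed form:
#' \eqn{\tau(q) = -\log_2(m_0^q + m_1^q)}, the ground truth used to
#' validate the scaling-exponent estimator (see [cascade_tau()]).
#'
#' To validate leader scaling exponents against \eqn{\tau(q)}, analyze the
#' cumulative sum of the returned cell masses (the distribution function of
#' the measure); under that convention \eqn{\zeta(q) = 1 + \tau(q)}, the
#' constant offset coming from the integration.
#'
#' @param spec an [synthetic_spec()] of kind `"binomial_cascade"`.
#' @param id,group,episode labels attached to the result.
#' @return an [signal()] object of length `2^levels` holding the cell masses.
#' @export
generate_binomial_cascade <- function(spec, id = spec$kind,
                                      group = NA_character_,
                                      episode = NA_character_) {
  stopifnot(inherits(spec, "mf_synth_spec"), spec$kind == "binomial_cascade")
  m0 <- spec$params$m0
  levels <- spec$params$levels
  if (!(m0 > 0 && m0 < 1)) stop("m0 must be in (0, 1); got ", m0)
  if (!(levels >= 1 && levels <= 20)) stop("levels must be in 1..20; got ", levels)
  mu <- 1
  for (i in seq_len(levels)) {
    mu <- as.vector(rbind(mu * m0, mu * (1 - m0)))
  }
  signal(mu, id = id, group = group, episode = episode)
}

#' Closed-form partition exponents of the binomial cascade
#'
#' \eqn{\tau(q) = -\log_2(m_0^q + (1 - m_0)^q)}; \eqn{\tau(0) = -1},
#' \eqn{\tau(1) = 0}.
#'
#' @param q moment orders.
#' @param m0 left-half weight.
#' @return numeric vector of exponents.
#' @export
cascade_tau <- function(q, m0) {
  -log2(m0^q + (1 - m0)^q)
}

#' Cry-like quasi-harmonic test signal
#'
#' Sum of `n_harmonics` sinusoids at multiples of the fundamental `f0` with
#' `1/k` amplitude decay, per-cycle multiplicative jitter on `f0`, plus
#' white noise at `noise_snr_db`; peak-normalized to 1. A smoke-test input
#' for the cepstral front-end: its real cepstrum peaks near quefrency
#' `sample_rate / f0`.
#'
#' @param spec an [synthetic_spec()] of kind `"cry_like"`.
#' @param id,group,episode labels attached to the result.
#' @return an [signal()] object with sample rate.
#' @export
generate_cry_like <- function(spec, id = spec$kind, group = NA_character_,
                              episode = NA_character_) {
  stopifnot(inherits(spec, "mf_synth_spec"), spec$kind == "cry_like")
  p <- spec$params
  if (!(p$f0 >= 200 && p$f0 <= 800)) {
    stop("f0 must be in [200, 800] Hz (cry fundamental range); got ", p$f0)
  }
  if (p$f0 * p$n_harmonics >= p$sample_rate / 2) {
    stop("highest harmonic ", p$f0 * p$n_harmonics,
         " Hz is at or above Nyquist ", p$sample_rate / 2, " Hz")
  }
  n <- spec$n
  if (n < 4096) stop("duration * sample_rate must be >= 4096; got ", n)
  with_local_seed(spec$seed, {
    # per-cycle jitter: piecewise-constant relative perturbation of f0,
    # held over each nominal fundamental period
    cycle_len <- max(1L, round(p$sample_rate / p$f0))
    n_cycles <- ceiling(n / cycle_len)
    jit <- if (p$jitter > 0) 1 + p$jitter * rnorm(n_cycles) else rep(1, n_cycles)
    f_inst <- p$f0 * rep(jit, each = cycle_len)[seq_len(n)]
    phase <- 2 * pi * cumsum(f_inst) / p$sample_rate
    x <- numeric(n)
    for (k in seq_len(p$n_harmonics)) {
      x <- x + sin(k * phase) / k
    }
    if (is.finite(p$noise_snr_db)) {
      sig_pow <- mean(x^2)
      noise_sd <- sqrt(sig_pow / 10^(p$noise_snr_db / 10))
      x <- x + rnorm(n, sd = noise_sd)
    }
    x <- x / max(abs(x))
    signal(x, sample_rate = p$sample_rate, id = id, group = group,
           episode = episode)
  })
}

# ---- cohorts ----------------------------------------------------------------

#' Specify a two-group synthetic cohort
#'
#' Two [synthetic_spec()] templates (typically differing in one parameter,
#' e.g. the MRW intermittency) and a number of signals per group. Per-signal
#' seeds are derived as `seed + index`, where `index` runs 1..2*n_per_group
#' over group A then group B, so any single signal can be regenerated in
#' isolation.
#'
#' @param n_per_group signals per group (>= 2).
#' @param group_a,group_b [synthetic_spec()] templates (their own seeds are
#'   ignored; derived seeds are used).
#' @param seed cohort seed.
#' @param labels length-2 character vector of group labels.
#' @param episode episode label stamped on every signal.
#' @return an object of class `mf_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group, group_a, group_b, seed = 1L,
                        labels = c("a", "b"), episode = "EXP") {
  stopifnot(inherits(group_a, "mf_synth_spec"),
            inherits(group_b, "mf_synth_spec"),
            length(labels) == 2, labels[1] != labels[2])
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_a = group_a, group_b = group_b,
                 seed = as.integer(seed), labels = as.character(labels),
                 episode = as.character(episode)),
            class = "mf_cohort_spec")
}

# derived seed for cohort member `index` (1-based over the whole cohort)
cohort_member_seed <- function(cohort, index) cohort$seed + as.integer(index)

# regenerate a single cohort member by index
cohort_member <- function(cohort, index) {
  npg <- cohort$n_per_group
  stopifnot(index >= 1, index <= 2 * npg)
  in_a <- index <= npg
  template <- if (in_a) cohort$group_a else cohort$group_b
  lbl <- if (in_a) cohort$labels[1] else cohort$labels[2]
  spec <- template
  spec$seed <- cohort_member_seed(cohort, index)
  generate_signal(spec, id = sprintf("%s_%03d", lbl, index),
                  group = lbl, episode = cohort$episode)
}

#' Generate a labeled two-group cohort
#'
#' @param cohort an [cohort_spec()].
#' @return list of [signal()] objects, group A (first label) then group B,
#'   each carrying its group and episode labels.
#' @export
#' @examples
#' ch <- cohort_spec(2,
#'   synthetic_spec("mrw", n = 1024, hurst = 0.5, lambda2 = 0.08),
#'   synthetic_spec("mrw", n = 1024, hurst = 0.5, lambda2 = 0.02),
#'   seed = 7, labels = c("healthy", "unhealthy"))
#' sigs <- generate_cohort(ch)
#' table(vapply(sigs, function(s) s$group, ""))
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "mf_cohort_spec"))
  lapply(seq_len(2 * cohort$n_per_group),
         function(i) cohort_member(cohort, i))
}
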