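# Independent oracles, deliberately naive: exhaustive enumeration and
# direct O(n^2) transforms, kept free of any code path they check.

# Exhaustive wavelet-leader enumeration. Scale-j position k (1-based) is
# the dyadic interval [(k-1)*2^j, k*2^j); the leader is the max of |d|
# over every interval at scales <= j inside [(k-2)*2^j, (k+1)*2^j).
# Trailing positions without complete finer-scale nesting and the two
# boundary positions are dropped.
brute_force_leaders <- function(details) {
  J <- length(details)
  ntilde <- integer(J)
  ntilde[1] <- length(details[[1]])
  if (J > 1) {
    for (j in 2:J) {
      ntilde[j] <- min(length(details[[j]]), ntilde[j - 1] %/% 2)
    }
  }
  lapply(seq_len(J), function(j) {
    n <- ntilde[j]
    vapply(2:(n - 1), function(k) {
      lo <- (k - 2) * 2^j
      hi <- (k + 1) * 2^j
      best <- -Inf
      for (jp in seq_len(j)) {
        for (kp in seq_len(ntilde[jp])) {
          a <- (kp - 1) * 2^jp
          b <- kp * 2^jp
          if (a >= lo && b <= hi) {
            best <- max(best, abs(details[[jp]][kp]))
          }
        }
      }
      best
    }, numeric(1))
  })
}

# Direct O(n^2) evaluation of the real cepstrum: explicit DFT, magnitude,
# log (with the same relative floor), explicit inverse DFT.
dft_real_cepstrum <- function(x, n_fft, floor_db = -120) {
  x <- c(x, rep(0, n_fft - length(x)))
  n <- n_fft
  k <- 0:(n - 1)
  mag <- vapply(k, function(kk) {
    Mod(sum(x * exp(-2i * pi * kk * k / n)))
  }, numeric(1))
  mag <- pmax(mag, max(mag) * 10^(floor_db / 20))
  lm <- log(mag)
  vapply(k, function(nn) {
    Re(sum(lm * exp(2i * pi * nn * k / n)) / n)
  }, numeric(1))
}

# Moment-scaling regression on increments: slope of log2 E|x(t+k)-x(t)|^q
# against log2 k, the classic structure-function estimate of zeta(q)
increment_zeta <- function(x, q, lags = 2^(0:4)) {
  lm <- vapply(lags, function(k) {
    log2(mean(abs(diff(x, lag = k))^q))
  }, numeric(1))
  unname(coef(lm_fit <- stats::lm(lm ~ log2(lags)))[2])
}

# analysis configuration used for long synthetic validation paths
validation_config <- function(n, ...) {
  vs <- validation_scales(n)
  mf_config(j1 = vs[1], j2 = vs[2], ...)
}
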