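# internal helpers shared across modules

next_pow2 <- function(n) {
  stopifnot(n >= 1)
  2^ceiling(log2(n))
}

is_pow2 <- function(n) {
  n >= 1 && abs(log2(n) - round(log2(n))) < 1e-9
}

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state; all generators are pure functions of their spec because of this
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# linear convolution of x with filter h, keeping only the fully-supported
# ("valid") part: indices where the filter support lies inside the data
conv_valid <- function(x, h) {
  n <- length(x)
  L <- length(h)
  if (n < L) {
    stop("series shorter than filter (", n, " < ", L, ")")
  }
  nf <- next_pow2(n + L - 1L)
  y <- Re(fft(fft(c(x, rep(0, nf - n))) * fft(c(h, rep(0, nf - L))),
              inverse = TRUE)) / nf
  y[L:n]
}

# weights of the slope-extracting linear regression of y against j:
# sum(w) = 0, sum(j * w) = 1, so sum(w * y) is the WLS slope estimate.
# `u` are the regression weights proper (uniform or per-scale counts).
slope_weights <- function(j, u = rep(1, length(j))) {
  stopifnot(length(j) == length(u), all(u > 0), length(j) >= 2)
  jbar <- sum(u * j) / sum(u)
  w <- u * (j - jbar)
  w / sum(w * (j - jbar))
}

# intercept-extracting companion: sum(v * y) is the WLS intercept
intercept_weights <- function(j, u = rep(1, length(j))) {
  w <- slope_weights(j, u)
  jbar <- sum(u * j) / sum(u)
  u / sum(u) - jbar * w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
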