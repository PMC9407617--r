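# DWT, leaders, structure functions, scaling exponents, Legendre spectrum
# and log-cumulants: closed-form cases, oracle equivalence, invariances.

test_that("biorthogonal analysis wavelets annihilate low-order polynomials", {
  cfg <- mf_config(j1 = 1, j2 = 3)
  const <- rep(3.7, 1024)
  dw <- mf_dwt(const, cfg)
  for (d in dw$details) expect_lt(max(abs(d)), 1e-10)

  ramp <- seq(0, 1, length.out = 1024)
  dw <- mf_dwt(ramp, cfg)
  for (d in dw$details) expect_lt(max(abs(d)), 1e-10)

  # bior3.3 has 3 vanishing moments: quadratics go too
  quad <- seq(-1, 1, length.out = 1024)^2
  dw <- mf_dwt(quad, cfg)
  for (d in dw$details) expect_lt(max(abs(d)), 1e-9)
})

test_that("interior coefficient counts shrink dyadically", {
  set.seed(3)
  cfg <- mf_config(j1 = 1, j2 = 5)
  dw <- mf_dwt(rnorm(4096), cfg)
  flen <- length(mfleaders:::wavelet_filters("bior3.3")$dec_lo)
  for (j in 1:5) {
    expect_lt(abs(dw$n_j[j] - 4096 / 2^j), flen + 1)
  }
  expect_error(mf_dwt(rnorm(40), mf_config(j1 = 1, j2 = 5)), "minimum")
})

test_that("fractional integration scales a pure tone by |k|^-gamma", {
  n <- 256
  k0 <- 8
  x <- cos(2 * pi * k0 * (0:(n - 1)) / n)
  y <- mfleaders:::fractional_integration(x, 1)
  expect_equal(y, x / k0, tolerance = 1e-10)
})

test_that("leaders match the hand example and closed-form fields", {
  d <- list(c(1, 3, 2, 5, 1, 1, 1, 1), c(4, 1, 1, 1))
  L <- compute_leaders(d)
  expect_equal(L$leaders[[1]], c(3, 5, 5, 5, 1, 1))
  expect_equal(L$leaders[[2]], c(5, 5))
  expect_equal(L$leaders, brute_force_leaders(d))

  # single scale: 3-neighborhood max only
  d1 <- list(c(2, -7, 1, 0, 4, 3))
  expect_equal(compute_leaders(d1)$leaders[[1]], c(7, 7, 4, 4))

  # constant field stays constant
  dc <- list(rep(2.5, 16), rep(-2.5, 8), rep(2.5, 4))
  for (l in compute_leaders(dc)$leaders) expect_true(all(l == 2.5))
})

test_that("optimized leaders equal exhaustive enumeration on random sets", {
  set.seed(42)
  checked <- 0
  for (rep in 1:50) {
    n1 <- sample(12:64, 1)
    J <- sample(1:4, 1)
    d <- list(rnorm(n1))
    if (J > 1) {
      for (j in 2:J) {
        nj <- length(d[[j - 1]]) %/% 2 + sample(-1:1, 1)
        if (nj < 3) break
        d[[j]] <- rnorm(nj) * 2^j
      }
    }
    fast <- tryCatch(compute_leaders(d)$leaders, error = function(e) NULL)
    if (is.null(fast)) next # too short to nest; outside the leaders domain
    expect_identical(fast, brute_force_leaders(d))
    checked <- checked + 1
  }
  expect_gte(checked, 40)
})

test_that("structure functions reproduce hand-computed moments", {
  fake <- structure(list(leaders = list(c(1, 2, 4)), n_j = 3L),
                    class = "mf_leaders")
  cfg <- mf_config(q = c(-2, -1, 0, 1, 2))
  sf <- structure_functions(fake, cfg)
  expect_equal(sf$S[sf$q == 2, 1], (1 + 4 + 16) / 3)
  expect_equal(sf$S[sf$q == -1, 1], (1 + 0.5 + 0.25) / 3)
  expect_equal(sf$S[sf$q == 0, 1], 1)
  expect_equal(sf$log2_S[sf$q == 0, 1], 0)

  degenerate <- structure(list(leaders = list(c(0, 1, 2)), n_j = 3L),
                          class = "mf_leaders")
  expect_error(structure_functions(degenerate, cfg), "gamint")
})

test_that("scaling exponents recover an exact power law and WLS oracle", {
  q <- seq(-2, 2, 0.5)
  H <- 0.7
  J <- 5
  log2S <- outer(q * H, 1:J)
  sf <- structure(list(q = q, log2_S = log2S, S = 2^log2S,
                       n_j = rep(64, J)),
                  class = "mf_structure_functions")
  z <- scaling_exponents(sf, mf_config(q = q, j1 = 1, j2 = 5))
  expect_equal(z$zeta, 0.7 * q, tolerance = 1e-12)
  expect_equal(z$zeta[q == 0], 0)
  expect_equal(z$residual_rms, rep(0, length(q)), tolerance = 1e-10)

  # weighted 3-point fit against an independent lm() solve
  set.seed(8)
  y <- matrix(rnorm(3 * length(q)), nrow = length(q))
  sfw <- structure(list(q = q, log2_S = y, S = 2^y,
                        n_j = c(512, 256, 128)),
                   class = "mf_structure_functions")
  zw <- scaling_exponents(sfw, mf_config(q = q, j1 = 1, j2 = 3,
                                         weighting = "by_count"))
  oracle <- apply(y, 1, function(yy) {
    unname(coef(lm(yy ~ c(1, 2, 3), weights = c(512, 256, 128)))[2])
  })
  expect_equal(zw$zeta, oracle, tolerance = 1e-10)
})

test_that("Legendre transform: monofractal collapse and parabolic closed form", {
  q <- seq(-5, 5, 0.5)
  mono <- structure(list(q = q, zeta = 0.6 * q),
                    class = "mf_scaling_exponents")
  sp <- legendre_spectrum(mono)
  expect_equal(sp$h, rep(0.6, length(sp$q)), tolerance = 1e-12)
  expect_equal(sp$D, rep(1, length(sp$q)), tolerance = 1e-12)
  expect_equal(sp$width, 0, tolerance = 1e-12)
  expect_false(sp$repaired)

  c1 <- 0.7; c2 <- -0.04
  par_z <- structure(list(q = q, zeta = c1 * q + c2 * q^2 / 2),
                     class = "mf_scaling_exponents")
  sp <- legendre_spectrum(par_z)
  expect_equal(sp$h, c1 + c2 * sp$q, tolerance = 1e-10)
  expect_equal(sp$D, 1 + (sp$h - c1)^2 / (2 * c2), tolerance = 1e-10)
  # spot values from the log-normal spectrum algebra
  expect_equal(sp$h[sp$q == 2], 0.62)
  expect_equal(sp$D[sp$q == 2], 0.92)
  expect_true(all(sp$D <= 1 + 1e-6))
  # nearest-to-zero moments attain the grid maximum 1 + c2 q^2 / 2
  expect_equal(max(sp$D), 1 + c2 * 0.5^2 / 2, tolerance = 1e-12)
})

test_that("non-concave scaling exponents are projected before the transform", {
  q <- seq(-2, 2, 0.5)
  z <- 0.5 * q
  z[5] <- z[5] - 0.3 # a convex dent at q = 0
  bent <- structure(list(q = q, zeta = z), class = "mf_scaling_exponents")
  sp <- legendre_spectrum(bent)
  expect_true(sp$repaired)
  expect_true(all(diff(sp$h) <= 1e-9))
  expect_true(all(sp$D <= 1 + 1e-6))
})

test_that("deterministic leader fields fix the log-cumulant sign convention", {
  H <- 0.5
  fake <- structure(list(leaders = lapply(1:3, function(j) rep(2^(j * H), 32)),
                         n_j = rep(32L, 3)),
                    class = "mf_leaders")
  cfg <- mf_config(j1 = 1, j2 = 3)
  lc <- log_cumulants(fake, cfg)
  expect_equal(lc$c1, H, tolerance = 1e-12)
  expect_equal(lc$c2, 0, tolerance = 1e-12)
  expect_equal(lc$c3, 0, tolerance = 1e-12)
  expect_equal(unname(lc$C[1, ]), (1:3) * H * log(2), tolerance = 1e-12)
})

test_that("full analysis is deterministic and amplitude-invariant", {
  x <- generate_fbm(synthetic_spec("fbm", n = 2^12, hurst = 0.7, seed = 6))
  cfg <- validation_config(2^12)
  r1 <- mf_analyze(x, cfg)
  r2 <- mf_analyze(x, cfg)
  expect_identical(r1$zeta$zeta, r2$zeta$zeta)
  expect_identical(r1$cumulants$c2, r2$cumulants$c2)

  xs <- x; xs$samples <- 7.3 * x$samples
  r3 <- mf_analyze(xs, cfg)
  expect_equal(r3$zeta$zeta, r1$zeta$zeta, tolerance = 1e-9)
  expect_equal(r3$spectrum$width, r1$spectrum$width, tolerance = 1e-9)
  expect_equal(r3$cumulants$c1, r1$cumulants$c1, tolerance = 1e-9)
  expect_equal(r3$cumulants$c2, r1$cumulants$c2, tolerance = 1e-9)
  expect_equal(r3$cumulants$c3, r1$cumulants$c3, tolerance = 1e-9)

  # monofractal path: narrow spectrum
  expect_lt(r1$spectrum$width, 0.3)
  # stage errors are annotated
  expect_error(mf_analyze(rnorm(64), cfg), "\\[dwt\\]")
})

test_that("the two estimation routes agree on a multifractal path", {
  x <- generate_mrw(synthetic_spec("mrw", n = 2^14, hurst = 0.5,
                                   lambda2 = 0.08, seed = 9))
  res <- mf_analyze(x, validation_config(2^14))
  expect_lt(abs(res$cumulants$c1 - res$spectrum$h_peak), 0.05)
  # curvature of zeta at 0 (second difference) matches c2
  q <- res$zeta$q
  i0 <- which(q == 0)
  dq <- q[2] - q[1]
  curv <- (res$zeta$zeta[i0 + 1] - 2 * res$zeta$zeta[i0] +
             res$zeta$zeta[i0 - 1]) / dq^2
  expect_lt(abs(res$cumulants$c2 - curv), 0.02)
})
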