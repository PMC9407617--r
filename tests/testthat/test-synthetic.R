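# Synthetic generators: determinism, refusal of degenerate specs, and
# agreement of each process with its known scaling ground truth.

test_that("fBm increments are white at H = 0.5 and generation is deterministic", {
  n <- 2^12
  spec <- synthetic_spec("fbm", n = n, hurst = 0.5, seed = 11)
  x <- generate_fbm(spec)$samples
  inc <- diff(x)
  r1 <- sum((inc - mean(inc))[-1] * (inc - mean(inc))[-length(inc)]) /
    sum((inc - mean(inc))^2)
  expect_lt(abs(r1), 3 / sqrt(n))

  expect_identical(generate_fbm(spec)$samples, x)
  # generation must not disturb the caller's RNG stream
  set.seed(99); a <- runif(1)
  set.seed(99); invisible(generate_fbm(spec)); b <- runif(1)
  expect_identical(a, b)
})

test_that("fBm k-step increment variance scales as k^{2H}", {
  x <- generate_fbm(synthetic_spec("fbm", n = 2^14, hurst = 0.8, seed = 1))$samples
  lags <- c(1, 2, 4, 8, 16)
  v <- vapply(lags, function(k) var(diff(x, lag = k)), numeric(1))
  slope <- unname(coef(lm(log(v) ~ log(lags)))[2])
  expect_lt(abs(slope - 2 * 0.8), 0.15)
})

test_that("stochastic specs refuse too-short or non-dyadic lengths", {
  expect_error(synthetic_spec("fbm", n = 128), "256")
  expect_error(synthetic_spec("fbm", n = 1000), "power of two")
  expect_error(generate_fbm(synthetic_spec("fbm", n = 512, hurst = 1.5)),
               "hurst")
  expect_error(generate_mrw(synthetic_spec("mrw", n = 512, lambda2 = 0.5)),
               "lambda2")
})

test_that("MRW with lambda2 = 0 degenerates to the fBm path of the same seed", {
  n <- 2^10
  x_mrw <- generate_mrw(synthetic_spec("mrw", n = n, hurst = 0.6,
                                       lambda2 = 0, seed = 4))$samples
  x_fbm <- generate_fbm(synthetic_spec("fbm", n = n, hurst = 0.6,
                                       seed = 4))$samples
  expect_identical(x_mrw, x_fbm)
})

test_that("MRW moment scaling is concave in q (multifractal signature)", {
  x <- generate_mrw(synthetic_spec("mrw", n = 2^15, hurst = 0.5,
                                   lambda2 = 0.08, seed = 2))$samples
  z2 <- increment_zeta(x, 2)
  z4 <- increment_zeta(x, 4)
  # zeta(0) = 0 by definition of the moment-scaling slope
  expect_lt(z4 - z2, z2 - 0)
  expect_identical(x, generate_mrw(synthetic_spec("mrw", n = 2^15, hurst = 0.5,
                                                  lambda2 = 0.08,
                                                  seed = 2))$samples)
})

test_that("binomial cascade: symmetric weights, combinatorics, box-count slope", {
  u <- generate_binomial_cascade(
    synthetic_spec("binomial_cascade", m0 = 0.5, levels = 8))$samples
  expect_equal(u, rep(2^-8, 2^8))

  mu <- generate_binomial_cascade(
    synthetic_spec("binomial_cascade", m0 = 0.25, levels = 10))$samples
  expect_equal(sum(mu), 1)
  vals <- sort(unique(signif(mu, 12)))
  expect_length(vals, 11)
  counts <- table(factor(signif(mu, 12), levels = vals))
  expect_equal(unname(as.integer(counts)), choose(10, 10:0))

  # partition function of box masses: log2 sum(mu_box^2) against the
  # coarsening octave has slope tau(2) = -log2(m0^2 + m1^2), exactly
  mu12 <- generate_binomial_cascade(
    synthetic_spec("binomial_cascade", m0 = 0.25, levels = 12))$samples
  js <- 1:6
  lS <- vapply(js, function(j) {
    boxes <- colSums(matrix(mu12, nrow = 2^j))
    log2(sum(boxes^2))
  }, numeric(1))
  slope <- unname(coef(lm(lS ~ js))[2])
  expect_equal(slope, cascade_tau(2, 0.25), tolerance = 1e-10)

  expect_error(generate_binomial_cascade(
    synthetic_spec("binomial_cascade", levels = 25)), "levels")
})

test_that("cry-like signal: harmonic stack, cepstral pitch peak, guards", {
  spec0 <- synthetic_spec("cry_like", f0 = 441, n_harmonics = 8, jitter = 0,
                          noise_snr_db = Inf, sample_rate = 44100,
                          duration = 0.2, seed = 1)
  x <- generate_cry_like(spec0)
  expect_equal(max(abs(x$samples)), 1)
  n <- length(x$samples)
  mag <- Mod(fft(x$samples))[1:(n / 2)]
  bin_hz <- 44100 / n
  for (k in 1:3) {
    expect_lt(abs((which.max(mag * (abs(seq_len(n / 2) - 1 - k * 441 / bin_hz) < 3)) - 1) *
                    bin_hz - k * 441), 1.5 * bin_hz)
  }

  # real cepstrum peaks at the pitch period fs/f0 = 100 samples (+/- 2)
  spec <- synthetic_spec("cry_like", f0 = 441, seed = 3)
  cep <- real_cepstrum(generate_cry_like(spec))
  search <- 50:200
  peak <- search[which.max(cep$coefficients[search + 1])]
  expect_lte(abs(peak - 100), 2)

  expect_identical(generate_cry_like(spec)$samples,
                   generate_cry_like(spec)$samples)
  expect_error(generate_cry_like(
    synthetic_spec("cry_like", f0 = 800, n_harmonics = 40)), "Nyquist")
  expect_error(generate_cry_like(synthetic_spec("cry_like", f0 = 100)),
               "f0")
})

test_that("cohorts are balanced, seeded per member, and regenerable", {
  ch <- cohort_spec(5,
                    synthetic_spec("mrw", n = 512, lambda2 = 0.08),
                    synthetic_spec("mrw", n = 512, lambda2 = 0.02),
                    seed = 21, labels = c("healthy", "unhealthy"))
  sigs <- generate_cohort(ch)
  groups <- vapply(sigs, function(s) s$group, "")
  expect_equal(sum(groups == "healthy"), 5)
  expect_equal(sum(groups == "unhealthy"), 5)

  # member 7 regenerated in isolation equals member 7 of the batch
  lone <- mfleaders:::cohort_member(ch, 7)
  expect_identical(lone$samples, sigs[[7]]$samples)
  expect_identical(lone$group, "unhealthy")

  expect_error(cohort_spec(1, ch$group_a, ch$group_b), "n_per_group")
})
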