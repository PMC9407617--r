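# Two-group descriptor comparison: t-test contracts, label-swap
# antisymmetry, average spectra, report assembly.

fake_result <- function(h, D, zeta = NULL, q = seq(-2, 2, 0.5),
                        id = "x", group = "g", mean_D = mean(D)) {
  qk <- q[q != 0]
  structure(list(
    id = id, group = group, episode = "EXP",
    zeta = structure(list(q = q, zeta = zeta %||% (0.5 * q)),
                     class = "mf_scaling_exponents"),
    spectrum = structure(list(q = qk, h = h, D = D,
                              width = max(h) - min(h),
                              h_peak = h[which.max(D)], repaired = FALSE),
                         class = "mf_spectrum"),
    cumulants = structure(list(c1 = 0.5, c2 = -0.01, c3 = 0,
                               intercepts = c(0, 0, 0), C = NULL),
                          class = "mf_log_cumulants"),
    mean_D = mean_D,
    diagnostics = list()),
    class = "mf_result")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("t_compare handles identity, hand case, separation, zero variance", {
  a <- c(1, 2, 3, 4, 5)
  id <- t_compare(a, a, tail = "two_sided")
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  expect_equal(t_compare(a, a, tail = "greater")$p, 0.5)

  hand <- t_compare(a, a + 1, tail = "two_sided", variance_mode = "pooled")
  expect_equal(hand$t, -1)
  expect_equal(hand$df, 8)
  expect_equal(hand$p, 2 * pt(-1, 8), tolerance = 1e-12)

  sep <- t_compare(a + 100, a, tail = "greater")
  expect_lt(sep$p, 1e-6)

  zz <- t_compare(c(2, 2, 2), c(2, 2, 2))
  expect_equal(zz$p, 1)
  expect_equal(zz$t, 0)
  zd <- t_compare(c(3, 3, 3), c(2, 2, 2), tail = "greater")
  expect_equal(zd$p, 0)
  expect_error(t_compare(1, 1:3), ">= 2")
})

test_that("label swap flips t and complements one-sided p exactly", {
  set.seed(13)
  for (i in 1:10) {
    a <- rnorm(8, mean = runif(1, -1, 1))
    b <- rnorm(11, mean = runif(1, -1, 1))
    for (vm in c("welch", "pooled")) {
      f <- t_compare(a, b, tail = "greater", variance_mode = vm)
      r <- t_compare(b, a, tail = "greater", variance_mode = vm)
      expect_identical(f$t, -r$t)
      expect_equal(f$p + r$p, 1, tolerance = 1e-12)
      f2 <- t_compare(a, b, tail = "two_sided", variance_mode = vm)
      r2 <- t_compare(b, a, tail = "two_sided", variance_mode = vm)
      expect_equal(f2$p, r2$p, tolerance = 1e-12)
    }
  }
})

test_that("average_spectrum: identity, mirror symmetry, grid mismatch", {
  q <- seq(-2, 2, 0.5)
  qk <- q[q != 0]
  r1 <- fake_result(h = 0.5 - 0.05 * qk, D = 1 - 0.02 * qk^2, q = q)
  one <- average_spectrum(list(r1))
  expect_equal(one$h, r1$spectrum$h)
  expect_equal(one$D, r1$spectrum$D)
  expect_equal(one$width, r1$spectrum$width)

  r2 <- fake_result(h = 0.5 + 0.05 * qk, D = 1 - 0.02 * qk^2, q = q)
  mir <- average_spectrum(list(r1, r2))
  expect_equal(mir$h, rep(0.5, length(qk)))
  expect_equal(mir$width, 0)

  r3 <- fake_result(h = rep(0.5, 4), D = rep(1, 4), q = seq(-1, 1, 0.5))
  expect_error(average_spectrum(list(r1, r3)), "mixed q grids")
})

test_that("the mean spectrum of an fBm cohort peaks near its Hurst exponent", {
  cfg <- validation_config(2^12)
  results <- lapply(1:10, function(s) {
    mf_analyze(generate_fbm(synthetic_spec("fbm", n = 2^12, hurst = 0.7,
                                           seed = s)), cfg)
  })
  avg <- average_spectrum(results)
  expect_lt(abs(avg$h[which.max(avg$D)] - 0.7), 0.1)
})

test_that("compare_groups assembles a consistent report", {
  q <- seq(-2, 2, 0.5)
  qk <- q[q != 0]
  mk <- function(group, shift, id) {
    fake_result(h = 0.5 - 0.05 * qk + shift, D = 1 - 0.02 * qk^2,
                q = q, group = group, id = id,
                mean_D = mean(1 - 0.02 * qk^2) + shift)
  }
  res <- c(lapply(1:4, function(i) mk("h", 0.02 * i, paste0("h", i))),
           lapply(1:4, function(i) mk("u", -0.02 * i, paste0("u", i))))
  tab <- cohort_table(res)
  expect_equal(nrow(tab), 8)
  cmp <- compare_groups(tab, alpha = 0.05)
  expect_equal(unname(cmp$groups["a"]), "h")
  expect_true(all(cmp$tests$p >= 0 & cmp$tests$p <= 1))
  expect_identical(cmp$tests$reject, cmp$tests$p < 0.05)
  expect_equal(cmp$tests$tail[cmp$tests$descriptor == "mean_D"], "greater")
  expect_equal(cmp$width_difference, cmp$width_a - cmp$width_b)

  # two identical (copied) groups: exact null, no rejections
  res0 <- c(lapply(1:3, function(i) mk("h", 0.01 * i, paste0("h", i))),
            lapply(1:3, function(i) {
              r <- mk("h", 0.01 * i, paste0("u", i)); r$group <- "u"; r
            }))
  cmp0 <- compare_groups(cohort_table(res0))
  expect_true(all(cmp0$tests$p >= 0.5))
  expect_false(any(cmp0$tests$reject))

  expect_error(compare_groups(tab[, setdiff(names(tab), "c2")]), "c2")
  one_group <- tab; one_group$group <- "h"
  expect_error(compare_groups(one_group), "two group")
})

test_that("descriptor_long reshapes the cohort table", {
  q <- seq(-2, 2, 0.5)
  qk <- q[q != 0]
  res <- lapply(1:4, function(i) {
    fake_result(h = 0.5 - 0.05 * qk, D = 1 - 0.02 * qk^2, q = q,
                group = c("h", "u")[1 + i %% 2], id = paste0("s", i))
  })
  long <- descriptor_long(cohort_table(res))
  expect_equal(nrow(long), 6 * 4)
  expect_setequal(unique(long$descriptor),
                  c("width", "h_peak", "mean_D", "c1", "c2", "c3"))
})
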