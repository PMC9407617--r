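# Two-group statistical comparison of multifractal descriptors: a
# one-sided Student/Welch t-test on the per-signal mean of D(h) (direction:
# reference group larger) and two-sided tests on the log-cumulants, at a
# configurable significance level (default 5%). Spectrum widths of the
# group-average spectra are reported descriptively, without a test.

#' Tabulate per-signal descriptors for a cohort
#'
#' @param results list of `mf_result` objects (from [mf_analyze()]).
#' @return a `data.frame` with columns `id`, `group`, `episode`, `width`,
#'   `h_peak`, `mean_D`, `c1`, `c2`, `c3`; the full per-signal `(h, D)` and
#'   \eqn{\zeta(q)} arrays are kept in attributes `spectra` and `q_grid`
#'   for [average_spectrum()].
#' @export
cohort_table <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "mf_result")))
  df <- data.frame(
    id = vapply(results, function(r) r$id, ""),
    group = vapply(results, function(r) r$group, ""),
    episode = vapply(results, function(r) r$episode, ""),
    width = vapply(results, function(r) r$spectrum$width, 0),
    h_peak = vapply(results, function(r) r$spectrum$h_peak, 0),
    mean_D = vapply(results, function(r) r$mean_D, 0),
    c1 = vapply(results, function(r) r$cumulants$c1, 0),
    c2 = vapply(results, function(r) r$cumulants$c2, 0),
    c3 = vapply(results, function(r) r$cumulants$c3, 0),
    stringsAsFactors = FALSE
  )
  attr(df, "spectra") <- lapply(results, function(r)
    list(h = r$spectrum$h, D = r$spectrum$D, zeta = r$zeta$zeta))
  attr(df, "q_grid") <- results[[1]]$zeta$q
  df
}

#' Group-average multifractal spectrum
#'
#' Pointwise mean of \eqn{h(q)} and \eqn{D(q)} across signals at each
#' moment `q`, and the width (`max - min`) of the mean \eqn{h}.
#'
#' @param results list of `mf_result` objects sharing one `q` grid.
#' @return list with `q`, `h`, `D`, `width`.
#' @export
average_spectrum <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "mf_result")))
  q0 <- results[[1]]$spectrum$q
  same <- vapply(results, function(r)
    length(r$spectrum$q) == length(q0) &&
      max(abs(r$spectrum$q - q0)) < 1e-12, logical(1))
  if (!all(same)) stop("results have mixed q grids; cannot average")
  H <- vapply(results, function(r) r$spectrum$h, numeric(length(q0)))
  D <- vapply(results, function(r) r$spectrum$D, numeric(length(q0)))
  h_mean <- rowMeans(matrix(H, nrow = length(q0)))
  D_mean <- rowMeans(matrix(D, nrow = length(q0)))
  list(q = q0, h = h_mean, D = D_mean, width = max(h_mean) - min(h_mean))
}

#' Two-sample t comparison of one descriptor
#'
#' Student (pooled-variance) or Welch t-test, one-sided
#' (`tail = "greater"`: H1 is mean(a) > mean(b)) or two-sided. When both
#' samples have zero variance the t statistic is degenerate: the
#' convention is `p = 1`, `t = 0` for equal means and `p = 0`,
#' `t = +/-Inf` for unequal means.
#'
#' @param a,b numeric samples, each of length >= 2, finite.
#' @param tail `"two_sided"` or `"greater"`.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `df`, `p`, `mean_a`, `mean_b`, `sd_a`, `sd_b`,
#'   `n_a`, `n_b`, `tail`, `variance_mode`.
#' @export
#' @examples
#' t_compare(1:5, 2:6, tail = "two_sided", variance_mode = "pooled")$t # -1
t_compare <- function(a, b, tail = c("two_sided", "greater"),
                      variance_mode = c("welch", "pooled")) {
  tail <- match.arg(tail)
  variance_mode <- match.arg(variance_mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values")
  if (!all(is.finite(c(a, b)))) stop("non-finite values in samples")
  out <- list(mean_a = mean(a), mean_b = mean(b),
              sd_a = sd(a), sd_b = sd(b),
              n_a = length(a), n_b = length(b),
              tail = tail, variance_mode = variance_mode)
  if (sd(a) == 0 && sd(b) == 0) {
    if (mean(a) == mean(b)) {
      out$t <- 0; out$df <- length(a) + length(b) - 2; out$p <- 1
    } else {
      out$t <- sign(mean(a) - mean(b)) * Inf
      out$df <- length(a) + length(b) - 2
      out$p <- if (tail == "greater" && mean(a) < mean(b)) 1 else 0
    }
    return(out)
  }
  tt <- stats::t.test(a, b,
                      alternative = if (tail == "greater") "greater"
                                    else "two.sided",
                      var.equal = (variance_mode == "pooled"))
  out$t <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p <- unname(tt$p.value)
  out
}

#' Compare multifractal descriptors between two groups
#'
#' Runs [t_compare()] on `mean_D` (one-sided, H1: reference group larger)
#' and on `c1`, `c2`, `c3` (two-sided), assembles alpha-level decisions
#' (with an additional Bonferroni-adjusted column for transparency; the
#' primary decisions are per-test), and reports the group-average spectra
#' and their widths descriptively.
#'
#' The per-signal "mean of D(h)" is the mean of \eqn{D} over the moment
#' grid (q = 0 excluded); this definition is recorded in the report.
#'
#' @param table a [cohort_table()] (or data.frame with the descriptor
#'   columns and a `group` column with exactly two levels).
#' @param alpha significance level.
#' @param reference the group taken as "A" (direction of the one-sided
#'   test); default: first group label in table order.
#' @param variance_mode `"welch"` (default) or `"pooled"`.
#' @return an object of class `mf_comparison`: `tests` (data.frame with
#'   one row per descriptor), `alpha`, `groups`, `avg_spectrum_a/b` (NULL
#'   unless the table carries spectra), `width_a`, `width_b`,
#'   `width_difference`, `mean_D_definition`.
#' @export
compare_groups <- function(table, alpha = 0.05, reference = NULL,
                           variance_mode = c("welch", "pooled")) {
  variance_mode <- match.arg(variance_mode)
  needed <- c("group", "mean_D", "c1", "c2", "c3")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  groups <- unique(table$group)
  if (length(groups) != 2) {
    stop("exactly two group labels required; got ",
         paste(groups, collapse = ", "))
  }
  reference <- reference %||% groups[1]
  if (!reference %in% groups) stop("reference '", reference, "' not a group")
  other <- setdiff(groups, reference)
  ia <- table$group == reference
  ib <- table$group == other
  if (sum(ia) < 2 || sum(ib) < 2) stop("each group needs >= 2 signals")

  descriptors <- c("mean_D", "c1", "c2", "c3")
  tails <- c(mean_D = "greater", c1 = "two_sided", c2 = "two_sided",
             c3 = "two_sided")
  rows <- lapply(descriptors, function(d) {
    tc <- t_compare(table[[d]][ia], table[[d]][ib], tail = tails[[d]],
                    variance_mode = variance_mode)
    data.frame(descriptor = d, mean_a = tc$mean_a, mean_b = tc$mean_b,
               sd_a = tc$sd_a, sd_b = tc$sd_b, t = tc$t, df = tc$df,
               p = tc$p, tail = tc$tail, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$reject <- tests$p < alpha
  tests$p_bonferroni <- stats::p.adjust(tests$p, method = "bonferroni")
  tests$reject_bonferroni <- tests$p_bonferroni < alpha

  spectra <- attr(table, "spectra")
  avg_a <- avg_b <- NULL
  width_a <- width_b <- NA_real_
  if (!is.null(spectra)) {
    mean_spec <- function(idx) {
      H <- sapply(spectra[idx], function(s) s$h)
      D <- sapply(spectra[idx], function(s) s$D)
      h <- rowMeans(H); Dm <- rowMeans(D)
      list(h = h, D = Dm, width = max(h) - min(h))
    }
    avg_a <- mean_spec(which(ia))
    avg_b <- mean_spec(which(ib))
    width_a <- avg_a$width
    width_b <- avg_b$width
  }
  structure(
    list(tests = tests, alpha = alpha,
         groups = c(a = reference, b = other),
         variance_mode = variance_mode,
         avg_spectrum_a = avg_a, avg_spectrum_b = avg_b,
         width_a = width_a, width_b = width_b,
         width_difference = width_a - width_b,
         mean_D_definition =
           "per-signal mean of D over the moment grid (q = 0 excluded)"),
    class = "mf_comparison"
  )
}

#' @export
print.mf_comparison <- function(x, ...) {
  cat(sprintf("<mf_comparison> %s (A) vs %s (B), alpha = %g, %s t-test\n",
              x$groups["a"], x$groups["b"], x$alpha, x$variance_mode))
  if (!is.na(x$width_a)) {
    cat(sprintf("  average-spectrum widths: A = %.4f, B = %.4f (diff %.4f)\n",
                x$width_a, x$width_b, x$width_difference))
  }
  df <- x$tests
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-7s %-9s t = %8.3f  p = %-10.4g %s\n",
                df$descriptor[i], paste0("(", df$tail[i], ")"), df$t[i],
                df$p[i], if (df$reject[i]) "reject" else "accept"))
  }
  invisible(x)
}

# serializable form of a comparison report
comparison_to_list <- function(cmp) {
  list(groups = as.list(cmp$groups), alpha = cmp$alpha,
       variance_mode = cmp$variance_mode,
       mean_D_definition = cmp$mean_D_definition,
       width_a = cmp$width_a, width_b = cmp$width_b,
       width_difference = cmp$width_difference,
       tests = cmp$tests,
       avg_spectrum_a = cmp$avg_spectrum_a,
       avg_spectrum_b = cmp$avg_spectrum_b)
}

#' Write a comparison report as JSON
#'
#' @param cmp an `mf_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(cmp, path) {
  stopifnot(inherits(cmp, "mf_comparison"))
  jsonlite::write_json(comparison_to_list(cmp), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Long-format descriptor table for external plotting
#'
#' @param table a [cohort_table()].
#' @return data.frame with columns `descriptor`, `group`, `value`.
#' @export
descriptor_long <- function(table) {
  descriptors <- c("width", "h_peak", "mean_D", "c1", "c2", "c3")
  do.call(rbind, lapply(descriptors, function(d) {
    data.frame(descriptor = d, group = table$group, value = table[[d]],
               stringsAsFactors = FALSE)
  }))
}
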