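# Diagnostic figures (base graphics): example signal and cepstrum,
# group-average singularity spectra and scaling exponents, descriptor
# boxplots. Written as PNG by the pipeline; also usable interactively.

#' Plot group-average singularity spectra
#'
#' @param cmp an `mf_comparison` carrying average spectra, or a list of two
#'   spectra as returned by [average_spectrum()].
#' @param labels group labels for the legend.
#' @return invisibly, `NULL`.
#' @export
plot_average_spectra <- function(cmp, labels = NULL) {
  if (inherits(cmp, "mf_comparison")) {
    specs <- list(cmp$avg_spectrum_a, cmp$avg_spectrum_b)
    labels <- labels %||% unname(cmp$groups)
  } else {
    specs <- cmp
    labels <- labels %||% paste("group", seq_along(specs))
  }
  if (any(vapply(specs, is.null, logical(1)))) {
    stop("no average spectra available")
  }
  xr <- range(unlist(lapply(specs, `[[`, "h")))
  yr <- range(unlist(lapply(specs, `[[`, "D")))
  plot(NA, xlim = xr, ylim = yr, xlab = "h", ylab = "D(h)",
       main = "Average multifractal spectrum")
  for (i in seq_along(specs)) {
    lines(specs[[i]]$h, specs[[i]]$D, col = i, lwd = 2)
    points(specs[[i]]$h, specs[[i]]$D, col = i, pch = i)
  }
  legend("bottom", legend = labels, col = seq_along(specs),
         lwd = 2, pch = seq_along(specs), bty = "n")
  invisible(NULL)
}

#' Plot group-average scaling exponents
#'
#' @param results_by_group named list: one list of `mf_result` per group.
#' @return invisibly, `NULL`.
#' @export
plot_average_zeta <- function(results_by_group) {
  stopifnot(is.list(results_by_group), length(results_by_group) >= 1)
  curves <- lapply(results_by_group, function(rs) {
    q <- rs[[1]]$zeta$q
    z <- rowMeans(vapply(rs, function(r) r$zeta$zeta, numeric(length(q))))
    list(q = q, zeta = z)
  })
  xr <- range(unlist(lapply(curves, `[[`, "q")))
  yr <- range(unlist(lapply(curves, `[[`, "zeta")))
  plot(NA, xlim = xr, ylim = yr, xlab = "q", ylab = "zeta(q)",
       main = "Average scaling exponents")
  for (i in seq_along(curves)) {
    lines(curves[[i]]$q, curves[[i]]$zeta, col = i, lwd = 2)
  }
  legend("topleft", legend = names(results_by_group),
         col = seq_along(curves), lwd = 2, bty = "n")
  invisible(NULL)
}

#' Boxplots of per-signal descriptors by group
#'
#' @param table a [cohort_table()].
#' @param descriptors which descriptor columns to plot.
#' @return invisibly, `NULL`.
#' @export
plot_descriptor_boxplots <- function(table,
                                     descriptors = c("mean_D", "c1", "c2",
                                                     "c3")) {
  op <- par(mfrow = c(2, ceiling(length(descriptors) / 2)))
  on.exit(par(op))
  for (d in descriptors) {
    boxplot(table[[d]] ~ table$group, xlab = "group", ylab = d, main = d)
  }
  invisible(NULL)
}

# pipeline figure writer; returns named vector of paths
write_figures <- function(out_dir, cfg_hash, first_sig, first_cep, results,
                          table, comparisons) {
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  paths <- character()
  grab <- function(name, code) {
    p <- file.path(fig_dir, sprintf("%s_%s.png", name, cfg_hash))
    png(p, width = 900, height = 600)
    ok <- tryCatch({ code; TRUE },
                   error = function(e) FALSE)
    dev.off()
    if (ok) paths[name] <<- p else unlink(p)
  }
  if (!is.null(first_sig)) {
    grab("example_signal", {
      plot(first_sig$samples, type = "l", xlab = "sample", ylab = "value",
           main = paste("Example signal:", first_sig$id))
    })
  }
  if (!is.null(first_cep)) {
    grab("example_cepstrum", {
      plot(seq_along(first_cep$coefficients) - 1, first_cep$coefficients,
           type = "l", xlab = "quefrency (samples)", ylab = "value",
           main = paste("Real cepstrum:", first_cep$id))
    })
  }
  if (length(comparisons)) {
    grab("average_spectrum", plot_average_spectra(comparisons[[1]]))
  }
  groups <- split(results, vapply(results, function(r) r$group, ""))
  if (length(groups) >= 1) {
    grab("average_zeta", plot_average_zeta(groups))
  }
  grab("boxplots", plot_descriptor_boxplots(table))
  paths
}
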