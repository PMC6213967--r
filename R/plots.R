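sex_palette <- c(F = "#d62728", M = "#2ca02c", N = "#9467bd")

open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(path, width = width, height = height),
         pdf = grDevices::pdf(path, width = width, height = height),
         stop("unsupported image extension '.", ext, "' (use png/svg/pdf)"))
}

#' Scatter plot of the per-chromosome first principal components
#'
#' Plots each sample's chrX first-component score (X.PC1) against its chrY
#' first-component score (Y.PC1). Female-called samples sit in the
#' negative/negative corner, males in the positive/positive corner, and
#' N-samples — whose chrX and chrY assignments conflict — fall in the two
#' off-diagonal quadrants. Reference samples can be underlaid for context.
#'
#' @param calls A `sex_calls` object from [estimate_sex()].
#' @param include_reference Underlay the reference samples' coordinates;
#'   default `TRUE`.
#' @param out_path Optional image path (`.png`, `.svg` or `.pdf`); when
#'   `NULL`, draws on the current device.
#' @param main Plot title.
#' @return `out_path` (or `NULL`), invisibly.
#' @export
plot_sex_estimation <- function(calls, include_reference = TRUE,
                                out_path = NULL, main = "Sex estimation") {
  stopifnot(inherits(calls, "sex_calls"))
  if (nrow(calls) == 0L) stop("no calls to plot")
  ref <- attr(calls, "reference")
  if (!is.null(out_path)) {
    open_device(out_path, 6, 6)
    on.exit(grDevices::dev.off())
  }
  xs <- c(calls$X.PC1, if (include_reference) ref$X.PC1)
  ys <- c(calls$Y.PC1, if (include_reference) ref$Y.PC1)
  graphics::plot(NA, xlim = range(xs), ylim = range(ys),
                 xlab = "X.PC1", ylab = "Y.PC1", main = main)
  if (include_reference && !is.null(ref))
    graphics::points(ref$X.PC1, ref$Y.PC1, pch = 21, cex = 1.4,
                     col = "grey60",
                     bg = ifelse(ref$sex == "f", "#f7c5c5", "#c8e6c9"))
  pch <- ifelse(calls$predicted == "N", 4L, 19L)
  graphics::points(calls$X.PC1, calls$Y.PC1, pch = pch, lwd = 2,
                   col = sex_palette[calls$predicted])
  graphics::legend("topleft",
                   legend = c("F", "M", "N", if (include_reference) "reference"),
                   col = c(sex_palette, if (include_reference) "grey60"),
                   pch = c(19L, 19L, 4L, if (include_reference) 21L),
                   bty = "n")
  invisible(out_path)
}

#' @export
plot.sex_calls <- function(x, include_reference = TRUE, ...) {
  plot_sex_estimation(x, include_reference = include_reference, ...)
}

envelope <- function(mat) {
  apply(mat, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75), names = FALSE)
}

panel_lines <- function(ref_f, ref_m, query, xlab, main) {
  nb <- ncol(ref_f)
  x <- seq_len(nb)
  qf <- envelope(ref_f)
  qm <- envelope(ref_m)
  ylim <- range(0, qf, qm, query)
  graphics::plot(NA, xlim = c(1, nb), ylim = ylim, xlab = xlab,
                 ylab = "proportion of probes", main = main)
  graphics::polygon(c(x, rev(x)), c(qf[1L, ], rev(qf[3L, ])), border = NA,
                    col = grDevices::adjustcolor("#d62728", 0.25))
  graphics::polygon(c(x, rev(x)), c(qm[1L, ], rev(qm[3L, ])), border = NA,
                    col = grDevices::adjustcolor("#2ca02c", 0.25))
  graphics::lines(x, qf[2L, ], col = "#d62728", lty = 2)
  graphics::lines(x, qm[2L, ], col = "#2ca02c", lty = 2)
  graphics::lines(x, query, col = "#1f1f1f", lwd = 2)
}

#' Distribution line chart of a sample against the reference envelopes
#'
#' Three-panel line chart of the diagnostic distributions — chrX
#' beta-values, chrY beta-values, chrY detection p-values — for one query
#' sample, drawn over the reference panel's female (red) and male (green)
#' per-bin median lines and interquartile bands. A Klinefelter-signature
#' sample tracks the female envelope on chrX and the male envelopes on
#' chrY; a Turner-signature sample does the opposite.
#'
#' @param profiles A `sex_profiles` object containing the query sample.
#' @param panel A `sex_reference`; re-binned internally to the profiles'
#'   scheme.
#' @param sample_id Which sample of `profiles` to draw.
#' @param out_path Optional image path (`.png`, `.svg` or `.pdf`).
#' @return `out_path` (or `NULL`), invisibly.
#' @export
plot_sex_distribution <- function(profiles, panel, sample_id,
                                  out_path = NULL) {
  stopifnot(inherits(profiles, "sex_profiles"),
            inherits(panel, "sex_reference"))
  i <- match(sample_id, profiles$sample_ids)
  if (is.na(i)) stop("sample ", sample_id, " not found in profiles")
  ref <- rebin(panel, profiles$scheme)  # errors on scheme mismatch
  f <- panel$sex == "f"
  if (!is.null(out_path)) {
    open_device(out_path, 10, 3.6)
    on.exit(grDevices::dev.off())
  }
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)
  panel_lines(ref$chrX_beta[f, , drop = FALSE],
              ref$chrX_beta[!f, , drop = FALSE],
              profiles$chrX_beta[i, ], "beta-value bin (chrX)",
              paste0(sample_id, ": chrX beta"))
  panel_lines(ref$chrY_beta[f, , drop = FALSE],
              ref$chrY_beta[!f, , drop = FALSE],
              profiles$chrY_beta[i, ], "beta-value bin (chrY)",
              paste0(sample_id, ": chrY beta"))
  panel_lines(ref$chrY_detp[f, , drop = FALSE],
              ref$chrY_detp[!f, , drop = FALSE],
              profiles$chrY_detp[i, ], "detection-p bin (chrY)",
              paste0(sample_id, ": chrY detection p"))
  invisible(out_path)
}
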