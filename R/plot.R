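# Figures: positional variance diagrams in the magenta/green/cyan z-level
# palette, MCMC log-likelihood traces, and CVIC curves.

#' Render a positional variance diagram as a heatmap
#'
#' One row per biomarker and one column per stage position; the z = 1, 2, 3
#' event channels are drawn in magenta, green and cyan, with colour
#' intensity equal to the positional frequency across MCMC samples.
#'
#' @param pvd A [build_pvd()] result.
#' @param subtype Subtype index to draw.
#' @param file Optional PNG path; drawn to the active device otherwise.
#' @param main Plot title.
#' @return The RGB raster (invisibly).
#' @export
plot_pvd <- function(pvd, subtype = 1, file = NULL, main = NULL) {
  grid <- pvd$grid
  freq <- pvd$freq[[subtype]]
  K <- length(grid$biomarkers)
  N <- grid$n_events
  levels <- sort(unique(grid$events$level))
  palette <- list(
    c(1, 0, 1), # magenta
    c(0, 1, 0), # green
    c(0, 1, 1) # cyan
  )
  raster <- array(1, dim = c(K, N, 3))
  for (li in seq_along(levels)) {
    col <- palette[[((li - 1) %% length(palette)) + 1]]
    idx <- which(grid$events$level == levels[li])
    for (e in idx) {
      b <- grid$events$biomarker[e]
      f <- freq[e, ]
      for (ch in 1:3) {
        raster[b, , ch] <- raster[b, , ch] - f * (1 - col[ch])
      }
    }
  }
  raster[raster < 0] <- 0

  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = max(380, 140 + 30 * K), res = 110)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(4, 7, 3, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, N + 0.5), ylim = c(K + 0.5, 0.5))
  graphics::rasterImage(raster, 0.5, K + 0.5, N + 0.5, 0.5, interpolate = FALSE)
  graphics::axis(1, at = pretty(seq_len(N)))
  graphics::axis(2, at = seq_len(K), labels = grid$biomarkers, las = 2, cex.axis = 0.7)
  graphics::title(
    main = if (is.null(main)) sprintf("Subtype %d progression", subtype) else main,
    xlab = "stage position"
  )
  invisible(raster)
}

#' Plot the MCMC log-likelihood trace
#'
#' @param samples An [mcmc_sample()] result.
#' @param file Optional PNG path.
#' @export
plot_loglik_trace <- function(samples, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 400, res = 110)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(samples$loglik,
    type = "l", xlab = "MCMC iteration",
    ylab = "log-likelihood", main = "MCMC trace"
  )
  graphics::abline(v = samples$burn_in, lty = 2)
  invisible(NULL)
}

#' Plot the CVIC model-selection curve
#'
#' @param cvic A [cvic_select()] result.
#' @param file Optional PNG path.
#' @export
plot_cvic <- function(cvic, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 400, res = 110)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(seq_along(cvic$cvic), cvic$cvic,
    type = "b", xlab = "number of subtypes",
    ylab = "CVIC", main = "Cross-validated model selection"
  )
  graphics::points(cvic$chosen, cvic$cvic[cvic$chosen], pch = 19)
  invisible(NULL)
}
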