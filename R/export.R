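## Export and quick-look plotting helpers for the spectral objects and the
## discriminant biplot.

#' @export
as.data.frame.power_spectrum <- function(x, ...) {
  data.frame(frequency = x$frequencies, power = x$power)
}

#' @export
as.data.frame.cumulative_spectrum <- function(x, ...) {
  data.frame(frequency = x$frequencies, cumulative = x$cumulative)
}

#' Write a spectrum or cumulative curve as CSV
#'
#' @param x A `power_spectrum` or `cumulative_spectrum`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = ",", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @export
plot.power_spectrum <- function(x, band = NULL, ...) {
  sel <- if (is.null(band)) rep(TRUE, length(x$frequencies))
         else x$frequencies >= band[1L] & x$frequencies <= band[2L]
  graphics::plot(x$frequencies[sel], x$power[sel], type = "l",
                 xlab = "Frequency (Hz)", ylab = "Relative amplitude", ...)
  invisible(x)
}

#' @export
plot.cumulative_spectrum <- function(x, ...) {
  graphics::plot(x$frequencies, x$cumulative, type = "l",
                 xlab = "Frequency (Hz)", ylab = "Cumulative proportion", ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}

#' Draw the discriminant biplot
#'
#' LD1/LD2 scores coloured by class, feature loadings as arrows, and the
#' 95% class ellipses from [biplot_data()].
#'
#' @param model An [fit_lda()] model.
#' @param data Data frame with the model's features and class column.
#' @param arrow_scale Multiplier applied to the loading arrows.
#' @return The [biplot_data()] list, invisibly.
#' @export
lda_biplot <- function(model, data, arrow_scale = 2) {
  bp <- biplot_data(model, data)
  cl <- factor(data[[model$class]], levels = model$classes)
  graphics::plot(bp$scores, col = as.integer(cl), pch = 19,
                 xlab = sprintf("LD1 (%.1f%%)", 100 * model$proportion_of_trace[1L]),
                 ylab = sprintf("LD2 (%.1f%%)", 100 * model$proportion_of_trace[2L]))
  for (e in bp$ellipses) {
    th <- seq(0, 2 * pi, length.out = 120)
    rot <- cbind(cos(e$angle) * e$axes[1L] * cos(th) -
                   sin(e$angle) * e$axes[2L] * sin(th),
                 sin(e$angle) * e$axes[1L] * cos(th) +
                   cos(e$angle) * e$axes[2L] * sin(th))
    graphics::lines(sweep(rot, 2L, e$centre, "+"), lty = 3)
  }
  graphics::arrows(0, 0, arrow_scale * bp$loadings[, 1L],
                   arrow_scale * bp$loadings[, 2L], length = 0.08, col = "grey40")
  graphics::text(arrow_scale * bp$loadings[, 1L] * 1.12,
                 arrow_scale * bp$loadings[, 2L] * 1.12,
                 rownames(bp$loadings), cex = 0.8)
  graphics::legend("topright", legend = model$classes, pch = 19,
                   col = seq_along(model$classes), bty = "n", cex = 0.8)
  invisible(bp)
}
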