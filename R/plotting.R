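#' Standardize and scale an averaged signal for plotting
#'
#' Converts an averaged channel signal to integer plot ordinates:
#' `floor(gamma * (x - mean(x)) / sd(x))`, with the sample standard deviation
#' (denominator `n - 1`). Standardization makes the plotted waveform
#' independent of how many sequences were averaged; `gamma` sets how many
#' pixels one standard deviation spans (times 1/`gamma` uV per pixel on real
#' P300 amplitudes). Shift-invariant by construction.
#'
#' @param x Numeric vector (one location, one channel) in uV, length >= 2.
#' @param gamma Positive integer scale.
#' @return An object of class `std_signal` with integer `values`, plus the
#'   `mean_uV`, `sd_uV` and `gamma` used.
#' @export
standardize_signal <- function(x, gamma = 4L) {
  if (length(x) < 2L) abort("need at least 2 samples to standardize")
  stopifnot(gamma >= 1)
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("degenerate signal: zero variance, cannot standardize")
  }
  structure(list(values = as.integer(floor(gamma * (x - m) / s)),
                 mean_uV = m, sd_uV = s, gamma = as.integer(gamma)),
            class = "std_signal")
}

#' Vertical zero offset of a standardized signal
#'
#' The plot ordinate at which the signal's zero value sits so the whole trace
#' fits the canvas: `floor((max - min) / 2) - floor((max + min) / 2)`, both
#' floors over the integer standardized values.
#'
#' @param values Integer vector of standardized values.
#' @return Integer offset.
#' @export
zero_offset <- function(values) {
  if (length(values) == 0L) abort("zero_offset needs a nonempty vector")
  mx <- max(values)
  mn <- min(values)
  as.integer(floor((mx - mn) / 2) - floor((mx + mn) / 2))
}

#' Render the binary plot image of a standardized signal
#'
#' Draws the signal as white (255) pixels on black (0): sample `n` lands at
#' pixel column `x = gamma * n` and ordinate `values[n] + zero_offset`, and
#' consecutive sample pixels are joined with classic integer Bresenham
#' segments, so the trace is an 8-connected polyline. Ordinates map to image
#' rows screen-style with larger ordinate = lower row on screen (row index
#' grows with amplitude), so a positive P300 deflection plots downward. One
#' all-black pixel of padding is added around the tight ordinate range so
#' finite-difference gradients at the extremes have support.
#'
#' Pixel coordinates are 0-based: pixel `(x, y)` is matrix entry
#' `pixels[y + 1, x + 1]`.
#'
#' @param sig A `std_signal` from [standardize_signal()].
#' @param pad Black padding (pixels) above and below the tight range.
#' @return An object of class `plot_image`: binary matrix `pixels`
#'   (`height x width`, values 0/255), `zero_row` (0-based pixel row of signal
#'   zero), `gamma`, `n_max`.
#' @export
render_plot <- function(sig, pad = 1L) {
  stopifnot(inherits(sig, "std_signal"))
  v <- sig$values
  gamma <- sig$gamma
  n_max <- length(v)
  z <- zero_offset(v)
  ord <- v + z
  mn <- min(ord)
  mx <- max(ord)
  height <- (mx - mn + 1L) + 2L * pad
  width <- gamma * n_max + 1L
  px <- matrix(0L, nrow = height, ncol = width)
  xs <- gamma * seq_len(n_max)            # 0-based pixel columns
  ys <- ord - mn + pad                    # 0-based pixel rows
  for (i in seq_len(n_max - 1L)) {
    seg <- bresenham(xs[i], ys[i], xs[i + 1L], ys[i + 1L])
    px[cbind(seg[, 2] + 1L, seg[, 1] + 1L)] <- 255L
  }
  px[ys[n_max] + 1L, xs[n_max] + 1L] <- 255L
  structure(list(pixels = px, zero_row = as.integer(0L + z - mn + pad),
                 gamma = gamma, n_max = n_max),
            class = "plot_image")
}

#' Classic integer Bresenham line rasterization
#'
#' 8-connected midpoint line between two integer pixels, endpoints included.
#'
#' @param x0,y0,x1,y1 Integer pixel coordinates.
#' @return Integer matrix with columns `x`, `y`, one row per pixel, ordered
#'   from `(x0, y0)` to `(x1, y1)`.
#' @export
bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0)
  dy <- -abs(y1 - y0)
  sx <- if (x0 < x1) 1L else -1L
  sy <- if (y0 < y1) 1L else -1L
  err <- dx + dy
  n <- max(dx, -dy) + 1L
  out <- matrix(0L, nrow = n, ncol = 2, dimnames = list(NULL, c("x", "y")))
  x <- as.integer(x0); y <- as.integer(y0)
  for (i in seq_len(n)) {
    out[i, ] <- c(x, y)
    if (x == x1 && y == y1) break
    e2 <- 2L * err
    if (e2 >= dy) { err <- err + dy; x <- x + sx }
    if (e2 <= dx) { err <- err + dx; y <- y + sy }
  }
  out
}

#' @export
print.plot_image <- function(x, ...) {
  cat(sprintf("<plot_image> %d x %d binary pixels (zero row %d, gamma %d, n_max %d)\n",
              nrow(x$pixels), ncol(x$pixels), x$zero_row, x$gamma, x$n_max))
  invisible(x)
}

#' @export
as_tibble.plot_image <- function(x, ...) {
  idx <- which(x$pixels == 255L, arr.ind = TRUE)
  tibble(x = idx[, "col"] - 1L, y = idx[, "row"] - 1L)
}

#' Plot a rendered signal-plot image
#'
#' @param object A `plot_image`.
#' @param ... Ignored.
#' @return A ggplot showing white trace pixels on a black canvas, rows growing
#'   downward as on screen.
#' @export
autoplot.plot_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(fill = "white", width = 1, height = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "pixel column", y = "pixel row") +
    ggplot2::theme(panel.background = ggplot2::element_rect(fill = "black"),
                   panel.grid = ggplot2::element_blank())
}

#' Dump a plot image as a PNG file (debugging aid)
#'
#' @param image A `plot_image`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plot_png <- function(image, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("the png package is required for write_plot_png()")
  }
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}
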