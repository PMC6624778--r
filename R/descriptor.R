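#' Patch scale from the waveform geometry
#'
#' The descriptor patch is `12*s` pixels on a side; its physical coverage
#' follows from the plot geometry (`gamma` columns per sample, `gamma` rows
#' per standard deviation): `s_x = gamma * lambda * fs / 12` makes the patch
#' span `lambda` seconds horizontally, and `s_y = gamma * delta_uV / 12` makes
#' it span `delta_uV` microvolts vertically. The integer scale used downstream
#' is the rounded common value; a warning is raised if the two directions
#' disagree by more than 0.1.
#'
#' With `gamma = 4`, a 0.56-s span at 16 Hz and a 9-uV amplitude both give
#' `s = 3`: the 36x36 patch captures a whole P300 transient.
#'
#' @param gamma Plot scale.
#' @param lambda_s Temporal span to cover, seconds.
#' @param fs Working sampling rate, Hz.
#' @param delta_uV Peak-to-peak amplitude to cover, uV.
#' @return A list with `s_x`, `s_y` (real) and `s` (the rounded common
#'   integer scale).
#' @examples
#' patch_scale(gamma = 4, lambda_s = 0.56, fs = 16, delta_uV = 9)$s  # 3
#' @export
patch_scale <- function(gamma, lambda_s, fs, delta_uV) {
  stopifnot(gamma > 0, lambda_s > 0, fs > 0, delta_uV > 0)
  s_x <- gamma * lambda_s * fs / 12
  s_y <- gamma * delta_uV / 12
  if (abs(s_x - s_y) > 0.1) {
    warn(sprintf("horizontal and vertical patch scales differ: s_x = %.3f, s_y = %.3f",
                 s_x, s_y))
  }
  list(s_x = s_x, s_y = s_y, s = as.integer(round((s_x + s_y) / 2)))
}

#' A descriptor keypoint
#'
#' Centre pixel (0-based coordinates) and scale of the patch a descriptor
#' summarises; the patch extends `12*s` pixels, a 4x4 grid of `3*s`-pixel
#' blocks centred on the keypoint.
#'
#' @param x,y Integer pixel column / row (0-based).
#' @param s Integer patch scale.
#' @export
keypoint <- function(x, y, s = 3L) {
  structure(list(x = as.integer(x), y = as.integer(y), s = as.integer(s)),
            class = "keypoint")
}

#' Default keypoint of a signal-plot image
#'
#' Placed at pixel column `floor(0.55 * fs * gamma)` — 0.55 s into the epoch,
#' just past the P300 peak so the patch straddles the transient — and at the
#' row of the signal's zero line. At the 16 Hz working rate and `gamma = 4`
#' this is column 35.
#'
#' @param image A `plot_image`.
#' @param cfg A [run_config()].
#' @return A [keypoint()].
#' @export
default_keypoint <- function(image, cfg = run_config()) {
  stopifnot(inherits(image, "plot_image"))
  keypoint(x = floor(0.55 * cfg$target_fs * cfg$gamma),
           y = image$zero_row, s = cfg$s)
}

#' Pixel gradient field of a plot image by finite differences
#'
#' Central differences on interior pixels (`(I[r, c+1] - I[r, c-1]) / 2` and
#' the row analogue), one-sided differences on the borders. The angle is
#' measured counterclockwise from the +x (increasing column) axis with +y
#' pointing down the image (increasing row), mapped to `[0, 360)` degrees.
#' Where the magnitude is zero the angle carries no information.
#'
#' @param image A `plot_image` (or a plain numeric matrix), at least 3x3.
#' @return An object of class `gradient_field` with matrices `magnitude` and
#'   `angle` (degrees) of the image's shape.
#' @export
gradient_field <- function(image) {
  I <- if (inherits(image, "plot_image")) image$pixels else image
  I <- matrix(as.numeric(I), nrow = nrow(I))
  nr <- nrow(I); nc <- ncol(I)
  if (nr < 3L || nc < 3L) abort("image must be at least 3x3 for gradients")
  jx <- matrix(0, nr, nc)
  jx[, 2:(nc - 1)] <- (I[, 3:nc] - I[, 1:(nc - 2)]) / 2
  jx[, 1] <- I[, 2] - I[, 1]
  jx[, nc] <- I[, nc] - I[, nc - 1]
  jy <- matrix(0, nr, nc)
  jy[2:(nr - 1), ] <- (I[3:nr, ] - I[1:(nr - 2), ]) / 2
  jy[1, ] <- I[2, ] - I[1, ]
  jy[nr, ] <- I[nr, ] - I[nr - 1, ]
  ang <- atan2(jy, jx) * 180 / pi
  ang <- (ang + 360) %% 360
  structure(list(magnitude = sqrt(jx^2 + jy^2), angle = ang),
            class = "gradient_field")
}

# Angular interpolation weight: alpha_deg is the (unwrapped) difference
# between gradient angle and bin centre in degrees; the r in {-1,0,1} terms
# implement the circular wrap of the 8-bin linear interpolation.
w_ang <- function(alpha_deg) {
  z <- alpha_deg / 45
  pmax(0, 1 - abs(z - 8)) + pmax(0, 1 - abs(z)) + pmax(0, 1 - abs(z + 8))
}

#' Histogram-of-gradient-orientations descriptor of a patch
#'
#' Accumulates every pixel's gradient into a 4 (block rows) x 4 (block cols)
#' x 8 (45-degree angle bins) histogram with trilinear interpolation: the
#' pixel offset from the keypoint, normalized by the block size `3*s`, is
#' shared bilinearly between the up-to-4 adjacent blocks (bin centres at
#' -3/2, -1/2, 1/2, 3/2 block units) and the gradient angle linearly between
#' its 2 adjacent angle bins, each contribution weighted by the gradient
#' magnitude and the leading factor `3*s`. Pixels outside the image, or far
#' enough from the keypoint that all their spatial weights vanish, contribute
#' nothing.
#'
#' The 128 coordinates are laid out as `8 * (4 * i + j) + bin + 1` for block
#' row `i`, block column `j` (both 0-3, top-left origin) and angle bin
#' `theta / 45`.
#'
#' @param field A `gradient_field`.
#' @param kp A [keypoint()].
#' @return An object of class `hist_descriptor`: numeric `h` of length 128,
#'   `normalized = FALSE`, and the keypoint used.
#' @export
hist_descriptor <- function(field, kp) {
  stopifnot(inherits(field, "gradient_field"), inherits(kp, "keypoint"))
  M <- field$magnitude
  A <- field$angle
  nr <- nrow(M); nc <- ncol(M)
  bs <- 3 * kp$s
  # pixels with any nonzero spatial weight satisfy |offset| < 2.5 * block
  cols <- which(abs((seq_len(nc) - 1L) - kp$x) < 2.5 * bs)
  rows <- which(abs((seq_len(nr) - 1L) - kp$y) < 2.5 * bs)
  if (length(cols) == 0L || length(rows) == 0L) {
    abort("empty patch: keypoint does not intersect the image")
  }
  M <- M[rows, cols, drop = FALSE]
  A <- A[rows, cols, drop = FALSE]
  vx <- ((cols - 1L) - kp$x) / bs
  vy <- ((rows - 1L) - kp$y) / bs
  centers <- c(-3, -1, 1, 3) / 2
  wx <- lapply(centers, function(cj) pmax(0, 1 - abs(vx - cj)))  # per column
  wy <- lapply(centers, function(ci) pmax(0, 1 - abs(vy - ci)))  # per row
  theta <- 45 * (0:7)
  MA <- lapply(theta, function(th) M * w_ang(A - th))
  h <- numeric(128L)
  for (i in 0:3) {
    for (j in 0:3) {
      Wij <- outer(wy[[i + 1L]], wx[[j + 1L]])
      for (b in 0:7) {
        h[8L * (4L * i + j) + b + 1L] <- bs * sum(MA[[b + 1L]] * Wij)
      }
    }
  }
  structure(list(h = h, normalized = FALSE, keypoint = kp),
            class = "hist_descriptor")
}

#' Normalize a descriptor to the unit range
#'
#' Divides by the maximum absolute entry (for the nonnegative raw histogram
#' this lands in `[0, 1]`); the zero descriptor maps to itself. Idempotent.
#'
#' @param d A `hist_descriptor`.
#' @return The normalized descriptor.
#' @export
normalize_descriptor <- function(d) {
  stopifnot(inherits(d, "hist_descriptor"))
  if (isTRUE(d$normalized)) return(d)
  m <- max(abs(d$h))
  if (m > 0) d$h <- d$h / m
  d$normalized <- TRUE
  d
}

#' @export
print.hist_descriptor <- function(x, ...) {
  cat(sprintf("<hist_descriptor> 128 bins, %s (max %.3g)\n",
              if (isTRUE(x$normalized)) "normalized" else "raw", max(abs(x$h))))
  invisible(x)
}

#' Full signal-to-descriptor pipeline for one averaged channel signal
#'
#' Standardizes, renders the binary plot, computes the gradient field and the
#' normalized descriptor at the default keypoint. This is the per-location,
#' per-channel feature extraction step of the speller.
#'
#' @param x Numeric vector: one location's averaged signal on one channel, uV.
#' @param cfg A [run_config()].
#' @return A normalized `hist_descriptor`, or an error for degenerate
#'   (constant) signals.
#' @export
signal_descriptor <- function(x, cfg = run_config()) {
  sig <- standardize_signal(x, gamma = cfg$gamma)
  img <- render_plot(sig)
  normalize_descriptor(hist_descriptor(gradient_field(img), default_keypoint(img, cfg)))
}

#' Tabulate descriptors of all locations and channels of an averaged trial
#'
#' @param avg An `averaged_trial`.
#' @param cfg A [run_config()].
#' @return A tibble with `trial_id`, `location`, `channel`, and `d1`..`d128`;
#'   locations whose signal is degenerate on a channel are omitted.
#' @export
trial_descriptors <- function(avg, cfg = run_config()) {
  stopifnot(inherits(avg, "averaged_trial"))
  C <- dim(avg$x)[3]
  rows <- list()
  for (l in 1:12) {
    for (ch in seq_len(C)) {
      d <- tryCatch(signal_descriptor(avg$x[l, , ch], cfg),
                    error = function(e) NULL)
      if (is.null(d)) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(trial_id = avg$trial_id, location = l,
               channel = avg$channel_labels[ch]),
        tibble::as_tibble_row(stats::setNames(d$h, paste0("d", 1:128))))
    }
  }
  dplyr::bind_rows(rows)
}

#' Write / read a descriptor table as CSV
#'
#' @param tbl A tibble as returned by [trial_descriptors()].
#' @param path File path.
#' @export
write_descriptors_csv <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_descriptors_csv
#' @export
read_descriptors_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
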