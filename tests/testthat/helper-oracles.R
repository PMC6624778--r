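# Independent reference implementations used as oracles. These deliberately
# re-derive results from first principles (literal formulas, dense sampling,
# explicit sorting) and stay independent of the package code paths they check.

# Literal per-pixel evaluation of the trilinearly interpolated orientation
# histogram: iterate every pixel, evaluate the spatial and angular weights
# from their defining formulas, accumulate into h(theta, i, j), flatten as
# 8 * (4*i + j) + bin + 1. Coordinates are 0-based pixel (x, y).
oracle_descriptor <- function(mag, ang, kp_x, kp_y, s) {
  w <- function(z) max(0, 1 - abs(z))
  centers <- c(-3 / 2, -1 / 2, 1 / 2, 3 / 2)
  theta <- 45 * (0:7)
  h <- numeric(128)
  nr <- nrow(mag); nc <- ncol(mag)
  for (py in 0:(nr - 1)) {
    for (px in 0:(nc - 1)) {
      m <- mag[py + 1, px + 1]
      if (m == 0) next
      vx <- (px - kp_x) / (3 * s)
      vy <- (py - kp_y) / (3 * s)
      a <- ang[py + 1, px + 1]
      wang <- numeric(8)
      for (b in 0:7) {
        alpha <- (a - theta[b + 1]) * pi / 180   # radians, as printed
        wang[b + 1] <- w(8 * alpha / (2 * pi) - 8) +
          w(8 * alpha / (2 * pi)) + w(8 * alpha / (2 * pi) + 8)
      }
      for (i in 0:3) {
        wyi <- w(vy - centers[i + 1])
        if (wyi == 0) next
        for (j in 0:3) {
          wij <- w(vx - centers[j + 1]) * wyi
          if (wij == 0) next
          for (b in 0:7) {
            idx <- 8 * (4 * i + j) + b + 1
            h[idx] <- h[idx] + 3 * s * wang[b + 1] * wij * m
          }
        }
      }
    }
  }
  h
}

crop_field <- function(f, rows, cols) {
  structure(list(magnitude = f$magnitude[rows, cols, drop = FALSE],
                 angle = f$angle[rows, cols, drop = FALSE]),
            class = "gradient_field")
}

random_gradient_field <- function(nr = 36, nc = 36) {
  structure(list(magnitude = matrix(abs(rnorm(nr * nc)), nr, nc),
                 angle = matrix(runif(nr * nc, 0, 360), nr, nc)),
            class = "gradient_field")
}

# Dense parametric line sampling: walk the continuous segment in tiny steps
# and round to pixels. Used as the rasterization reference.
naive_line_pixels <- function(x0, y0, x1, y1, steps = 2000) {
  t <- seq(0, 1, length.out = steps)
  px <- unique(cbind(round(x0 + t * (x1 - x0)), round(y0 + t * (y1 - y0))))
  colnames(px) <- c("x", "y")
  px
}

chebyshev_within <- function(a, b, dist = 1) {
  # every row of a within Chebyshev distance `dist` of some row of b
  all(apply(a, 1, function(p) {
    any(pmax(abs(b[, 1] - p[1]), abs(b[, 2] - p[2])) <= dist)
  }))
}

is_8_connected_path <- function(px) {
  if (nrow(px) < 2) return(TRUE)
  d <- abs(diff(px))
  all(d <= 1) && all(rowSums(d) >= 1)
}

# Plain-loop k-NBNN re-implementation: explicit distances, explicit sort.
oracle_nbnn <- function(Q, Tm, k, metric = "cosine") {
  dist1 <- function(q, d) {
    if (metric == "cosine") {
      1 - sum(q * d) / (sqrt(sum(q^2)) * sqrt(sum(d^2)))
    } else {
      sum((q - d)^2)
    }
  }
  scores <- numeric(12)
  for (l in 1:12) {
    ds <- numeric(nrow(Tm))
    for (hh in seq_len(nrow(Tm))) ds[hh] <- dist1(Q[l, ], Tm[hh, ])
    ds <- sort(ds)
    scores[l] <- sum(ds[seq_len(min(k, length(ds)))])
  }
  list(row = which.min(scores[1:6]), col = 6 + which.min(scores[7:12]),
       scores = scores)
}

# Minimal hand-built template set around a 12 x 128 descriptor bank.
make_tset <- function(Tm, k = 7, metric = "cosine", bpc = "Cz") {
  n <- nrow(Tm)
  structure(list(
    templates = tibble::tibble(channel = bpc, trial_id = seq_len(n),
                               role = "row", location = 1L,
                               d = lapply(seq_len(n), function(i) Tm[i, ])),
    bpc = bpc, k = as.integer(k), metric = metric,
    channel_crr = tibble::tibble(channel = bpc, crr = NA_real_),
    cfg = run_config(k = k, metric = metric)),
    class = "template_set")
}

# A tiny hand-built session: zero (or given) samples at 16 Hz with
# well-formed intensification sequences.
tiny_session <- function(n_seq = 2, n_trials = 1, fs = 16, n_max = 16,
                         n_channels = 1, samples = NULL, perm_seed = 1) {
  set.seed(perm_seed)
  soa <- 4L   # samples between flashes
  ev <- list()
  t0 <- 0L
  for (tr in seq_len(n_trials)) {
    for (i in seq_len(n_seq)) {
      onsets <- t0 + (seq_len(12L) - 1L) * soa + 1L
      ev[[length(ev) + 1L]] <- tibble::tibble(
        sample_index = onsets, location = sample(1:12),
        sequence_index = i, trial_id = tr, is_target = NA)
      t0 <- t0 + 12L * soa
    }
    t0 <- t0 + n_max
  }
  ev <- do.call(rbind, ev)
  n <- max(ev$sample_index) + n_max
  if (is.null(samples)) {
    samples <- matrix(0, nrow = n, ncol = n_channels)
  }
  labels <- c("Fz", "Cz", "Pz", "Oz", "P3", "P4", "PO7", "PO8")[seq_len(n_channels)]
  eeg_session(samples, fs = fs, channel_labels = labels, events = ev)
}
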