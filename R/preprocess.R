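#' Signal enhancement: notch, lowpass, FIR decimation
#'
#' Runs the enhancement chain that lifts the P300 above basal EEG before
#' averaging: a mains notch filter, a 4th-order 10 Hz lowpass Butterworth, and
#' an order-30 FIR anti-alias decimation down to the working rate
#' (`cfg$target_fs`, 16 Hz by default). All filters are causal (forward-only),
#' as an online speller would run them. Event sample indices are rescaled by
#' the rate ratio, rounding toward the floor.
#'
#' When the input rate is an integer multiple of the target the decimator is
#' an order-30 lowpass FIR followed by sample picking; otherwise the rate is
#' converted by the equivalent rational-factor polyphase resampler (e.g.
#' 250 Hz -> 16 Hz by 8/125).
#'
#' @param session An [eeg_session()].
#' @param cfg A [run_config()].
#' @return A new [eeg_session()] at `cfg$target_fs` Hz.
#' @export
enhance_signal <- function(session, cfg = run_config()) {
  stopifnot(inherits(session, "eeg_session"))
  fs <- session$fs
  target <- cfg$target_fs
  if (fs < 2 * target) {
    abort(sprintf("invalid sampling rate: fs = %g Hz is below 2 x target rate (%g Hz)",
                  fs, 2 * target))
  }
  x <- session$samples
  if (cfg$notch_hz > 0 && cfg$notch_hz < fs / 2) {
    coefs <- notch_biquad(cfg$notch_hz, fs)
    x <- apply(x, 2, function(ch) as.numeric(signal::filter(coefs$b, coefs$a, ch)))
  }
  bw <- signal::butter(4, 10 / (fs / 2), type = "low")
  x <- apply(x, 2, function(ch) as.numeric(signal::filter(bw, ch)))

  ratio <- fs / target
  if (abs(ratio - round(ratio)) < 1e-9) {
    r <- as.integer(round(ratio))
    if (r > 1L) {
      h <- as.numeric(signal::fir1(30, 1 / r))
      h <- h / sum(h)   # unity DC gain
      x <- apply(x, 2, function(ch) as.numeric(signal::filter(h, 1, ch)))
      x <- x[seq(1L, nrow(x), by = r), , drop = FALSE]
    }
  } else {
    pq <- rational_factor(target, fs)
    x <- apply(x, 2, function(ch) as.numeric(signal::resample(ch, pq[1], pq[2])))
  }

  ev <- session$events
  if (nrow(ev) > 0L) {
    ev$sample_index <- as.integer(floor((ev$sample_index - 1L) / ratio) + 1L)
    ev <- ev[ev$sample_index <= nrow(x), , drop = FALSE]
  }
  eeg_session(x, fs = target, channel_labels = session$channel_labels,
              events = ev)
}

# RBJ cookbook second-order notch section; Q = 30 gives a ~f0/30 Hz stopband.
notch_biquad <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Smallest integers p/q with new_fs = fs * p / q.
rational_factor <- function(target, fs, max_den = 10000L) {
  scale <- 1e6
  p <- round(target * scale)
  q <- round(fs * scale)
  g <- gcd_int(p, q)
  p <- p / g; q <- q / g
  if (q > max_den) abort("cannot express rate conversion as a small rational factor")
  c(as.integer(p), as.integer(q))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Amplitude-based artifact rejection
#'
#' Scans every complete intensification sequence (its 12 flashes plus their
#' `t_max`-second epochs) and drops the whole sequence from the event list
#' whenever any channel sample within those epochs deviates beyond
#' `±cfg$artifact_uV` (strictly greater in absolute value). Samples are left
#' untouched. Trials that lose every sequence are reported in the
#' `flagged_trials` attribute of the result and trigger a warning; downstream
#' averaging refuses them.
#'
#' @param session An enhanced [eeg_session()].
#' @param cfg A [run_config()].
#' @return The session with offending sequences removed from `events`.
#' @export
reject_artifacts <- function(session, cfg = run_config()) {
  stopifnot(inherits(session, "eeg_session"))
  ev <- session$events
  if (nrow(ev) == 0L) return(session)
  n <- nrow(session$samples)
  n_max <- round(session$fs * cfg$t_max)
  absx <- abs(session$samples)
  groups <- dplyr::group_split(dplyr::group_by(ev, .data$trial_id, .data$sequence_index))
  keep <- vapply(groups, function(g) {
    idx <- unlist(lapply(g$sample_index, function(o) o:min(o + n_max - 1L, n)))
    !any(absx[idx, ] > cfg$artifact_uV)
  }, logical(1))
  kept <- dplyr::bind_rows(groups[keep])
  before <- unique(ev$trial_id)
  after <- unique(kept$trial_id)
  lost <- setdiff(before, after)
  out <- eeg_session(session$samples, session$fs, session$channel_labels, kept)
  attr(out, "flagged_trials") <- lost
  attr(out, "n_rejected_sequences") <- sum(!keep)
  if (length(lost) > 0L) {
    warn(sprintf("all sequences rejected for trial(s): %s",
                 paste(lost, collapse = ", ")))
  }
  out
}

#' Epoch segmentation into per-trial segment stacks
#'
#' For each trial and each surviving intensification sequence, extracts the 12
#' epochs of `n_max = fs * t_max` samples starting at each flash onset
#' (half-open windows `[onset, onset + n_max)`), and rearranges them by
#' location so indices 1-6 are row flashes and 7-12 column flashes. Sequences
#' whose epochs would run past the end of the recording are dropped.
#'
#' @param session An enhanced, artifact-filtered [eeg_session()].
#' @param cfg A [run_config()].
#' @param on_empty What to do when a trial has no usable sequence: `"error"`
#'   (default) aborts naming the trial; `"drop"` omits the trial with a
#'   warning.
#' @return A list of `trial_segments` objects, one per trial, each holding the
#'   array `segments[i, l, n, c]` (sequence, location, sample, channel) and
#'   `k_a_effective`, the number of sequences that survived.
#' @export
segment_trials <- function(session, cfg = run_config(),
                           on_empty = c("error", "drop")) {
  stopifnot(inherits(session, "eeg_session"))
  on_empty <- match.arg(on_empty)
  ev <- session$events
  if (nrow(ev) == 0L) abort("session has no events to segment")
  flagged <- attr(session, "flagged_trials") %||% integer()
  if (length(flagged) > 0L) {
    if (on_empty == "error") {
      abort(sprintf("no usable intensification sequence in trial %d",
                    flagged[1]))
    }
    warn(sprintf("dropping trial %s: no usable intensification sequence",
                 paste(flagged, collapse = ", ")))
  }
  n <- nrow(session$samples)
  C <- ncol(session$samples)
  n_max <- round(session$fs * cfg$t_max)
  trials <- sort(unique(ev$trial_id))
  out <- list()
  for (tid in trials) {
    tev <- ev[ev$trial_id == tid, , drop = FALSE]
    seqs <- sort(unique(tev$sequence_index))
    stacks <- list()
    used <- integer()
    for (si in seqs) {
      sev <- tev[tev$sequence_index == si, , drop = FALSE]
      if (max(sev$sample_index) + n_max - 1L > n) next
      seg <- array(0, dim = c(12L, n_max, C))
      for (r in seq_len(nrow(sev))) {
        o <- sev$sample_index[r]
        seg[sev$location[r], , ] <- session$samples[o:(o + n_max - 1L), , drop = FALSE]
      }
      stacks[[length(stacks) + 1L]] <- seg
      used <- c(used, si)
    }
    if (length(stacks) == 0L) {
      if (on_empty == "error") {
        abort(sprintf("no usable intensification sequence in trial %d", tid))
      }
      warn(sprintf("dropping trial %d: no usable intensification sequence", tid))
      next
    }
    segments <- array(0, dim = c(length(stacks), 12L, n_max, C))
    for (i in seq_along(stacks)) segments[i, , , ] <- stacks[[i]]
    out[[length(out) + 1L]] <- structure(
      list(trial_id = tid, segments = segments,
           k_a_effective = length(stacks), n_max = n_max,
           sequence_ids = used, channel_labels = session$channel_labels),
      class = "trial_segments")
  }
  out
}

#' @export
print.trial_segments <- function(x, ...) {
  cat(sprintf("<trial_segments> trial %d: %d sequence(s) x 12 locations x %d samples x %d channels\n",
              x$trial_id, x$k_a_effective, x$n_max, dim(x$segments)[4]))
  invisible(x)
}

#' Ensemble averaging of time-locked epochs
#'
#' Point-to-point mean over the stacked intensification sequences:
#' `x[l, n, c] = mean_i S[i, l, n, c]`. When sequences were rejected the mean
#' runs over the `k_a_effective` survivors.
#'
#' @param trial A `trial_segments` object from [segment_trials()].
#' @param k_a_used Optional cap: average only the first `k_a_used` surviving
#'   sequences (used for performance-vs-repetitions curves).
#' @return An `averaged_trial` with array `x[l, n, c]` (location, sample,
#'   channel) in uV.
#' @export
ensemble_average <- function(trial, k_a_used = NULL) {
  stopifnot(inherits(trial, "trial_segments"))
  k <- trial$k_a_effective
  if (!is.null(k_a_used)) k <- min(k, k_a_used)
  if (k < 1L) abort("k_a_effective must be at least 1")
  seg <- trial$segments[seq_len(k), , , , drop = FALSE]
  x <- apply(seg, c(2, 3, 4), mean)
  if (!all(is.finite(x))) abort("averaged trial contains non-finite values")
  structure(list(trial_id = trial$trial_id, x = x, k_a_used = k,
                 channel_labels = trial$channel_labels),
            class = "averaged_trial")
}

#' @export
print.averaged_trial <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf("<averaged_trial> trial %d: 12 locations x %d samples x %d channels (k_a = %d)\n",
              x$trial_id, d[2], d[3], x$k_a_used))
  invisible(x)
}
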