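#' Parameters of the synthetic oddball speller session
#'
#' Defaults emulate the recording conditions of a wet-electrode 6x6 visual
#' speller: 8 channels at 256 Hz, 0.125-s flashes with 0.125-s inter-stimulus
#' intervals, `k_a = 10` intensification sequences per letter, a positive
#' P300-like deflection peaking 300 ms after each target flash with a 400-ms
#' span and 5 uV peak amplitude, and pink (1/f) background noise of 28 uV
#' standard deviation — an SNR of about -15 dB, the regime reported for real
#' P300 recordings.
#'
#' @param word Target characters to spell (string or character vector).
#' @param n_channels Number of EEG channels.
#' @param channel_labels Channel names; defaults to the standard 10-20 montage
#'   Fz, Cz, Pz, Oz, P3, P4, PO7, PO8 (truncated/extended to `n_channels`).
#' @param fs Sampling frequency, Hz.
#' @param k_a Intensification sequences per trial.
#' @param flash_s Flash duration, s.
#' @param isi_s Inter-stimulus interval, s.
#' @param p300_amp_uV Peak amplitude of the evoked deflection, uV.
#' @param p300_latency_s Latency of the peak after flash onset, s.
#' @param p300_span_s Total span of the unimodal bump, s.
#' @param latency_jitter_s Half-width of the uniform latency jitter, s.
#' @param noise_sd_uV Standard deviation of the background noise, uV.
#' @param noise Background noise colour: `"pink"` (1/f, default) or
#'   `"white"`.
#' @param responsive_channels Labels of the channels carrying the evoked
#'   response; defaults to the centroparietal pair Cz, Pz (intersected with
#'   the available labels).
#' @param intertrial_s Pause after each trial, s (must fit the last epoch).
#' @param seed Integer RNG seed; same seed, same session, bit for bit.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(word = "HELLO", n_channels = 8L, channel_labels = NULL,
                       fs = 256, k_a = 10L, flash_s = 0.125, isi_s = 0.125,
                       p300_amp_uV = 5, p300_latency_s = 0.3,
                       p300_span_s = 0.4, latency_jitter_s = 0.02,
                       noise_sd_uV = 28, noise = c("pink", "white"),
                       responsive_channels = NULL, intertrial_s = 1.5,
                       seed = 1L) {
  noise <- match.arg(noise)
  if (length(word) == 1L) word <- strsplit(word, "")[[1]]
  stopifnot(flash_s + isi_s > 0, p300_amp_uV >= 0, noise_sd_uV >= 0,
            n_channels >= 1, k_a >= 1, fs > 0)
  std <- c("Fz", "Cz", "Pz", "Oz", "P3", "P4", "PO7", "PO8")
  if (is.null(channel_labels)) {
    channel_labels <- if (n_channels <= 8L) std[seq_len(n_channels)] else
      c(std, paste0("Ch", 9:n_channels))
  }
  stopifnot(length(channel_labels) == n_channels)
  if (is.null(responsive_channels)) {
    responsive_channels <- intersect(c("Cz", "Pz"), channel_labels)
    if (length(responsive_channels) == 0L) responsive_channels <- channel_labels[1]
  }
  structure(list(word = word, n_channels = as.integer(n_channels),
                 channel_labels = channel_labels, fs = fs,
                 k_a = as.integer(k_a), flash_s = flash_s, isi_s = isi_s,
                 p300_amp_uV = p300_amp_uV, p300_latency_s = p300_latency_s,
                 p300_span_s = p300_span_s,
                 latency_jitter_s = latency_jitter_s,
                 noise_sd_uV = noise_sd_uV, noise = noise,
                 responsive_channels = responsive_channels,
                 intertrial_s = intertrial_s, seed = as.integer(seed)),
            class = "sim_params")
}

# 1/f-amplitude-shaped Gaussian noise, scaled to the requested SD.
pink_noise <- function(n, sd_uV) {
  if (sd_uV == 0) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)           # symmetric frequency index, DC guarded
  W <- W / sqrt(f)
  x <- Re(fft(W, inverse = TRUE)) / n
  x <- x - mean(x)
  x * sd_uV / sd(x)
}

#' Simulate an oddball speller session with known ground truth
#'
#' Builds a complete copy-spelling session: for each letter of `params$word`,
#' `k_a` random 12-permutations of row/column flashes at the configured
#' cadence; per-channel background noise (pink by default); and, on the
#' responsive channels, a positive half-sine bump of span `p300_span_s`
#' peaking `p300_latency_s` (± uniform jitter) after every flash of the target
#' letter's row or column. Overlapping bumps from consecutive target flashes
#' add linearly. The stimulation log records every flash with its trial,
#' sequence, location and target flag, and always passes session validation.
#'
#' @param params A [sim_params()].
#' @param matrix A [speller_matrix()]; every word character must be in it.
#' @return An [eeg_session()] with `is_target` populated.
#' @examples
#' s <- simulate_session(sim_params(word = "AB", k_a = 2, seed = 7))
#' s
#' @export
simulate_session <- function(params = sim_params(), matrix = speller_matrix()) {
  stopifnot(inherits(params, "sim_params"))
  locs <- lapply(params$word, function(ch) letter_locations(matrix, ch))
  set.seed(params$seed)
  fs <- params$fs
  soa <- round((params$flash_s + params$isi_s) * fs)   # samples per flash slot
  flash_n <- max(1L, round(params$flash_s * fs))
  seq_n <- 12L * soa
  trial_n <- params$k_a * seq_n + round(params$intertrial_s * fs)
  lead_n <- round(1 * fs)
  n_total <- lead_n + length(params$word) * trial_n
  C <- params$n_channels

  ev <- list()
  bump_onsets <- list()
  for (t in seq_along(params$word)) {
    t0 <- lead_n + (t - 1L) * trial_n
    tgt <- locs[[t]]
    for (i in seq_len(params$k_a)) {
      perm <- sample(1:12)
      onsets <- t0 + (i - 1L) * seq_n + (seq_len(12L) - 1L) * soa + 1L
      is_t <- perm %in% c(tgt[["row"]], tgt[["col"]])
      ev[[length(ev) + 1L]] <- tibble(
        sample_index = as.integer(onsets), location = as.integer(perm),
        sequence_index = i, trial_id = t, is_target = is_t)
      bump_onsets[[length(bump_onsets) + 1L]] <- onsets[is_t]
    }
  }
  ev <- dplyr::bind_rows(ev)
  bump_onsets <- unlist(bump_onsets)

  erp <- numeric(n_total)
  if (params$p300_amp_uV > 0) {
    span_n <- round(params$p300_span_s * fs)
    half <- span_n / 2
    bump <- params$p300_amp_uV * sin(pi * seq_len(span_n) / (span_n + 1))
    for (o in bump_onsets) {
      jit <- runif(1, -params$latency_jitter_s, params$latency_jitter_s)
      start <- o + round((params$p300_latency_s + jit) * fs) - round(half)
      idx <- start:(start + span_n - 1L)
      ok <- idx >= 1L & idx <= n_total
      erp[idx[ok]] <- erp[idx[ok]] + bump[ok]
    }
  }

  samples <- matrix(0, nrow = n_total, ncol = C)
  for (c in seq_len(C)) {
    samples[, c] <- if (params$noise == "pink")
      pink_noise(n_total, params$noise_sd_uV)
    else rnorm(n_total, sd = params$noise_sd_uV)
  }
  resp <- match(params$responsive_channels, params$channel_labels)
  for (c in resp) samples[, c] <- samples[, c] + erp

  eeg_session(samples, fs = fs, channel_labels = params$channel_labels,
              events = ev)
}

#' Nominal SNR of the simulated P300, in dB
#'
#' Peak evoked amplitude over background standard deviation:
#' `20 * log10(p300_amp_uV / noise_sd_uV)`.
#'
#' @param params A [sim_params()].
#' @return SNR in dB.
#' @examples
#' snr_db(sim_params(p300_amp_uV = 5, noise_sd_uV = 28))  # about -15 dB
#' @export
snr_db <- function(params) {
  stopifnot(inherits(params, "sim_params"), params$noise_sd_uV > 0)
  20 * log10(params$p300_amp_uV / params$noise_sd_uV)
}
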