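cfg16 <- run_config()

test_that("the enhancement chain is linear, deterministic, and rate-checked", {
  s <- tiny_session(fs = 256, n_channels = 2)
  n <- nrow(s$samples)
  s$samples[] <- 0
  out <- enhance_signal(s, cfg16)
  expect_equal(out$fs, 16)
  expect_true(all(out$samples == 0))
  # deterministic: bit-identical on identical input
  s$samples[] <- rnorm(length(s$samples))
  expect_identical(enhance_signal(s, cfg16)$samples,
                   enhance_signal(s, cfg16)$samples)
  slow <- eeg_session(matrix(0, 64, 1), fs = 24, channel_labels = "Cz")
  expect_error(enhance_signal(slow, cfg16), "invalid sampling rate")
})

test_that("DC survives the chain and 20 Hz is strongly attenuated", {
  dc <- eeg_session(matrix(10, 1024, 1), fs = 256, channel_labels = "Cz")
  out <- enhance_signal(dc, cfg16)
  expect_equal(nrow(out$samples), 64)
  # causal filters settle; the tail must sit at the DC value (unity gain)
  expect_lt(max(abs(out$samples[49:64, 1] - 10)), 0.2)

  t <- (0:2047) / 256
  sine <- eeg_session(matrix(sin(2 * pi * 20 * t), ncol = 1), fs = 256,
                      channel_labels = "Cz")
  o <- enhance_signal(sine, cfg16)$samples[, 1]
  rms <- function(x) sqrt(mean(x^2))
  settled <- o[17:length(o)]
  measured <- rms(settled) / rms(sin(2 * pi * 20 * t))
  expect_lt(measured, 0.05)
  # consistency with the designed Butterworth magnitude response at 20 Hz
  butter_gain <- 1 / sqrt(1 + (20 / 10)^8)
  expect_lt(measured, butter_gain)
})

test_that("event indices rescale by the rate ratio with floor rounding", {
  ev <- tibble::tibble(sample_index = seq(1L, 45L, by = 4L) + 256L,
                       location = 1:12, sequence_index = 1L, trial_id = 1L,
                       is_target = NA)
  s <- eeg_session(matrix(rnorm(2048), ncol = 1), fs = 256,
                   channel_labels = "Cz", events = ev)
  out <- enhance_signal(s, cfg16)
  expect_equal(out$events$sample_index,
               as.integer(floor((ev$sample_index - 1L) / 16) + 1L))
})

test_that("artifact rejection drops exactly the contaminated sequences", {
  s <- tiny_session(n_seq = 3, n_channels = 2)
  expect_equal(nrow(reject_artifacts(s, cfg16)$events), 36L)

  # amplitudes everywhere just under threshold: nothing removed
  s$samples[] <- 69.9
  expect_equal(nrow(reject_artifacts(s, cfg16)$events), 36L)

  # a single +71 uV sample inside sequence 2's epochs (and reachable from no
  # other sequence's epochs) removes exactly those 12 events
  s$samples[] <- 0
  ev2 <- s$events[s$events$sequence_index == 2L, ]
  spike_at <- min(ev2$sample_index) + 20L
  s$samples[spike_at, 2] <- 71
  kept <- reject_artifacts(s, cfg16)$events
  expect_equal(nrow(kept), 24L)
  expect_equal(sort(unique(kept$sequence_index)), c(1L, 3L))

  # degenerate threshold 0: any nonzero sample kills its sequence
  cfg0 <- run_config(artifact_uV = 0)
  s0 <- tiny_session(n_seq = 2)
  s0$samples[5, 1] <- 1e-4
  kept0 <- reject_artifacts(s0, cfg0)$events
  expect_equal(sort(unique(kept0$sequence_index)), 2L)
})

test_that("a trial losing all sequences is flagged and warned about", {
  s <- tiny_session(n_seq = 1, n_trials = 2)
  s$samples[2, 1] <- 500   # inside trial 1, sequence 1 epochs only
  expect_warning(out <- reject_artifacts(s, cfg16), "trial")
  expect_equal(attr(out, "flagged_trials"), 1L)
  expect_error(segment_trials(out, cfg16), "trial 1")
  expect_warning(kept <- segment_trials(out, cfg16, on_empty = "drop"),
                 "dropping trial 1")
  expect_equal(length(kept), 1L)
})

test_that("segmentation uses half-open windows rearranged by location", {
  nmax <- 16L
  s <- tiny_session(n_seq = 2, n_max = nmax)
  s$samples[, 1] <- seq_len(nrow(s$samples))   # ramp encodes sample index
  trs <- segment_trials(s, cfg16)
  expect_length(trs, 1L)
  tr <- trs[[1]]
  expect_equal(dim(tr$segments), c(2L, 12L, nmax, 1L))
  ev <- s$events
  for (i in 1:2) {
    for (l in 1:12) {
      o <- ev$sample_index[ev$sequence_index == i & ev$location == l]
      expect_equal(tr$segments[i, l, , 1], as.numeric(o:(o + nmax - 1L)))
    }
  }
})

test_that("segment extraction is invariant to event order within a sequence", {
  s <- tiny_session(n_seq = 2, perm_seed = 42)
  s$samples[, 1] <- rnorm(nrow(s$samples))
  shuffled <- s
  ord <- sample(nrow(shuffled$events))
  shuffled$events <- shuffled$events[ord, ]
  a <- segment_trials(s, cfg16)[[1]]
  b <- segment_trials(shuffled, cfg16)[[1]]
  expect_equal(a$segments, b$segments)
})

test_that("a full 10-sequence trial yields 120 epochs", {
  s <- tiny_session(n_seq = 10)
  tr <- segment_trials(s, cfg16)[[1]]
  expect_equal(tr$k_a_effective * 12L, 120L)
})

test_that("epochs running past the recording end drop their sequence", {
  s <- tiny_session(n_seq = 2)
  # keep all events but cut the tail so sequence 2's last epoch cannot fit
  short <- eeg_session(s$samples[1:100, , drop = FALSE], s$fs,
                       s$channel_labels, s$events)
  tr <- segment_trials(short, cfg16)
  expect_equal(tr[[1]]$k_a_effective, 1L)
  expect_equal(tr[[1]]$sequence_ids, 1L)
})

test_that("ensemble averaging equals the naive per-point mean", {
  s <- tiny_session(n_seq = 4, n_channels = 2)
  s$samples[] <- rnorm(length(s$samples))
  tr <- segment_trials(s, cfg16)[[1]]
  avg <- ensemble_average(tr)
  # brute-force loop oracle
  ref <- array(0, dim = dim(tr$segments)[2:4])
  for (l in 1:12) for (n in 1:16) for (c in 1:2) {
    acc <- 0
    for (i in seq_len(tr$k_a_effective)) acc <- acc + tr$segments[i, l, n, c]
    ref[l, n, c] <- acc / tr$k_a_effective
  }
  expect_equal(avg$x, ref, tolerance = 1e-12)

  # averaging identical segments is the identity
  tr$segments[2, , , ] <- tr$segments[1, , , ]
  tr$segments[3, , , ] <- tr$segments[1, , , ]
  tr$segments[4, , , ] <- tr$segments[1, , , ]
  expect_equal(ensemble_average(tr)$x[1, , 1], tr$segments[1, 1, , 1])

  # two segments holding 0 and 2 average to 1
  tr$segments[1, , , ] <- 0
  tr$segments[2, , , ] <- 2
  tr2 <- tr; tr2$segments <- tr$segments[1:2, , , , drop = FALSE]
  tr2$k_a_effective <- 2L
  expect_true(all(ensemble_average(tr2)$x == 1))
})

test_that("averaging k_a i.i.d. noise sequences shrinks variance about 1/k_a", {
  set.seed(99)
  k_a <- 10L
  ratios <- replicate(200, {
    tr <- structure(list(trial_id = 1L,
                         segments = array(rnorm(k_a * 12 * 16), dim = c(k_a, 12, 16, 1)),
                         k_a_effective = k_a, n_max = 16L, sequence_ids = 1:k_a,
                         channel_labels = "Cz"),
                    class = "trial_segments")
    var(as.numeric(ensemble_average(tr)$x)) / var(as.numeric(tr$segments))
  })
  expect_gt(mean(ratios), 0.6 / k_a)
  expect_lt(mean(ratios), 1.4 / k_a)
})
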