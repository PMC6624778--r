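#' An EEG speller session
#'
#' Couples a multichannel recording with its stimulation log. The samples are
#' amplitudes in microvolts, one column per channel; the stimulation log is a
#' tibble of flash onsets, one row per intensification of one of the 12
#' locations of the speller matrix (rows 1-6, columns 7-12). Sample indices are
#' 1-based throughout, matching R's indexing.
#'
#' Within every `(trial_id, sequence_index)` pair the 12 logged locations must
#' form a permutation of 1..12 — one complete intensification sequence — and
#' construction fails otherwise, naming the offending trial and sequence.
#'
#' @param samples Numeric matrix, `n_samples x C`, amplitudes in uV.
#' @param fs Sampling frequency in Hz.
#' @param channel_labels Character vector of `C` unique channel names
#'   (10-20 system names such as "Cz").
#' @param events Tibble (or data frame) with columns `sample_index` (1-based
#'   flash-onset sample), `location` (1-12), `sequence_index` (1..k_a within
#'   the trial), `trial_id`, and optionally `is_target` (logical; known in
#'   copy-spelling, `NA` otherwise).
#'
#' @return An object of class `eeg_session`.
#' @export
eeg_session <- function(samples, fs, channel_labels, events = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(events) || nrow(events) == 0L) {
    events <- tibble(sample_index = integer(), location = integer(),
                     sequence_index = integer(), trial_id = integer(),
                     is_target = logical())
  }
  events <- as_tibble(events)
  if (!"is_target" %in% names(events)) events$is_target <- NA
  events <- events[, c("sample_index", "location", "sequence_index",
                       "trial_id", "is_target")]
  events$sample_index <- as.integer(events$sample_index)
  events$location <- as.integer(events$location)
  events$sequence_index <- as.integer(events$sequence_index)
  events$trial_id <- as.integer(events$trial_id)
  events$is_target <- as.logical(events$is_target)
  colnames(samples) <- channel_labels
  x <- structure(list(samples = samples, fs = fs,
                      channel_labels = as.character(channel_labels),
                      events = events),
                 class = "eeg_session")
  validate_eeg_session(x)
}

validate_eeg_session <- function(x) {
  C <- ncol(x$samples)
  if (C < 1L) abort("session must have at least one channel")
  if (!is.numeric(x$fs) || length(x$fs) != 1L || x$fs <= 0) {
    abort("fs must be a positive scalar")
  }
  if (length(x$channel_labels) != C) abort("one label per channel required")
  if (anyDuplicated(x$channel_labels)) abort("channel labels must be unique")
  ev <- x$events
  n <- nrow(x$samples)
  if (nrow(ev) > 0L) {
    if (any(ev$sample_index < 1L | ev$sample_index > n)) {
      abort("event sample_index out of recording range")
    }
    if (any(!ev$location %in% 1:12)) abort("event locations must be in 1..12")
    bad <- dplyr::group_by(ev, .data$trial_id, .data$sequence_index)
    bad <- dplyr::summarise(bad,
      ok = dplyr::n() == 12L && setequal(.data$location, 1:12),
      .groups = "drop")
    bad <- dplyr::filter(bad, !.data$ok)
    if (nrow(bad) > 0L) {
      abort(sprintf(
        "intensification sequence is not a 12-location permutation (trial %d, sequence %d)",
        bad$trial_id[1], bad$sequence_index[1]))
    }
  }
  x
}

#' @export
print.eeg_session <- function(x, ...) {
  cat(sprintf("<eeg_session> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  cat(sprintf("  channels: %s\n", paste(x$channel_labels, collapse = ", ")))
  cat(sprintf("  events: %d flashes, %d trial(s)\n", nrow(x$events),
              length(unique(x$events$trial_id))))
  invisible(x)
}

#' @export
as_tibble.eeg_session <- function(x, ...) {
  session_to_frame(x)
}

# CSV-shaped frame: Time, channels..., StimCode, Trial, IsTarget.
# StimCode/Trial/IsTarget are written on the onset row only.
session_to_frame <- function(session) {
  n <- nrow(session$samples)
  df <- as_tibble(as.data.frame(session$samples))
  names(df) <- session$channel_labels
  df <- dplyr::bind_cols(tibble(Time = (seq_len(n) - 1) / session$fs), df)
  df$StimCode <- 0L
  df$Trial <- 0L
  df$IsTarget <- NA_integer_
  ev <- session$events
  if (nrow(ev) > 0L) {
    df$StimCode[ev$sample_index] <- ev$location
    df$Trial[ev$sample_index] <- ev$trial_id
    df$IsTarget[ev$sample_index] <- as.integer(ev$is_target)
  }
  df
}

#' Read an EEG speller session from its native CSV form
#'
#' The native session file is a plain UTF-8 CSV with a header row and columns
#' `Time`, one per channel, `StimCode` (0, or 1-12 while a location flashes),
#' `Trial` (trial id at/during the flash) and optionally `IsTarget` (0/1).
#' A flash onset is the *first* sample of a run of equal nonzero stimulus
#' codes, so codes held for the whole flash duration collapse to one event.
#' Sequence indices are inferred per trial: consecutive groups of 12 onsets in
#' temporal order are sequences 1, 2, ...
#'
#' @param path CSV file path.
#' @return A validated [eeg_session()].
#' @export
read_session_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("session file not found: ", path))
  # base parser: correctly-rounded doubles, so write/read/write is stable
  df <- as_tibble(utils::read.csv(path, check.names = FALSE))
  required <- c("Time", "StimCode", "Trial")
  if (!all(required %in% names(df))) {
    abort(paste0("malformed session header: need columns ",
                 paste(required, collapse = ", "),
                 " plus at least one channel column"))
  }
  chans <- setdiff(names(df), c("Time", "StimCode", "Trial", "IsTarget"))
  if (length(chans) < 1L) abort("malformed session header: no channel columns")
  n <- nrow(df)
  if (n < 2L) abort("session file too short to infer sampling rate")
  fs <- 1 / stats::median(diff(df$Time))
  fs <- round(fs, 6)
  code <- as.integer(df$StimCode)
  onset <- which(code > 0L & c(TRUE, diff(code) != 0L | code[-n] == 0L))
  ev <- NULL
  if (length(onset) > 0L) {
    trial <- as.integer(df$Trial[onset])
    tgt <- if ("IsTarget" %in% names(df)) df$IsTarget[onset] == 1 else
      rep(NA, length(onset))
    ord <- order(onset)
    ev <- tibble(sample_index = onset[ord], location = code[onset][ord],
                 trial_id = trial[ord], is_target = tgt[ord])
    ev <- dplyr::group_by(ev, .data$trial_id)
    ev <- dplyr::mutate(ev,
      sequence_index = as.integer((dplyr::row_number() - 1L) %/% 12L + 1L))
    ev <- dplyr::ungroup(ev)
  }
  eeg_session(as.matrix(df[, chans, drop = FALSE]), fs = fs,
              channel_labels = chans, events = ev)
}

#' Write an EEG speller session to the native CSV form
#'
#' Amplitudes are serialised with full double precision (well beyond 6
#' significant digits) and the event list round-trips exactly through
#' [read_session_csv()].
#'
#' @param session An [eeg_session()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session_csv <- function(session, path) {
  stopifnot(inherits(session, "eeg_session"))
  df <- session_to_frame(session)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Adapter for the public ALS speller dataset (008-2014, BNCI Horizon)
#'
#' Best-effort reader for the 8-channel, 256 Hz ALS patient recordings
#' distributed as MATLAB files. The surrounding pipeline never requires it:
#' every other entry point works from the native CSV format. This build has no
#' MATLAB container reader available, so the adapter currently reports an
#' explicit unsupported-format error for any input; convert the recording to
#' the native session CSV to use it.
#'
#' @param path Path to a `.mat` file in the 008-2014 layout.
#' @return An [eeg_session()] with `is_target` populated (when supported).
#' @export
read_bnci_mat <- function(path) {
  if (!grepl("\\.mat$", path, ignore.case = TRUE)) {
    abort(paste0("unsupported format: expected a .mat file, got ", path))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  abort(paste0(
    "unsupported format: no MATLAB container reader is available in this ",
    "build; export the recording to the native session CSV (see ",
    "?read_session_csv) and use that instead"))
}
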