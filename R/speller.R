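#' @keywords internal
descriptor_distance <- function(q, d, metric = "cosine") {
  if (metric == "cosine") {
    nq <- sqrt(sum(q * q)); nd <- sqrt(sum(d * d))
    if (nq == 0 || nd == 0) return(1)
    1 - sum(q * d) / (nq * nd)
  } else {
    sum((q - d)^2)
  }
}

# distances from one query vector to the rows of a template matrix
query_distances <- function(q, Tm, metric = "cosine") {
  if (metric == "cosine") {
    nq <- sqrt(sum(q * q))
    nd <- sqrt(rowSums(Tm * Tm))
    s <- as.numeric(Tm %*% q)
    out <- rep(1, nrow(Tm))
    ok <- nd > 0 & nq > 0
    out[ok] <- 1 - s[ok] / (nd[ok] * nq)
    out
  } else {
    rowSums(sweep(Tm, 2, q)^2)
  }
}

# Preprocess a raw session into per-trial segment stacks:
# enhance -> artifact rejection -> segmentation.
preprocess_session <- function(session, cfg = run_config()) {
  enh <- enhance_signal(session, cfg)
  rej <- withCallingHandlers(reject_artifacts(enh, cfg),
                             warning = function(w) invokeRestart("muffleWarning"))
  trials <- withCallingHandlers(segment_trials(rej, cfg, on_empty = "drop"),
                                warning = function(w) invokeRestart("muffleWarning"))
  list(trials = trials,
       n_rejected = attr(rej, "n_rejected_sequences") %||% 0L,
       flagged_trials = attr(rej, "flagged_trials") %||% integer())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 12 x 128 query matrix for one channel of an averaged trial; degenerate
# locations yield NA rows.
channel_queries <- function(avg, ch_index, cfg) {
  Q <- matrix(NA_real_, nrow = 12L, ncol = 128L)
  for (l in 1:12) {
    d <- tryCatch(signal_descriptor(avg$x[l, , ch_index], cfg),
                  error = function(e) NULL)
    if (!is.null(d)) Q[l, ] <- d$h
  }
  Q
}

nbnn_scores <- function(Q, Tm, k, metric) {
  k_eff <- min(k, nrow(Tm))
  vapply(1:12, function(l) {
    q <- Q[l, ]
    if (anyNA(q)) return(Inf)
    sum(sort(query_distances(q, Tm, metric))[seq_len(k_eff)])
  }, numeric(1))
}

#' k-NBNN row/column decision for one trial
#'
#' For each of the 12 locations, sorts the calibration templates of the best
#' performing channel by distance to that location's query descriptor and sums
#' the `k` nearest distances; the predicted row is the argmin over locations
#' 1-6 and the predicted column the argmin over 7-12 (ties broken by the
#' lowest location index). The distance is the cosine distance by default
#' (`tset$metric`). If fewer than `k` templates exist, `k` is truncated with a
#' warning.
#'
#' @param queries 12 x 128 numeric matrix of normalized query descriptors
#'   (row `l` = location `l`, channel `tset$bpc`), or a list of 12
#'   `hist_descriptor`s. `NA` rows (degenerate locations) score `Inf`.
#' @param tset A `template_set` from [calibrate()].
#' @param matrix A [speller_matrix()] used to name the predicted letter.
#' @return A one-row tibble: `row_hat`, `col_hat`, `letter`, `score_1` ..
#'   `score_12` (the accumulated distances).
#' @export
nbnn_decide <- function(queries, tset, matrix = speller_matrix()) {
  stopifnot(inherits(tset, "template_set"))
  if (is.list(queries) && !is.matrix(queries)) {
    queries <- do.call(rbind, lapply(queries, function(d) d$h))
  }
  stopifnot(is.matrix(queries), nrow(queries) == 12L, ncol(queries) == 128L)
  Tm <- template_matrix(tset, tset$bpc)
  if (nrow(Tm) < tset$k) {
    warn(sprintf("only %d templates available; truncating k from %d",
                 nrow(Tm), tset$k))
  }
  scores <- nbnn_scores(queries, Tm, tset$k, tset$metric)
  row_hat <- which.min(scores[1:6])
  col_hat <- 6L + which.min(scores[7:12])
  out <- tibble(row_hat = as.integer(row_hat), col_hat = as.integer(col_hat),
                letter = matrix_letter(matrix, row_hat, col_hat))
  dplyr::bind_cols(out, tibble::as_tibble_row(
    stats::setNames(scores, paste0("score_", 1:12))))
}

template_matrix <- function(tset, channel) {
  rows <- tset$templates[tset$templates$channel == channel, , drop = FALSE]
  do.call(rbind, rows$d)
}

#' Calibration: template-set construction and channel selection
#'
#' For every calibration trial and every channel, extracts the two descriptors
#' at the instructed letter's row and column locations — the P300 templates —
#' and pools them per channel into the template set `T^c`. The best performing
#' channel (`bpc`) is the channel with the highest character recognition rate
#' under leave-one-trial-out evaluation within the calibration set
#' (self-templates excluded; ties go to the earlier channel).
#'
#' @param x An [eeg_session()] (preprocessed internally), or a list of
#'   `averaged_trial` objects already averaged.
#' @param targets The instructed letters, as a character vector (one per
#'   trial, in trial-id order) or a single string.
#' @param matrix A [speller_matrix()].
#' @param cfg A [run_config()].
#' @return An object of class `template_set`: tibble `templates` (`channel`,
#'   `trial_id`, `role`, `location`, list-column `d` of 128-vectors), `bpc`,
#'   `k`, `metric`, and the per-channel leave-one-out calibration CRR in
#'   `channel_crr`.
#' @export
calibrate <- function(x, targets, matrix = speller_matrix(), cfg = run_config()) {
  if (length(targets) == 1L && nchar(targets[1]) > 1L) {
    targets <- strsplit(targets, "")[[1]]
  }
  if (inherits(x, "eeg_session")) {
    prep <- preprocess_session(x, cfg)
    avg <- lapply(prep$trials, ensemble_average, k_a_used = cfg$k_a)
  } else {
    avg <- x
    stopifnot(all(vapply(avg, inherits, TRUE, "averaged_trial")))
  }
  n_trials <- length(avg)
  if (n_trials < 2L) {
    abort("calibration needs at least 2 trials (leave-one-out channel selection)")
  }
  if (length(targets) != n_trials) {
    abort(sprintf("got %d target letters for %d calibration trials",
                  length(targets), n_trials))
  }
  channels <- avg[[1]]$channel_labels
  locs <- lapply(targets, function(ch) letter_locations(matrix, ch))

  # all queries once: D[[t]][[c]] is 12 x 128 (NA rows where degenerate)
  D <- lapply(avg, function(a) {
    lapply(seq_along(channels), function(ci) channel_queries(a, ci, cfg))
  })

  templates <- list()
  for (t in seq_len(n_trials)) {
    for (ci in seq_along(channels)) {
      for (role in c("row", "col")) {
        l <- locs[[t]][[role]]
        dvec <- D[[t]][[ci]][l, ]
        if (anyNA(dvec)) {
          warn(sprintf("degenerate signal skipped: trial %d, channel %s, location %d",
                       avg[[t]]$trial_id, channels[ci], l))
          next
        }
        templates[[length(templates) + 1L]] <- tibble(
          channel = channels[ci], trial_id = avg[[t]]$trial_id,
          role = role, location = l, d = list(dvec))
      }
    }
  }
  templates <- dplyr::bind_rows(templates)

  crr <- vapply(seq_along(channels), function(ci) {
    correct <- vapply(seq_len(n_trials), function(t) {
      keep <- templates$channel == channels[ci] &
        templates$trial_id != avg[[t]]$trial_id
      Tm <- do.call(rbind, templates$d[keep])
      if (is.null(Tm) || nrow(Tm) == 0L) return(FALSE)
      scores <- nbnn_scores(D[[t]][[ci]], Tm, cfg$k, cfg$metric)
      r <- which.min(scores[1:6]); cc <- 6L + which.min(scores[7:12])
      matrix_letter(matrix, r, cc) == targets[t]
    }, logical(1))
    100 * mean(correct)
  }, numeric(1))

  bpc <- channels[which.max(crr)]
  structure(list(templates = templates, bpc = bpc, k = cfg$k,
                 metric = cfg$metric,
                 channel_crr = tibble(channel = channels, crr = crr),
                 cfg = cfg),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d templates on %d channel(s); bpc = %s (calibration CRR %.1f%%), k = %d, %s distance\n",
              nrow(x$templates), length(unique(x$templates$channel)), x$bpc,
              x$channel_crr$crr[x$channel_crr$channel == x$bpc], x$k, x$metric))
  invisible(x)
}

#' @export
tidy.template_set <- function(x, ...) {
  dplyr::select(x$templates, "channel", "trial_id", "role", "location")
}

#' @export
glance.template_set <- function(x, ...) {
  tibble(bpc = x$bpc,
         calibration_crr = x$channel_crr$crr[x$channel_crr$channel == x$bpc],
         n_templates = nrow(x$templates), k = x$k, metric = x$metric)
}

#' Decode the letters of a session with a calibrated template set
#'
#' Runs the full chain per trial — enhancement, artifact rejection,
#' segmentation, ensemble averaging over the first `k_a_used` surviving
#' sequences, plotting, descriptor extraction on the best performing channel,
#' and the k-NBNN decision. Trials that fail (e.g. every location degenerate)
#' yield an `NA` letter rather than aborting the run.
#'
#' @param session An [eeg_session()].
#' @param tset A `template_set` from [calibrate()].
#' @param matrix A [speller_matrix()].
#' @param cfg A [run_config()].
#' @param k_a_used How many surviving sequences to average (default: all up
#'   to `cfg$k_a`).
#' @return A tibble with one row per trial: `trial_id`, `row_hat`, `col_hat`,
#'   `letter`, `score_1` .. `score_12`.
#' @export
identify_letter <- function(session, tset, matrix = speller_matrix(),
                            cfg = run_config(), k_a_used = NULL) {
  stopifnot(inherits(session, "eeg_session"))
  prep <- preprocess_session(session, cfg)
  decode_segments(prep$trials, tset, matrix, cfg, k_a_used)
}

decode_segments <- function(trials, tset, matrix, cfg, k_a_used = NULL) {
  stopifnot(inherits(tset, "template_set"))
  bpc_index <- function(labels) match(tset$bpc, labels)
  rows <- lapply(trials, function(tr) {
    res <- tryCatch({
      avg <- ensemble_average(tr, k_a_used = k_a_used %||% cfg$k_a)
      ci <- bpc_index(avg$channel_labels)
      if (is.na(ci)) abort(paste0("channel not present in session: ", tset$bpc))
      Q <- channel_queries(avg, ci, cfg)
      if (all(is.na(Q))) abort("all locations degenerate")
      pred <- nbnn_decide(Q, tset, matrix)
      dplyr::bind_cols(tibble(trial_id = tr$trial_id), pred)
    }, error = function(e) {
      warn(sprintf("trial %d failed: %s", tr$trial_id, conditionMessage(e)))
      dplyr::bind_cols(
        tibble(trial_id = tr$trial_id, row_hat = NA_integer_,
               col_hat = NA_integer_, letter = NA_character_),
        tibble::as_tibble_row(stats::setNames(rep(NA_real_, 12),
                                              paste0("score_", 1:12))))
    })
    res
  })
  dplyr::bind_rows(rows)
}
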