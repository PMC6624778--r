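#' Character recognition rate
#'
#' Percentage of correctly decoded letters. Trials whose pipeline failed
#' (`NA` prediction) count as errors in the denominator, so the rate reflects
#' usable performance; failures are reported separately in the evaluation
#' report.
#'
#' @param predicted Character vector of decoded letters (may contain `NA`).
#' @param actual Character vector of instructed letters, same length.
#' @return CRR in percent (0-100).
#' @export
crr <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  if (length(actual) == 0L) return(NA_real_)
  100 * sum(!is.na(predicted) & predicted == actual) / length(actual)
}

#' Wolpaw information transfer rate, bits per selection
#'
#' `log2(N) + P*log2(P) + (1-P)*log2((1-P)/(N-1))` for accuracy `P` over `N`
#' targets. Reported informationally alongside the CRR.
#'
#' @param p Accuracy in `[0, 1]`.
#' @param n Number of selectable targets (36 for the 6x6 matrix).
#' @return Bits per selection.
#' @export
itr_wolpaw <- function(p, n = 36) {
  stopifnot(p >= 0, p <= 1, n >= 2)
  b <- log2(n)
  if (p > 0) b <- b + p * log2(p)
  if (p < 1) b <- b + (1 - p) * log2((1 - p) / (n - 1))
  b
}

#' Offline BCI evaluation: calibrate, decode, score
#'
#' Calibrates a template set on the calibration session, decodes the test
#' session at the best performing channel, and reports character recognition
#' rates — optionally sweeping the number of averaged intensification
#' sequences `k_a_used` from 1 to `cfg$k_a` to trace the
#' performance-vs-repetitions curve.
#'
#' @param calib_session,test_session [eeg_session()] objects.
#' @param calib_targets,test_targets Instructed letters for each session
#'   (string or character vector, one letter per trial).
#' @param matrix A [speller_matrix()].
#' @param cfg A [run_config()].
#' @param ka_sweep If `TRUE`, also compute the CRR at every
#'   `k_a_used = 1 .. cfg$k_a` (the test session is preprocessed once).
#' @return An object of class `eval_report`: `channel_crr` (calibration CRR
#'   per channel), `bpc`, `test_crr`, `itr_bits`, `predictions` (tibble),
#'   `ka_curve` (tibble or `NULL`), rejected-sequence counts, and the config
#'   echo.
#' @export
evaluate <- function(calib_session, calib_targets, test_session, test_targets,
                     matrix = speller_matrix(), cfg = run_config(),
                     ka_sweep = FALSE) {
  if (length(test_targets) == 1L && nchar(test_targets[1]) > 1L) {
    test_targets <- strsplit(test_targets, "")[[1]]
  }
  calib_prep <- preprocess_session(calib_session, cfg)
  calib_avg <- lapply(calib_prep$trials, ensemble_average, k_a_used = cfg$k_a)
  tset <- calibrate(calib_avg, calib_targets, matrix, cfg)

  test_prep <- preprocess_session(test_session, cfg)
  preds <- decode_segments(test_prep$trials, tset, matrix, cfg, cfg$k_a)
  actual <- test_targets[seq_len(nrow(preds))]
  test_crr <- crr(preds$letter, actual)

  ka_curve <- NULL
  if (isTRUE(ka_sweep)) {
    ka_curve <- dplyr::bind_rows(lapply(seq_len(cfg$k_a), function(ka) {
      p <- decode_segments(test_prep$trials, tset, matrix, cfg, ka)
      tibble(k_a_used = ka, crr = crr(p$letter, actual))
    }))
  }

  structure(list(
    channel_crr = tset$channel_crr,
    bpc = tset$bpc,
    test_crr = test_crr,
    itr_bits = itr_wolpaw(test_crr / 100),
    predictions = dplyr::mutate(preds, actual = actual,
                                correct = !is.na(.data$letter) & .data$letter == actual),
    ka_curve = ka_curve,
    n_rejected_calib = calib_prep$n_rejected,
    n_rejected_test = test_prep$n_rejected,
    n_failed_trials = sum(is.na(preds$letter)),
    config = unclass(cfg),
    schema_version = "1.0"
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat(sprintf("  bpc: %s (calibration CRR %.1f%%)\n", x$bpc,
              x$channel_crr$crr[x$channel_crr$channel == x$bpc]))
  cat(sprintf("  test CRR: %.1f%% over %d trial(s) (%.2f bits/selection)\n",
              x$test_crr, nrow(x$predictions), x$itr_bits))
  cat(sprintf("  rejected sequences: %d calibration, %d test; failed trials: %d\n",
              x$n_rejected_calib, x$n_rejected_test, x$n_failed_trials))
  if (!is.null(x$ka_curve)) {
    cat("  CRR by k_a_used:",
        paste(sprintf("%d:%.0f%%", x$ka_curve$k_a_used, x$ka_curve$crr),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) x$predictions

#' @export
glance.eval_report <- function(x, ...) {
  tibble(bpc = x$bpc, test_crr = x$test_crr, itr_bits = x$itr_bits,
         n_trials = nrow(x$predictions), n_failed = x$n_failed_trials,
         n_rejected_calib = x$n_rejected_calib,
         n_rejected_test = x$n_rejected_test)
}

#' Plot the performance-vs-repetitions curve of an evaluation
#'
#' @param object An `eval_report` produced with `ka_sweep = TRUE`.
#' @param ... Ignored.
#' @return A ggplot of CRR against the number of averaged sequences.
#' @export
autoplot.eval_report <- function(object, ...) {
  if (is.null(object$ka_curve)) {
    abort("no k_a curve in this report; rerun evaluate() with ka_sweep = TRUE")
  }
  ggplot2::ggplot(object$ka_curve,
                  ggplot2::aes(x = .data$k_a_used, y = .data$crr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 100 / 36, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$ka_curve$k_a_used) +
    ggplot2::labs(x = "intensification sequences averaged (k_a)",
                  y = "character recognition rate (%)") +
    ggplot2::ylim(0, 100)
}

#' Serialize an evaluation report to JSON
#'
#' Stable, versioned schema (`schema_version` field) for downstream tooling.
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- report
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}
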