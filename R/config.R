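#' Pipeline run configuration
#'
#' Bundles every tunable parameter of the decoding pipeline. Defaults are the
#' operating point of the method: a plot scale `gamma = 4` and patch scale
#' `s = 3` (so one pixel is 1/4 uV vertically and 1/64 s horizontally at the
#' 16 Hz working rate, and the 36x36-pixel patch covers 9 uV and 0.56 s),
#' `k = 7` neighbours under the cosine distance, `k_a = 10` intensification
#' sequences per trial, 1-s epochs, and +/-70 uV artifact rejection.
#'
#' @param gamma Positive integer image scale: a signal standardised to unit
#'   variance is stretched by `gamma` both in time (columns per sample) and
#'   amplitude (pixels per standard-deviation quarter). Default 4.
#' @param s Positive integer patch scale; the descriptor patch is a 4x4 grid
#'   of blocks of `3*s` pixels, i.e. `12*s` pixels on a side. Default 3.
#' @param k Neighbour count of the k-NBNN letter decision. Default 7.
#' @param k_a Number of intensification sequences (full 12-flash permutations)
#'   per trial. Default 10.
#' @param t_max Epoch length in seconds from each flash onset. Default 1.
#' @param target_fs Working sampling rate in Hz after decimation. Default 16.
#' @param artifact_uV Peak amplitude (uV) beyond which a whole intensification
#'   sequence is discarded. Default 70.
#' @param notch_hz Mains frequency (Hz) removed by the notch filter; set to 0
#'   to disable. Default 50.
#' @param metric Distance between descriptors: `"cosine"` (default) or
#'   `"sqeuclidean"` for ablation.
#' @param seed Integer seed recorded alongside the run.
#'
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config()
#' cfg$gamma
#' @export
run_config <- function(gamma = 4L, s = 3L, k = 7L, k_a = 10L, t_max = 1,
                       target_fs = 16, artifact_uV = 70, notch_hz = 50,
                       metric = c("cosine", "sqeuclidean"), seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(gamma >= 1, s >= 1, k >= 1, k_a >= 1, t_max > 0, target_fs > 0,
            artifact_uV >= 0, notch_hz >= 0)
  structure(
    list(gamma = as.integer(gamma), s = as.integer(s), k = as.integer(k),
         k_a = as.integer(k_a), t_max = t_max, target_fs = target_fs,
         artifact_uV = artifact_uV, notch_hz = notch_hz, metric = metric,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-11s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a run configuration as a flat key=value file
#'
#' One `key=value` pair per line; unknown keys are rejected so typos surface
#' early. Lines starting with `#` are comments.
#'
#' @param path File path.
#' @return `read_run_config()` returns a [run_config()]; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  known <- names(formals(run_config))
  if (any(!keys %in% known)) {
    abort(paste0("unknown config key(s): ",
                 paste(setdiff(keys, known), collapse = ", ")))
  }
  args <- as.list(vals)
  names(args) <- keys
  num <- setdiff(keys, "metric")
  args[num] <- lapply(args[num], as.numeric)
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param cfg A [run_config()].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(v) format(v, scientific = FALSE), "")),
             path)
  invisible(path)
}
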