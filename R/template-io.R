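#' Save or load a calibrated template set
#'
#' Plain-text JSON serialization of a `template_set` (descriptors, roles,
#' best performing channel, neighbour count, metric and per-channel
#' calibration CRR), so calibration and spelling can run as separate
#' invocations.
#'
#' @param tset A `template_set` from [calibrate()].
#' @param path File path (JSON).
#' @return `write_template_set()` returns `path` invisibly;
#'   `read_template_set()` returns the reconstructed `template_set`.
#' @export
write_template_set <- function(tset, path) {
  stopifnot(inherits(tset, "template_set"))
  payload <- list(
    schema_version = "1.0",
    bpc = tset$bpc, k = tset$k, metric = tset$metric,
    channel_crr = tset$channel_crr,
    config = unclass(tset$cfg),
    templates = lapply(seq_len(nrow(tset$templates)), function(i) {
      r <- tset$templates[i, ]
      list(channel = r$channel, trial_id = r$trial_id, role = r$role,
           location = r$location, d = r$d[[1]])
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_template_set
#' @export
read_template_set <- function(path) {
  if (!file.exists(path)) abort(paste0("template set not found: ", path))
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(p$templates) || is.null(p$bpc)) {
    abort("not a template-set file: missing templates/bpc fields")
  }
  templates <- dplyr::bind_rows(lapply(p$templates, function(r) {
    tibble(channel = r$channel, trial_id = as.integer(r$trial_id),
           role = r$role, location = as.integer(r$location),
           d = list(as.numeric(unlist(r$d))))
  }))
  cc <- dplyr::bind_rows(lapply(p$channel_crr, as_tibble))
  cfgl <- p$config
  cfg <- run_config(gamma = cfgl$gamma, s = cfgl$s, k = cfgl$k,
                    k_a = cfgl$k_a, t_max = cfgl$t_max,
                    target_fs = cfgl$target_fs, artifact_uV = cfgl$artifact_uV,
                    notch_hz = cfgl$notch_hz, metric = cfgl$metric,
                    seed = cfgl$seed)
  structure(list(templates = templates, bpc = p$bpc, k = as.integer(p$k),
                 metric = p$metric, channel_crr = cc, cfg = cfg),
            class = "template_set")
}
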