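SESSION_SCHEMA_VERSION <- "1.0"

#' Write a session log as JSON
#'
#' Serializes the full trial-by-trial record, per-epoch results, summary
#' scores, the configuration, the seed, and a `schema_version` field.
#' Identical sessions serialize to byte-identical files.
#'
#' @param session An `ff_session`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_log <- function(session, path) {
  stopifnot(inherits(session, "ff_session"))
  payload <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    seed = session$seed,
    config = unclass(session$config),
    threshold_score = session$threshold_score,
    mean_accuracy_pct = session$mean_accuracy_pct,
    estimated_duration_min = session$estimated_duration_min,
    epochs = session$epochs,
    trials = session$trials
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a session log written by [write_session_log()]
#'
#' @param path Path to a session-log JSON file.
#' @return An `ff_session`.
#' @export
read_session_log <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("schema_version", "config", "trials", "epochs",
              "threshold_score", "mean_accuracy_pct")
  missing <- setdiff(needed, names(raw))
  if (length(missing)) {
    abort(paste0("Session log is missing fields: ",
                 paste(missing, collapse = ", ")))
  }
  cfg_args <- raw$config
  cfg_args <- cfg_args[names(cfg_args) %in% names(formals(assessment_config))]
  structure(
    list(
      trials = as_tibble(raw$trials),
      epochs = as_tibble(raw$epochs),
      threshold_score = as.integer(raw$threshold_score),
      mean_accuracy_pct = raw$mean_accuracy_pct,
      estimated_duration_min = raw$estimated_duration_min,
      seed = as.integer(raw$seed),
      config = do.call(assessment_config, cfg_args)
    ),
    class = "ff_session"
  )
}
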