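# Typed pipeline errors. Every abort carries a failure code from the batch
# taxonomy plus the pipeline stage that raised it.

rw_failure_codes <- c(
  "NO_WATER_COLUMN", "NO_HORIZON", "HORIZON_OFF_LEFT_EDGE",
  "INSUFFICIENT_EDGES", "NO_CANDIDATE_LINES", "NO_VANISHING_POINT",
  "SEARCH_NON_CONVERGENCE", "RESOLUTION_TOO_LOW", "CALIBRATION_MISSING",
  "READ_ERROR"
)

stop_rw <- function(code, stage, message) {
  code <- match.arg(code, rw_failure_codes)
  cond <- structure(
    class = c("rw_error", "error", "condition"),
    list(message = sprintf("[%s/%s] %s", stage, code, message),
         call = sys.call(-1), code = code, stage = stage)
  )
  stop(cond)
}

#' Classify a pipeline error into a failure record
#'
#' Maps a stage name and a raised condition onto the batch failure taxonomy.
#' Errors raised by pipeline stages carry their own code; anything else is
#' mapped to a stage-generic code with the full message preserved.
#'
#' @param stage Pipeline stage name (e.g. `"horizon"`, `"search"`).
#' @param error A condition object.
#' @return A list with elements `code`, `stage` and `message`.
#' @export
classify_failure <- function(stage, error) {
  if (inherits(error, "rw_error")) {
    return(list(code = error$code, stage = error$stage, message = conditionMessage(error)))
  }
  generic <- c(load = "READ_ERROR", calibrate = "CALIBRATION_MISSING",
               undistort = "CALIBRATION_MISSING", horizon = "NO_HORIZON",
               roll = "NO_HORIZON", source_plane = "INSUFFICIENT_EDGES",
               grid = "NO_CANDIDATE_LINES", search = "SEARCH_NON_CONVERGENCE")
  code <- if (stage %in% names(generic)) generic[[stage]] else "READ_ERROR"
  list(code = code, stage = stage, message = conditionMessage(error))
}
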