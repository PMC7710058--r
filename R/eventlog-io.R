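## Line-delimited event-log format: one JSON header line (config snapshot,
## seed, animal id, schema version, logging conventions), then one
## tab-separated record per event:
##   timestamp_ms <TAB> event_kind <TAB> trial_id <TAB> payload_json
## Malformed lines are hard errors reported with their line number.

#' Write an event log to disk
#'
#' @param log [EventLog-class].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [readEventLog()]
#' @export
writeEventLog <- function(log, path) {
  stopifnot(is(log, "EventLog"))
  ev <- log@events
  header <- jsonlite::toJSON(log@header, auto_unbox = TRUE, digits = NA,
                             null = "null")
  body <- sprintf("%d\t%s\t%s\t%s",
                  as.integer(ev$timestamp_ms), ev$event_kind,
                  ifelse(is.na(ev$trial_id), "NA",
                         as.character(as.integer(ev$trial_id))),
                  ev$payload)
  writeLines(c(as.character(header), body), path)
  invisible(path)
}

#' Read an event log from disk
#'
#' Parses and validates the format written by [writeEventLog()]. Any
#' malformed line (wrong field count, non-numeric timestamp, unknown event
#' kind, invalid payload JSON) aborts with the offending line number; the
#' resulting object must pass all [EventLog-class] invariants.
#'
#' @param path File written by [writeEventLog()].
#' @return An [EventLog-class].
#' @export
readEventLog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty log file: ", path)
  header <- tryCatch(
    jsonlite::fromJSON(lines[1L], simplifyVector = TRUE),
    error = function(e) stop("line 1: malformed JSON header: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(header$schema))
    stop("line 1: header lacks a schema field", call. = FALSE)

  body <- lines[-1L]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != 4L))
      stop("line ", which(nf != 4L)[1L] + 1L,
           ": expected 4 tab-separated fields, found ",
           nf[which(nf != 4L)[1L]], call. = FALSE)
    m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
    ts <- suppressWarnings(as.numeric(m[, 1L]))
    if (anyNA(ts))
      stop("line ", which(is.na(ts))[1L] + 1L, ": non-numeric timestamp",
           call. = FALSE)
    bad_kind <- !m[, 2L] %in% .EVENT_KINDS
    if (any(bad_kind))
      stop("line ", which(bad_kind)[1L] + 1L, ": unknown event kind '",
           m[which(bad_kind)[1L], 2L], "'", call. = FALSE)
    id <- suppressWarnings(as.integer(m[, 3L]))
    bad_id <- is.na(id) & m[, 3L] != "NA"
    if (any(bad_id))
      stop("line ", which(bad_id)[1L] + 1L, ": malformed trial id",
           call. = FALSE)
    bad_payload <- !vapply(m[, 4L], jsonlite::validate, logical(1),
                           USE.NAMES = FALSE)
    if (any(bad_payload))
      stop("line ", which(bad_payload)[1L] + 1L, ": invalid payload JSON",
           call. = FALSE)
    ev <- data.frame(timestamp_ms = ts, event_kind = m[, 2L], trial_id = id,
                     payload = m[, 4L], stringsAsFactors = FALSE)
  } else {
    ev <- data.frame(timestamp_ms = numeric(0), event_kind = character(0),
                     trial_id = integer(0), payload = character(0))
  }
  new("EventLog", header = header, events = ev)
}
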