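# Canonical timeline representation and its JSON/JSONL serialization.
#
# A timeline is a data.frame (class "timeline") with one row per timestamped
# user activity, sorted stably by timestamp:
#   participant_id  character
#   timestamp       POSIXct, minute resolution, participant-local wall clock
#                   (stored with tz = "UTC" purely as a container; no timezone
#                   conversion is ever applied -- diurnal features need
#                   wall-clock semantics)
#   kind            one of the nine activity kinds (see event_kinds())
#   text            character, "" for non-text activities
#   co_tagged       list of character vectors (tagged handles)

#' Recognized activity kinds
#'
#' The canonical event vocabulary: self-authored posts (`status`), comments,
#' shares, likes, photo uploads, check-ins, friending events (`friend_add`),
#' co-tagging events (`co_tag`) and third-party app use (`app_use`).
#'
#' @return Character vector of the nine kind names.
#' @export
event_kinds <- function() {
  c("status", "comment", "share", "like", "photo", "check_in",
    "friend_add", "co_tag", "app_use")
}

# kinds that are behavioral-only: they never carry text
.behavioral_only_kinds <- c("like", "friend_add")

.timestamp_format <- "%Y-%m-%dT%H:%M"

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = .timestamp_format, tz = "UTC")
  # accept second-resolution input, truncated to the minute
  sec <- is.na(out) & !is.na(x)
  if (any(sec)) {
    full <- as.POSIXct(x[sec], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    out[sec] <- trunc(full, units = "mins")
  }
  out
}

format_timestamp <- function(x) format(x, format = .timestamp_format, tz = "UTC")

#' Construct a timeline from event vectors
#'
#' Events are sorted stably by timestamp (ties keep insertion order), the
#' invariant expected by every downstream consumer.
#'
#' @param participant_id Character scalar or vector of participant ids.
#' @param timestamp POSIXct vector, or character in `YYYY-MM-DDTHH:MM` form.
#' @param kind Character vector of activity kinds (see [event_kinds()]).
#' @param text Character vector of post text; `""` for behavioral events.
#' @param co_tagged List of character vectors of tagged handles.
#' @return A `timeline` data.frame.
#' @export
timeline <- function(participant_id, timestamp, kind,
                     text = character(length(kind)),
                     co_tagged = rep(list(character(0)), length(kind))) {
  if (is.character(timestamp)) timestamp <- parse_timestamp(timestamp)
  n <- length(timestamp)
  participant_id <- rep_len(as.character(participant_id), n)
  text <- rep_len(as.character(text), n)
  if (!is.list(co_tagged)) stop("`co_tagged` must be a list of character vectors")
  co_tagged <- rep_len(co_tagged, max(n, 0L))
  df <- data.frame(participant_id = participant_id,
                   timestamp = timestamp,
                   kind = as.character(kind),
                   text = text,
                   stringsAsFactors = FALSE)
  df$co_tagged <- co_tagged
  as_timeline(df)
}

#' @rdname timeline
#' @param x A data.frame with timeline columns.
#' @export
as_timeline <- function(x) {
  need <- c("participant_id", "timestamp", "kind", "text", "co_tagged")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing timeline columns: ", paste(miss, collapse = ", "))
  x <- x[need]
  ord <- order(x$timestamp)   # stable sort: ties keep insertion order
  x <- x[ord, , drop = FALSE]
  rownames(x) <- NULL
  class(x) <- c("timeline", "data.frame")
  x
}

#' @export
print.timeline <- function(x, ...) {
  pid <- unique(x$participant_id)
  cat(sprintf("<timeline> %d events, participant %s\n", nrow(x),
              paste(pid, collapse = ", ")))
  if (nrow(x)) {
    cat(sprintf("  span: %s .. %s\n",
                format_timestamp(min(x$timestamp)),
                format_timestamp(max(x$timestamp))))
    print(utils::head(as.data.frame(x)[c("timestamp", "kind", "text")], 5))
    if (nrow(x) > 5) cat("  ...\n")
  }
  invisible(x)
}

#' Validate timeline invariants
#'
#' Checks that events are sorted by timestamp, belong to a single participant,
#' carry a recognized kind, have parseable timestamps, and that behavioral-only
#' kinds (`like`, `friend_add`) carry no text. Validation never throws: it
#' returns a character vector of violations, empty when all invariants hold.
#'
#' @param x A timeline.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_timeline <- function(x) {
  v <- character(0)
  if (!all(c("participant_id", "timestamp", "kind", "text", "co_tagged") %in% names(x)))
    return("not a timeline: missing columns")
  n <- nrow(x)
  if (n == 0) return(v)
  if (length(unique(x$participant_id)) > 1)
    v <- c(v, "multiple participant ids in one timeline")
  bad_ts <- which(is.na(x$timestamp))
  for (i in bad_ts) v <- c(v, sprintf("unparseable timestamp at index %d", i))
  if (length(bad_ts) == 0 && n > 1) {
    d <- diff(as.numeric(x$timestamp))
    for (i in which(d < 0)) v <- c(v, sprintf("unsorted at index %d", i + 1L))
  }
  bad_kind <- which(!x$kind %in% event_kinds())
  for (i in bad_kind) v <- c(v, sprintf("unknown kind '%s' at index %d", x$kind[i], i))
  txt <- which(x$kind %in% .behavioral_only_kinds & nzchar(x$text))
  for (i in txt) v <- c(v, sprintf("text on behavioral-only kind at index %d", i))
  v
}

event_to_json <- function(participant_id, timestamp, kind, text, co_tagged) {
  # fixed field order so output is byte-stable
  jsonlite::toJSON(
    list(participant_id = participant_id,
         timestamp = format_timestamp(timestamp),
         kind = kind,
         text = text,
         co_tagged = as.character(co_tagged)),
    auto_unbox = TRUE)
}

#' Write / read the canonical JSONL timeline format
#'
#' One event per line with fields exactly
#' `{participant_id, timestamp, kind, text, co_tagged}`; the first line is the
#' schema header `{"schema": "timeline/1"}`. Field order is fixed, so writing
#' the same timeline twice yields byte-identical files, and
#' `read_canonical(write_canonical(t))` reproduces `t` field-by-field.
#'
#' @param x A valid timeline.
#' @param path Output (or input) file path.
#' @return `write_canonical` returns `path` invisibly; `read_canonical`
#'   returns a `timeline`.
#' @export
write_canonical <- function(x, path) {
  v <- validate_timeline(x)
  if (length(v)) stop("invalid timeline: ", v[1])
  header <- '{"schema":"timeline/1"}'
  lines <- character(nrow(x))
  for (i in seq_len(nrow(x))) {
    lines[i] <- event_to_json(x$participant_id[i], x$timestamp[i], x$kind[i],
                              x$text[i], x$co_tagged[[i]])
  }
  con <- file(path, open = "wb")   # "wb" keeps line endings platform-stable
  on.exit(close(con))
  writeLines(c(header, lines), con = con, sep = "\n")
  invisible(path)
}

#' @rdname write_canonical
#' @export
read_canonical <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty file: ", path)
  hdr <- tryCatch(jsonlite::fromJSON(lines[1]), error = function(e) NULL)
  if (is.null(hdr$schema) || !identical(hdr$schema, "timeline/1"))
    stop("schema version mismatch: expected timeline/1 header on line 1")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(timeline(character(0), as.POSIXct(character(0), tz = "UTC"),
                    character(0)))
  }
  recs <- vector("list", length(body))
  for (i in seq_along(body)) {
    rec <- tryCatch(jsonlite::fromJSON(body[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$timestamp) || is.null(rec$kind))
      stop(sprintf("malformed event on line %d of %s", i + 1L, path))
    recs[[i]] <- rec
  }
  timeline(
    participant_id = vapply(recs, function(r) as.character(r$participant_id), ""),
    timestamp = vapply(recs, function(r) as.character(r$timestamp), ""),
    kind = vapply(recs, function(r) as.character(r$kind), ""),
    text = vapply(recs, function(r) if (is.null(r$text)) "" else as.character(r$text), ""),
    co_tagged = lapply(recs, function(r) as.character(r$co_tagged))
  )
}

#' Parse an archive directory into a timeline
#'
#' Reads every `*.json` file under `root` in the canonical archive schema:
#' each file is an object `{"participant_id": id, "activities": [...]}` where
#' every activity has `timestamp` and `kind`, and optionally `text` and
#' `co_tagged`. Records with an unrecognized kind or unparseable timestamp are
#' skipped and counted (attribute `n_skipped`), not fatal. This schema is
#' defined by this package -- real platform exports vary by vintage and are
#' out of scope.
#'
#' @param root Directory containing at least one archive JSON file.
#' @param min_events Minimum number of parseable events; fewer is treated as
#'   insufficient data and raises an error.
#' @return A `timeline` with attribute `n_skipped`.
#' @export
parse_archive <- function(root, min_events = 1) {
  if (!dir.exists(root)) stop("archive directory not found: ", root)
  files <- sort(list.files(root, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0) stop("no JSON files under ", root)
  pid <- NULL
  recs <- list()
  n_skipped <- 0L
  for (f in files) {
    obj <- jsonlite::fromJSON(f, simplifyVector = FALSE)
    if (is.null(obj$participant_id)) stop("archive file lacks participant_id: ", f)
    if (is.null(pid)) pid <- as.character(obj$participant_id)
    if (!identical(pid, as.character(obj$participant_id)))
      stop("archive mixes participants: ", f)
    for (a in obj$activities) {
      kind <- if (is.null(a$kind)) NA_character_ else as.character(a$kind)
      ts <- if (is.null(a$timestamp)) NA else parse_timestamp(as.character(a$timestamp))
      if (is.na(kind) || !kind %in% event_kinds() || is.na(ts)) {
        n_skipped <- n_skipped + 1L
        next
      }
      recs[[length(recs) + 1L]] <- list(
        timestamp = ts, kind = kind,
        text = if (is.null(a$text)) "" else as.character(a$text),
        co_tagged = if (is.null(a$co_tagged)) character(0)
                    else as.character(unlist(a$co_tagged)))
    }
  }
  if (length(recs) < max(1L, min_events))
    stop(sprintf("insufficient data: %d parseable events (minimum %d)",
                 length(recs), max(1L, min_events)))
  tl <- timeline(
    participant_id = pid,
    timestamp = do.call(c, lapply(recs, `[[`, "timestamp")),
    kind = vapply(recs, `[[`, "", "kind"),
    text = vapply(recs, `[[`, "", "text"),
    co_tagged = lapply(recs, `[[`, "co_tagged"))
  attr(tl, "n_skipped") <- n_skipped
  tl
}

#' Write a timeline back out in the archive schema
#'
#' Inverse of [parse_archive()] for a single participant; mainly used to build
#' test fixtures from generated cohorts.
#'
#' @param x A valid timeline.
#' @param dir Output directory (created if needed).
#' @return The written file path, invisibly.
#' @export
write_archive <- function(x, dir) {
  v <- validate_timeline(x)
  if (length(v)) stop("invalid timeline: ", v[1])
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pid <- if (nrow(x)) x$participant_id[1] else "unknown"
  acts <- lapply(seq_len(nrow(x)), function(i) {
    list(timestamp = format_timestamp(x$timestamp[i]),
         kind = x$kind[i], text = x$text[i],
         co_tagged = as.character(x$co_tagged[[i]]))
  })
  path <- file.path(dir, paste0(pid, ".json"))
  jsonlite::write_json(list(participant_id = pid, activities = acts), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a hospitalization table
#'
#' CSV with header exactly `participant_id,admit_date,discharge_date`
#' (ISO-8601 dates, discharge may be blank). Rows are returned sorted by
#' participant then admit date. A discharge earlier than its admission is an
#' error.
#'
#' @param path CSV file path.
#' @return data.frame with `participant_id`, `admit_date` (Date),
#'   `discharge_date` (Date, possibly `NA`).
#' @export
read_hospitalizations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "admit_date", "discharge_date")
  if (!identical(names(df)[seq_along(need)], need))
    stop("hospitalization CSV must have header participant_id,admit_date,discharge_date")
  out <- data.frame(participant_id = df$participant_id,
                    admit_date = as.Date(df$admit_date),
                    discharge_date = as.Date(ifelse(nzchar(df$discharge_date),
                                                    df$discharge_date, NA)),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$admit_date))) stop("unparseable admit_date in ", path)
  bad <- which(!is.na(out$discharge_date) & out$discharge_date < out$admit_date)
  if (length(bad))
    stop("discharge before admission on row(s) ", paste(bad, collapse = ", "))
  out[order(out$participant_id, out$admit_date), , drop = FALSE]
}

#' Write a hospitalization table
#'
#' @param hosp data.frame as returned by [read_hospitalizations()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hospitalizations <- function(hosp, path) {
  out <- data.frame(
    participant_id = hosp$participant_id,
    admit_date = format(hosp$admit_date, "%Y-%m-%d"),
    discharge_date = ifelse(is.na(hosp$discharge_date), "",
                            format(hosp$discharge_date, "%Y-%m-%d")),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
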