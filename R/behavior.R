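# Behavioral activity features: per-period event rates by kind and diurnal bin.
#
# The four diurnal bins partition the 24-hour wall clock:
#   morning  [05:00, 12:00)
#   noon     [12:00, 17:00)
#   night    [17:00, 22:00)
#   midnight [22:00, 05:00 next day)
# Morning and midnight follow the reported significant windows (05:00-12:00
# and 22:00-05:00); noon and night complete the partition.

#' Diurnal bin names
#' @return `c("morning", "noon", "night", "midnight")`.
#' @export
diurnal_bins <- function() c("morning", "noon", "night", "midnight")

#' Map timestamps to diurnal bins
#'
#' Bins are half-open in local wall-clock time, so 05:00 is morning, 12:00 is
#' noon, 17:00 is night and 22:00 is midnight; every instant maps to exactly
#' one bin.
#'
#' @param timestamp POSIXct vector (participant-local wall clock).
#' @return Character vector of bin names.
#' @export
diurnal_bin <- function(timestamp) {
  lt <- as.POSIXlt(timestamp, tz = "UTC")
  h <- lt$hour + lt$min / 60
  ifelse(h >= 5 & h < 12, "morning",
         ifelse(h >= 12 & h < 17, "noon",
                ifelse(h >= 17 & h < 22, "night", "midnight")))
}

# feature families: the nine raw kinds plus derived co-tagging behavior
# (co_tag events plus status/photo events carrying tags)
activity_families <- function() c(event_kinds(), "co_tagging")

behavior_feature_names <- function() {
  as.vector(outer(activity_families(), c("overall", diurnal_bins()),
                  function(f, b) paste0(f, "__", b)))
}

#' Activity rates of one period
#'
#' Counts events of each kind (plus the derived co-tagging family: `co_tag`
#' events and status/photo events with a non-empty tag list) overall and per
#' diurnal bin, and normalizes to a 30-day-equivalent rate
#' (`count * 30 / period_length_days`) so periods of different granularity
#' are feature-comparable. Overall rates equal the sum of the four bin rates
#' exactly.
#'
#' @param period One period row (`start`, `end` as Dates).
#' @param events Timeline rows already assigned to that period.
#' @param normalize Normalize to per-30-days rates (default TRUE); FALSE
#'   returns raw counts.
#' @return Named numeric vector `<family>__{overall,morning,noon,night,midnight}`.
#' @export
activity_features <- function(period, events, normalize = TRUE) {
  len <- as.numeric(period$end - period$start)
  nms <- behavior_feature_names()
  out <- stats::setNames(numeric(length(nms)), nms)
  if (nrow(events)) {
    edate <- as.Date(events$timestamp, tz = "UTC")
    if (any(edate < period$start | edate >= period$end))
      stop("events outside the period passed to activity_features()")
    bin <- diurnal_bin(events$timestamp)
    fam <- list()
    for (k in event_kinds()) fam[[k]] <- events$kind == k
    fam[["co_tagging"]] <- events$kind == "co_tag" |
      (events$kind %in% c("status", "photo") & lengths(events$co_tagged) > 0)
    for (f in names(fam)) {
      sel <- fam[[f]]
      out[paste0(f, "__overall")] <- sum(sel)
      for (b in diurnal_bins())
        out[paste0(f, "__", b)] <- sum(sel & bin == b)
    }
  }
  if (normalize) out <- out * 30 / len
  out
}
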