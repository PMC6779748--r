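# Segmentation of a participant's study window into labeled periods.
#
# The study window runs from the first hospitalization to the most recent
# relapse hospitalization. The 30 days before each non-index admission are a
# period of relapse; all remaining time (minus, by default, inpatient stays)
# is tiled into fixed-length periods of relative health. "1 month" is 30 days
# throughout (60 and 90 days for the 2- and 3-month configurations).

#' Segmentation configuration
#'
#' @param relapse_window_days Length of the pre-admission relapse window in
#'   days (default 30, the 1-month convention).
#' @param health_granularity_days Length of each health period in days; 30, 60
#'   or 90 for the 1-/2-/3-month model configurations.
#' @param exclude_inpatient Drop inpatient days from health time (default
#'   TRUE: a hospitalized patient is not "relatively healthy").
#' @param min_posts_per_period Periods with fewer assigned posts are flagged
#'   `excluded` (default 1).
#' @param inpatient_stay_days Imputed stay length when a discharge date is
#'   missing (default 13 days, the cohort's median stay).
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(relapse_window_days = 30,
                                health_granularity_days = 30,
                                exclude_inpatient = TRUE,
                                min_posts_per_period = 1,
                                inpatient_stay_days = 13) {
  stopifnot(relapse_window_days >= 1,
            health_granularity_days %in% c(30, 60, 90),
            min_posts_per_period >= 0,
            inpatient_stay_days >= 0)
  structure(list(relapse_window_days = as.integer(relapse_window_days),
                 health_granularity_days = as.integer(health_granularity_days),
                 exclude_inpatient = isTRUE(exclude_inpatient),
                 min_posts_per_period = as.integer(min_posts_per_period),
                 inpatient_stay_days = as.integer(inpatient_stay_days)),
            class = "segmentation_config")
}

# impute missing discharges as admit + stay; flags the imputation
impute_discharge <- function(hosp, stay_days = 13) {
  imp <- is.na(hosp$discharge_date)
  hosp$discharge_imputed <- imp
  hosp$discharge_date[imp] <- hosp$admit_date[imp] + stay_days
  hosp
}

check_sorted_admits <- function(hosp) {
  if (nrow(hosp) > 1 && is.unsorted(hosp$admit_date))
    stop("hospitalizations must be sorted by admit date")
}

#' Study window of one participant
#'
#' The half-open interval from the day of the first hospitalization to the day
#' of the most recent relapse hospitalization. Admissions after the first are
#' the participant's relapse events; a participant with a single
#' hospitalization has no relapse and is excluded from the analysis.
#'
#' @param hosp Hospitalizations of one participant, sorted by admit date.
#' @return list with Date elements `start` (first admit, inclusive) and `end`
#'   (last admit, exclusive).
#' @export
study_window <- function(hosp) {
  if (nrow(hosp) == 0) stop("no hospitalizations")
  check_sorted_admits(hosp)
  if (nrow(hosp) < 2)
    stop("no relapse hospitalization: participant has a single admission",
         call. = FALSE)
  list(start = hosp$admit_date[1], end = hosp$admit_date[nrow(hosp)])
}

new_periods <- function(participant_id = character(0), start = as.Date(character(0)),
                        end = as.Date(character(0)), label = character(0),
                        granularity_days = integer(0),
                        anchor = as.Date(character(0))) {
  data.frame(participant_id = participant_id, start = start, end = end,
             label = label, granularity_days = granularity_days,
             anchor = anchor, n_posts = rep(NA_integer_, length(start)),
             excluded = rep(FALSE, length(start)), stringsAsFactors = FALSE)
}

#' Relapse windows of one participant
#'
#' One period per non-index hospitalization: the `relapse_window_days` before
#' the admission, `[admit - w, admit)`. Windows never reach back before the
#' previous hospitalization's discharge (admit if the discharge is absent);
#' windows that are empty after this clipping are dropped with a warning.
#'
#' @param hosp Hospitalizations of one participant, sorted by admit date, at
#'   least two rows.
#' @param cfg A [segmentation_config()].
#' @return data.frame of relapse periods (`start`, `end`, `label = "relapse"`,
#'   `anchor` = the admit date).
#' @export
relapse_windows <- function(hosp, cfg = segmentation_config()) {
  check_sorted_admits(hosp)
  if (nrow(hosp) < 2) stop("need >= 2 hospitalizations for relapse windows")
  w <- cfg$relapse_window_days
  pid <- hosp$participant_id[1]
  out <- new_periods()
  for (i in 2:nrow(hosp)) {
    admit <- hosp$admit_date[i]
    barrier <- if (!is.na(hosp$discharge_date[i - 1])) hosp$discharge_date[i - 1]
               else hosp$admit_date[i - 1]
    start <- max(admit - w, barrier)
    if (start >= admit) {
      warning(sprintf("empty relapse window before %s dropped (participant %s)",
                      format(admit), pid))
      next
    }
    out <- rbind(out, new_periods(pid, start, admit, "relapse",
                                  as.integer(w), admit))
  }
  out
}

# subtract interval [s, e) from a list of disjoint runs (data.frame start/end)
subtract_interval <- function(runs, s, e) {
  if (nrow(runs) == 0 || e <= s) return(runs)
  pieces <- list()
  for (i in seq_len(nrow(runs))) {
    a <- runs$start[i]; b <- runs$end[i]
    if (e <= a || s >= b) {            # no overlap
      pieces[[length(pieces) + 1L]] <- data.frame(start = a, end = b)
      next
    }
    if (a < s) pieces[[length(pieces) + 1L]] <- data.frame(start = a, end = s)
    if (e < b) pieces[[length(pieces) + 1L]] <- data.frame(start = e, end = b)
  }
  if (length(pieces) == 0) data.frame(start = as.Date(character(0)),
                                      end = as.Date(character(0)))
  else do.call(rbind, pieces)
}

#' Health periods of one participant
#'
#' The study window minus relapse windows minus (optionally) inpatient stays
#' is decomposed into maximal runs; each run is tiled left-to-right with
#' consecutive `[t, t + granularity)` periods. A trailing remainder shorter
#' than the granularity is dropped, keeping all health periods the same
#' length and hence feature-comparable.
#'
#' @param window Study window as returned by [study_window()].
#' @param relapse_periods Relapse periods from [relapse_windows()].
#' @param inpatient Hospitalizations (admit/discharge define the inpatient
#'   stays to exclude); may be NULL when `exclude_inpatient` is FALSE.
#' @param cfg A [segmentation_config()].
#' @return data.frame of health periods.
#' @export
health_periods <- function(window, relapse_periods, inpatient = NULL,
                           cfg = segmentation_config()) {
  g <- cfg$health_granularity_days
  runs <- data.frame(start = window$start, end = window$end)
  if (!is.null(relapse_periods) && nrow(relapse_periods)) {
    for (i in seq_len(nrow(relapse_periods)))
      runs <- subtract_interval(runs, relapse_periods$start[i],
                                relapse_periods$end[i])
  }
  if (cfg$exclude_inpatient && !is.null(inpatient) && nrow(inpatient)) {
    stays <- impute_discharge(inpatient, cfg$inpatient_stay_days)
    for (i in seq_len(nrow(stays)))
      runs <- subtract_interval(runs, stays$admit_date[i],
                                stays$discharge_date[i])
  }
  pid <- if (!is.null(relapse_periods) && nrow(relapse_periods))
    relapse_periods$participant_id[1]
  else if (!is.null(inpatient) && nrow(inpatient)) inpatient$participant_id[1]
  else NA_character_
  out <- new_periods()
  for (i in seq_len(nrow(runs))) {
    len <- as.integer(runs$end[i] - runs$start[i])
    k <- len %/% g
    if (k < 1) next
    starts <- runs$start[i] + g * (seq_len(k) - 1L)
    out <- rbind(out, new_periods(pid, starts, starts + g, "health",
                                  as.integer(g), as.Date(NA)))
  }
  out
}

period_id <- function(periods) {
  sprintf("%s|%s|%s", periods$participant_id,
          format(periods$start, "%Y-%m-%d"), format(periods$end, "%Y-%m-%d"))
}

check_disjoint <- function(periods) {
  for (pid in unique(periods$participant_id)) {
    p <- periods[periods$participant_id == pid, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) > 1 && any(utils::head(p$end, -1) > utils::tail(p$start, -1)))
      stop("overlapping periods for participant ", pid)
  }
  invisible(TRUE)
}

#' Assign events to periods
#'
#' An event with timestamp `t` belongs to the unique period with
#' `start <= date(t) < end` (half-open convention), else to no period.
#' Periods receiving fewer than `min_posts` events are flagged
#' `excluded = TRUE` but retained for audit.
#'
#' @param events A timeline (or row-bound timelines of several participants).
#' @param periods Pairwise-disjoint periods.
#' @param min_posts Exclusion threshold on `n_posts` (default 1).
#' @return `periods` with `n_posts` and `excluded` filled, and attribute
#'   `assignment`: for each event row, the index of its period (NA if none).
#' @export
assign_posts <- function(events, periods, min_posts = 1) {
  check_disjoint(periods)
  assignment <- rep(NA_integer_, nrow(events))
  if (nrow(events) && nrow(periods)) {
    edate <- as.Date(events$timestamp, tz = "UTC")
    for (pid in unique(periods$participant_id)) {
      rows <- which(periods$participant_id == pid)
      p <- periods[rows, , drop = FALSE]
      ord <- order(p$start)
      ev <- which(events$participant_id == pid)
      if (!length(ev)) next
      idx <- findInterval(as.numeric(edate[ev]), as.numeric(p$start[ord]))
      ok <- idx >= 1 & idx <= nrow(p)
      inside <- ok
      inside[ok] <- edate[ev][ok] < p$end[ord][idx[ok]]
      assignment[ev[inside]] <- rows[ord][idx[inside]]
    }
  }
  counts <- tabulate(assignment, nbins = nrow(periods))
  periods$n_posts <- as.integer(counts)
  periods$excluded <- counts < min_posts
  attr(periods, "assignment") <- assignment
  periods
}

#' Segment a whole cohort
#'
#' Runs [study_window()], [relapse_windows()], [health_periods()] and
#' [assign_posts()] for every participant that has at least two
#' hospitalizations; participants with a single admission are skipped and
#' counted (attribute `n_no_relapse`).
#'
#' @param events Row-bound timelines of the cohort.
#' @param hosp Hospitalization table (all participants).
#' @param cfg A [segmentation_config()].
#' @return Periods data.frame for the cohort with `n_posts`/`excluded` filled
#'   and attributes `assignment` and `n_no_relapse`.
#' @export
segment_cohort <- function(events, hosp, cfg = segmentation_config()) {
  all_periods <- list()
  n_no_relapse <- 0L
  for (pid in unique(hosp$participant_id)) {
    h <- hosp[hosp$participant_id == pid, , drop = FALSE]
    h <- h[order(h$admit_date), , drop = FALSE]
    if (nrow(h) < 2) {
      n_no_relapse <- n_no_relapse + 1L
      next
    }
    h <- impute_discharge(h, cfg$inpatient_stay_days)
    win <- study_window(h)
    rel <- relapse_windows(h, cfg)
    hea <- health_periods(win, rel, h, cfg)
    if (nrow(hea)) hea$participant_id <- pid
    all_periods[[pid]] <- rbind(rel, hea)
  }
  if (!length(all_periods)) stop("no participant with a relapse hospitalization")
  periods <- do.call(rbind, all_periods)
  rownames(periods) <- NULL
  periods <- assign_posts(events, periods, cfg$min_posts_per_period)
  attr(periods, "n_no_relapse") <- n_no_relapse
  periods
}
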