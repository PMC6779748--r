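# Synthetic cohort generator.
#
# Emulates the structure the analysis assumes: per participant, a sequence of
# hospitalizations (the first is the index admission, the rest are relapses)
# spaced Uniform(90, 300) days apart; timestamped events arriving as a
# Poisson process; post text drawn token-by-token from the category lexicon
# plus a neutral filler vocabulary; and, inside each 30-day pre-relapse
# window, multiplicative shifts on category emission probabilities, on
# co-tagging/friending rates and on the midnight diurnal weight (the
# directions the exploratory screen reports). A machine-readable truth log
# records the planted schedule so every pipeline stage can be tested against
# it.

# event-kind mix of a healthy period (probabilities sum to 1)
.kind_probs <- c(status = 0.40, comment = 0.16, like = 0.14, share = 0.06,
                 photo = 0.08, check_in = 0.05, co_tag = 0.05,
                 friend_add = 0.04, app_use = 0.02)

.text_kinds <- c("status", "comment", "share", "photo", "check_in")

#' Default per-token category emission probabilities
#'
#' Baseline probability that a generated token is drawn from each lexicon
#' category; remaining mass goes to the neutral filler vocabulary. Values are
#' of the order of the category proportions seen in social-media text
#' (function-word classes common, topical classes rare).
#'
#' @return Named numeric vector over the built-in lexicon categories.
#' @export
default_category_probs <- function() {
  c(first_person_singular = 0.050, first_person_plural = 0.004,
    second_person = 0.012, indefinite_pronoun = 0.008, quantifier = 0.006,
    negation = 0.008, verbs = 0.050, future_tense = 0.005,
    causation = 0.004, insight = 0.005, discrepancies = 0.004,
    tentativeness = 0.005, certainty = 0.004, inclusive = 0.010,
    exclusive = 0.006, family = 0.004, friends = 0.008, humans = 0.004,
    home = 0.004, work = 0.012, achievement = 0.007, money = 0.003,
    religion = 0.002, death = 0.002, body = 0.006, health = 0.009,
    bio = 0.004, sexual = 0.002, feel = 0.006, hear = 0.004,
    anger = 0.005, anxiety = 0.002, sadness = 0.003,
    negative_affect = 0.006, inhibition = 0.002, swear = 0.004)
}

#' Default pre-relapse effect multipliers
#'
#' Multiplicative shifts applied inside 30-day pre-relapse windows, following
#' the directions of the exploratory screen: elevated swear, anger, death,
#' hear, feel, first-/second-person and negative-affect usage; depressed
#' work, friends, health, achievement and body usage; elevated co-tagging and
#' friending rates; and a heavier midnight posting bin
#' (`midnight_weight`).
#'
#' @return Named numeric vector of multipliers (> 0).
#' @export
default_effect_multipliers <- function() {
  c(swear = 2.0, anger = 1.6, death = 2.0, hear = 2.5, feel = 1.5,
    first_person_singular = 1.5, first_person_plural = 3.0,
    second_person = 1.5, negative_affect = 1.5,
    work = 0.5, friends = 0.6, health = 0.25, achievement = 0.8, body = 0.8,
    co_tag = 3.0, friend_add = 1.2, midnight_weight = 1.8)
}

#' Synthetic cohort configuration
#'
#' @param n_participants Number of participants.
#' @param hosp_per_participant Integer range (length-2) of hospitalizations
#'   per participant; default `c(2, 4)` (so one to three relapses each).
#' @param followup_days Length of each participant's generated event stream
#'   in days (default 720).
#' @param base_post_rate Poisson event rate per day (default 2).
#' @param base_category_probs Per-token category emission probabilities
#'   (default [default_category_probs()]).
#' @param diurnal_weights Length-4 weights (morning, noon, night, midnight)
#'   summing to 1.
#' @param effect_multipliers Pre-relapse multipliers
#'   (default [default_effect_multipliers()]); all 1 generates a null cohort.
#' @param relapse_window_days Planted pre-relapse window length (default 30).
#' @param inpatient_stay_days Discharge is admit + this many days
#'   (default 13, the cohort's median stay).
#' @param seed Integer seed; the single source of randomness.
#' @return A `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 50,
                             hosp_per_participant = c(2, 4),
                             followup_days = 720,
                             base_post_rate = 2.0,
                             base_category_probs = default_category_probs(),
                             diurnal_weights = c(morning = 0.30, noon = 0.30,
                                                 night = 0.25, midnight = 0.15),
                             effect_multipliers = default_effect_multipliers(),
                             relapse_window_days = 30,
                             inpatient_stay_days = 13,
                             seed = 1) {
  stopifnot(n_participants >= 1,
            length(hosp_per_participant) == 2,
            hosp_per_participant[1] >= 2,
            hosp_per_participant[2] >= hosp_per_participant[1],
            followup_days >= 1, base_post_rate > 0,
            all(base_category_probs >= 0), all(base_category_probs <= 1),
            length(diurnal_weights) == 4,
            abs(sum(diurnal_weights) - 1) <= 1e-9,
            all(effect_multipliers > 0),
            relapse_window_days >= 1, inpatient_stay_days >= 0)
  if ((hosp_per_participant[2] - 1) * 90 > followup_days)
    stop("followup_days too short for the requested hospitalization spacing")
  structure(list(n_participants = as.integer(n_participants),
                 hosp_per_participant = as.integer(hosp_per_participant),
                 followup_days = as.integer(followup_days),
                 base_post_rate = base_post_rate,
                 base_category_probs = base_category_probs,
                 diurnal_weights = diurnal_weights,
                 effect_multipliers = effect_multipliers,
                 relapse_window_days = as.integer(relapse_window_days),
                 inpatient_stay_days = as.integer(inpatient_stay_days),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# state-adjusted per-token category probabilities; total mass capped at 1
token_probs <- function(cfg, state) {
  p <- cfg$base_category_probs
  if (state == "pre_relapse") {
    mult <- cfg$effect_multipliers
    mult <- mult[names(mult) %in% names(p)]
    p[names(mult)] <- p[names(mult)] * mult
    if (sum(p) > 1) p <- p / sum(p)   # renormalize if mass exceeds the budget
  }
  p
}

# state-adjusted diurnal weights (midnight multiplier, renormalized)
state_diurnal_weights <- function(cfg, state) {
  w <- cfg$diurnal_weights
  if (state == "pre_relapse" && "midnight_weight" %in% names(cfg$effect_multipliers)) {
    w[4] <- w[4] * cfg$effect_multipliers[["midnight_weight"]]
    w <- w / sum(w)
  }
  w
}

# state-adjusted kind mix (co_tag / friend_add multipliers, renormalized)
state_kind_probs <- function(cfg, state) {
  kp <- .kind_probs
  if (state == "pre_relapse") {
    for (k in c("co_tag", "friend_add")) {
      if (k %in% names(cfg$effect_multipliers))
        kp[k] <- kp[k] * cfg$effect_multipliers[[k]]
    }
    kp <- kp / sum(kp)
  }
  kp
}

# neutral filler words, filtered at run time against the lexicon so fillers
# never hit a category
filler_vocabulary <- function(lexicon) {
  base <- c("the", "a", "an", "to", "of", "in", "on", "at", "for", "from",
            "this", "that", "these", "those", "there", "here", "then", "when",
            "where", "while", "about", "into", "over", "under", "again",
            "just", "really", "very", "quite", "pretty", "today", "yesterday",
            "morning", "evening", "week", "month", "year", "day", "time",
            "thing", "things", "stuff", "place", "way", "picture", "photo",
            "game", "movie", "show", "book", "song", "weather", "coffee",
            "lunch", "dinner", "park", "city", "street", "car", "train",
            "blue", "green", "red", "small", "big", "new", "old", "nice",
            "cool", "fun", "okay", "yes", "yeah", "hello", "hey", "morningtime")
  M <- category_matrix(base, lexicon)
  base[rowSums(M) == 0]
}

# draw n tokens under per-token category probabilities
sample_tokens <- function(n, probs, lexicon, filler) {
  if (n == 0) return(character(0))
  pool <- c(names(probs), ".filler")
  pr <- c(probs, max(0, 1 - sum(probs)))
  cat_idx <- sample.int(length(pool), n, replace = TRUE, prob = pr)
  out <- character(n)
  for (j in unique(cat_idx)) {
    sel <- cat_idx == j
    words <- if (pool[j] == ".filler") filler
             else sub("\\*$", "", lexicon$categories[[pool[j]]])
    out[sel] <- words[sample.int(length(words), sum(sel), replace = TRUE)]
  }
  out
}

#' Draw the text of one post
#'
#' Token count is `1 + Poisson(8)`; each token comes from a lexicon category
#' with the state-adjusted emission probabilities, otherwise from the neutral
#' filler vocabulary. In the `pre_relapse` state the configured multipliers
#' raise swear/anger/death/hear/feel and pronoun usage and depress
#' work/friends/health/achievement/body usage.
#'
#' @param state `"healthy"` or `"pre_relapse"`.
#' @param lexicon A `lexicon` covering all categories in
#'   `base_category_probs`.
#' @param cfg A [synthetic_config()].
#' @return A single post text string.
#' @export
sample_post_text <- function(state = c("healthy", "pre_relapse"),
                             lexicon = default_lexicon(),
                             cfg = synthetic_config()) {
  state <- match.arg(state)
  miss <- setdiff(names(cfg$base_category_probs), names(lexicon$categories))
  if (length(miss)) stop("lexicon lacks category: ", miss[1])
  n <- 1L + stats::rpois(1, 8)
  paste(sample_tokens(n, token_probs(cfg, state), lexicon,
                      filler_vocabulary(lexicon)), collapse = " ")
}

# minutes-of-day sampler for one diurnal bin (midnight wraps past 24:00)
.bin_minutes <- list(morning = c(5 * 60, 12 * 60),
                     noon = c(12 * 60, 17 * 60),
                     night = c(17 * 60, 22 * 60),
                     midnight = c(22 * 60, 29 * 60))

sample_minute_of_day <- function(bins) {
  out <- integer(length(bins))
  for (b in unique(bins)) {
    sel <- bins == b
    rng <- .bin_minutes[[b]]
    out[sel] <- (sample.int(rng[2] - rng[1], sum(sel), replace = TRUE) - 1L +
                   rng[1]) %% 1440L
  }
  out
}

#' Generate a synthetic cohort
#'
#' Per participant: hospitalization admits spaced Uniform(90, 300) days apart
#' starting at the cohort origin, discharges `inpatient_stay_days` later, and
#' a Poisson event stream at `base_post_rate` per day over the follow-up,
#' with the planted pre-relapse shifts applied inside every
#' `[admit - relapse_window_days, admit)` window (clipped at the previous
#' discharge). All randomness derives from `cfg$seed`; the same seed yields
#' an identical cohort.
#'
#' @param cfg A [synthetic_config()].
#' @param lexicon Lexicon used for text emission (default the built-in
#'   mini-lexicon, shared with the analysis side).
#' @return A `synthetic_cohort`: list with `timelines` (named list of
#'   `timeline` objects), `hospitalizations` (data.frame), `truth` (planted
#'   schedule per participant) and `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config(),
                            lexicon = default_lexicon()) {
  miss <- setdiff(names(cfg$base_category_probs), names(lexicon$categories))
  if (length(miss)) stop("lexicon lacks category: ", miss[1])
  origin <- as.Date("2016-01-01")
  filler <- filler_vocabulary(lexicon)
  probs_h <- token_probs(cfg, "healthy")
  probs_p <- token_probs(cfg, "pre_relapse")
  dw_h <- state_diurnal_weights(cfg, "healthy")
  dw_p <- state_diurnal_weights(cfg, "pre_relapse")
  kp_h <- state_kind_probs(cfg, "healthy")
  kp_p <- state_kind_probs(cfg, "pre_relapse")
  handles <- sprintf("friend_%02d", 1:20)

  timelines <- list()
  hosp <- list()
  truth <- list()
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_participants)) {
      pid <- sprintf("P%03d", i)
      n_h <- sample_one(seq(cfg$hosp_per_participant[1],
                            cfg$hosp_per_participant[2]))
      gaps <- NULL
      for (try in 1:100) {
        g <- round(stats::runif(n_h - 1, 90, 300))
        if (sum(g) <= cfg$followup_days - 1) { gaps <- g; break }
      }
      if (is.null(gaps)) stop("could not place hospitalizations within followup")
      admits <- origin + cumsum(c(0, gaps))
      discharges <- admits + cfg$inpatient_stay_days
      # planted relapse windows, clipped at the previous discharge
      w_start <- pmax(admits[-1] - cfg$relapse_window_days,
                      discharges[-length(discharges)])
      w_end <- admits[-1]

      n_ev <- stats::rpois(1, cfg$base_post_rate * cfg$followup_days)
      day <- sort(stats::runif(n_ev, 0, cfg$followup_days))
      edate <- origin + floor(day)
      pre <- rep(FALSE, n_ev)
      for (k in seq_along(w_start))
        pre <- pre | (edate >= w_start[k] & edate < w_end[k])

      bins <- character(n_ev)
      kinds <- character(n_ev)
      bin_names <- diurnal_bins()
      for (st in c("h", "p")) {
        sel <- if (st == "h") !pre else pre
        if (!any(sel)) next
        dw <- if (st == "h") dw_h else dw_p
        kp <- if (st == "h") kp_h else kp_p
        bins[sel] <- bin_names[sample.int(4, sum(sel), replace = TRUE, prob = dw)]
        kinds[sel] <- names(kp)[sample.int(length(kp), sum(sel),
                                           replace = TRUE, prob = kp)]
      }
      minutes <- sample_minute_of_day(bins)
      ts <- as.POSIXct(edate, tz = "UTC") + minutes * 60

      text <- character(n_ev)
      has_text <- kinds %in% .text_kinds
      ntok <- integer(n_ev)
      ntok[has_text] <- 1L + stats::rpois(sum(has_text), 8)
      for (st in c("h", "p")) {
        sel <- has_text & (if (st == "h") !pre else pre)
        if (!any(sel)) next
        probs <- if (st == "h") probs_h else probs_p
        toks <- sample_tokens(sum(ntok[sel]), probs, lexicon, filler)
        grp <- rep(seq_len(sum(sel)), ntok[sel])
        text[sel] <- vapply(split(toks, grp), paste, "", collapse = " ")
      }

      co_tagged <- rep(list(character(0)), n_ev)
      is_ct <- which(kinds == "co_tag")
      for (j in is_ct)
        co_tagged[[j]] <- handles[sample.int(length(handles),
                                             sample.int(2, 1))]
      sp <- which(kinds %in% c("status", "photo"))
      tagged_sp <- sp[stats::runif(length(sp)) < 0.08]
      for (j in tagged_sp) co_tagged[[j]] <- handles[sample.int(length(handles), 1)]

      tl <- timeline(pid, ts, kinds, text, co_tagged)
      timelines[[pid]] <- tl
      hosp[[pid]] <- data.frame(participant_id = pid, admit_date = admits,
                                discharge_date = discharges,
                                stringsAsFactors = FALSE)
      win_counts <- integer(length(w_start))
      for (k in seq_along(w_start))
        win_counts[k] <- sum(edate >= w_start[k] & edate < w_end[k])
      truth[[pid]] <- list(
        admits = admits, discharges = discharges,
        relapse_windows = data.frame(start = w_start, end = w_end),
        window_event_counts = win_counts,
        multipliers = cfg$effect_multipliers,
        null_effect = all(abs(cfg$effect_multipliers - 1) < 1e-12))
    }
  })
  hospitalizations <- do.call(rbind, hosp)
  rownames(hospitalizations) <- NULL
  structure(list(timelines = timelines, hospitalizations = hospitalizations,
                 truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  n_ev <- sum(vapply(x$timelines, nrow, 0L))
  cat(sprintf("<synthetic_cohort> %d participants, %d events, seed %d\n",
              length(x$timelines), n_ev, x$config$seed))
  invisible(x)
}

#' Row-bind all cohort timelines
#'
#' @param cohort A `synthetic_cohort`.
#' @return One data.frame of all events (sorted within participant).
#' @export
cohort_events <- function(cohort) {
  out <- do.call(rbind, lapply(cohort$timelines, as.data.frame))
  rownames(out) <- NULL
  out
}

#' Write a cohort to disk as canonical fixtures
#'
#' One canonical JSONL timeline per participant, a hospitalization CSV, and
#' the planted truth as JSON; everything loads back through
#' [read_canonical()], [read_hospitalizations()] and [segment_cohort()].
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of written paths.
#' @export
emit_fixture <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tl_paths <- character(0)
  for (pid in names(cohort$timelines)) {
    p <- file.path(out_dir, paste0(pid, ".jsonl"))
    write_canonical(cohort$timelines[[pid]], p)
    tl_paths <- c(tl_paths, p)
  }
  hosp_path <- file.path(out_dir, "hospitalizations.csv")
  write_hospitalizations(cohort$hospitalizations, hosp_path)
  truth_path <- file.path(out_dir, "truth.json")
  truth_out <- lapply(cohort$truth, function(t) {
    list(admits = format(t$admits, "%Y-%m-%d"),
         discharges = format(t$discharges, "%Y-%m-%d"),
         relapse_windows = data.frame(
           start = format(t$relapse_windows$start, "%Y-%m-%d"),
           end = format(t$relapse_windows$end, "%Y-%m-%d")),
         window_event_counts = t$window_event_counts,
         multipliers = as.list(t$multipliers),
         null_effect = t$null_effect)
  })
  jsonlite::write_json(truth_out, truth_path, auto_unbox = TRUE)
  invisible(list(timelines = tl_paths, hospitalizations = hosp_path,
                 truth = truth_path))
}
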