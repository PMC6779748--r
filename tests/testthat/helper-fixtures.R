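# shared fixtures, built in code at test time

tiny_timeline <- function(pid = "P1") {
  timeline(
    participant_id = pid,
    timestamp = c("2017-01-05T06:30", "2017-01-05T12:00", "2017-02-10T23:10",
                  "2017-03-01T17:00", "2017-03-02T04:59"),
    kind = c("status", "like", "co_tag", "status", "comment"),
    text = c("I hate work today", "", "", "feeling fine with friends", "can't stop"),
    co_tagged = list(character(0), character(0), "friend_01",
                     character(0), character(0)))
}

two_admit_hosp <- function(pid = "P1",
                           admits = c("2017-01-01", "2017-06-01"),
                           discharges = NULL) {
  data.frame(participant_id = pid,
             admit_date = as.Date(admits),
             discharge_date = if (is.null(discharges)) as.Date(rep(NA, length(admits)))
                              else as.Date(discharges),
             stringsAsFactors = FALSE)
}

# small cohorts reused across tests, cached per (seed, ...) within the run
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(seed = 1, n = 8, followup = 450, rate = 1.0,
                         multipliers = default_effect_multipliers(),
                         hosp = c(2, min(4, 2 + followup %/% 300))) {
  key <- paste(seed, n, followup, rate, paste(hosp, collapse = "-"),
               paste(round(multipliers, 4), collapse = ","), sep = "|")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  cfg <- synthetic_config(n_participants = n, followup_days = followup,
                          base_post_rate = rate, hosp_per_participant = hosp,
                          effect_multipliers = multipliers, seed = seed)
  co <- generate_cohort(cfg)
  .cohort_cache[[key]] <- co
  co
}

null_multipliers <- function() {
  m <- default_effect_multipliers()
  m[] <- 1
  m
}

# independent brute-force oracle: two-sided exact Wilcoxon signed-rank p by
# enumerating all 2^n sign assignments (mid-ranks, zeros discarded)
wilcoxon_enumeration_oracle <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(statistic = 0, p_value = 1))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_le <- mean(Ws <= W + 1e-12)
  p_ge <- mean(Ws >= W - 1e-12)
  list(statistic = W, p_value = min(1, 2 * min(p_le, p_ge)))
}
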