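test_that("cohort generation is deterministic in the seed", {
  a <- generate_cohort(synthetic_config(n_participants = 3, seed = 123))
  b <- generate_cohort(synthetic_config(n_participants = 3, seed = 123))
  expect_identical(a$timelines, b$timelines)
  expect_identical(a$hospitalizations, b$hospitalizations)
  expect_identical(a$truth, b$truth)

  c2 <- generate_cohort(synthetic_config(n_participants = 3, seed = 124))
  expect_false(identical(a$timelines, c2$timelines))
})

test_that("event volume follows the configured Poisson rate", {
  co <- generate_cohort(synthetic_config(n_participants = 50,
                                         followup_days = 720,
                                         base_post_rate = 2.0, seed = 8))
  total <- sum(vapply(co$timelines, nrow, 0L))
  mu <- 50 * 720 * 2
  expect_lt(abs(total - mu), 3 * sqrt(mu))
})

test_that("null-effect configurations are recorded and neutral", {
  cfg <- synthetic_config(n_participants = 2,
                          effect_multipliers = null_multipliers(), seed = 3)
  co <- generate_cohort(cfg)
  expect_true(all(vapply(co$truth, `[[`, TRUE, "null_effect")))

  co2 <- generate_cohort(synthetic_config(n_participants = 2, seed = 3))
  expect_false(any(vapply(co2$truth, `[[`, TRUE, "null_effect")))
})

test_that("post text respects the category emission probabilities", {
  lex <- default_lexicon()
  cfg0 <- synthetic_config(
    base_category_probs = setNames(rep(0, 36), names(default_category_probs())),
    seed = 1)
  co_cats <- category_matrix(tokenize(withr::with_seed(
    1, paste(replicate(50, sample_post_text("healthy", lex, cfg0)),
             collapse = " "))), lex)
  expect_equal(sum(co_cats), 0)          # all-filler text hits no category

  probs <- default_category_probs()
  probs[] <- 0; probs["swear"] <- 1
  cfg1 <- synthetic_config(base_category_probs = probs, seed = 1)
  toks <- tokenize(withr::with_seed(
    2, paste(replicate(30, sample_post_text("healthy", lex, cfg1)),
             collapse = " ")))
  swear_stems <- sub("\\*$", "", lex$categories$swear)
  expect_true(all(toks %in% swear_stems))   # every token drawn from the list

  # binomial concentration at a 1% swear emission rate
  probs[] <- 0; probs["swear"] <- 0.01
  cfgp <- synthetic_config(base_category_probs = probs, seed = 1)
  toks <- withr::with_seed(3, tokenize(
    paste(replicate(1200, sample_post_text("healthy", lex, cfgp)),
          collapse = " ")))
  prop <- mean(toks %in% swear_stems)       # emitted-from-list frequency
  expect_gt(prop, 0.005)
  expect_lt(prop, 0.015)
})

test_that("pre-relapse multipliers shift emissions in the planted directions", {
  lex <- default_lexicon()
  cfg <- synthetic_config(seed = 1)
  draw <- function(state, seed) withr::with_seed(seed, tokenize(
    paste(replicate(800, sample_post_text(state, lex, cfg)), collapse = " ")))
  th <- draw("healthy", 10)
  tp <- draw("pre_relapse", 11)
  prop <- function(toks, cat) category_proportions(toks, lex)[[cat]]
  expect_gt(prop(tp, "swear"), prop(th, "swear"))
  expect_gt(prop(tp, "hear"), prop(th, "hear"))
  expect_lt(prop(tp, "health"), prop(th, "health"))
  expect_lt(prop(tp, "work"), prop(th, "work"))
})

test_that("fixtures round-trip through files, parsing and segmentation", {
  co <- small_cohort(seed = 17, n = 2, followup = 400)
  dir <- withr::local_tempdir()
  paths <- emit_fixture(co, dir)
  expect_length(paths$timelines, 2)
  expect_true(file.exists(paths$hospitalizations))
  expect_true(file.exists(paths$truth))

  ev <- do.call(rbind, lapply(paths$timelines,
                              function(p) as.data.frame(read_canonical(p))))
  hosp <- read_hospitalizations(paths$hospitalizations)
  expect_equal(hosp, co$hospitalizations)

  periods <- segment_cohort(ev, hosp, segmentation_config())
  for (pid in names(co$truth)) {
    rel <- periods[periods$participant_id == pid & periods$label == "relapse", ]
    expect_equal(rel$start, co$truth[[pid]]$relapse_windows$start)
    expect_equal(rel$end, co$truth[[pid]]$relapse_windows$end)
  }

  truth <- jsonlite::fromJSON(paths$truth)
  expect_setequal(names(truth), names(co$truth))
})

test_that("the generated diurnal mix shifts toward midnight before relapse", {
  co <- small_cohort(seed = 23, n = 10, followup = 600, rate = 2)
  ev <- cohort_events(co)
  pre <- rep(FALSE, nrow(ev))
  for (pid in names(co$truth)) {
    w <- co$truth[[pid]]$relapse_windows
    sel <- ev$participant_id == pid
    d <- as.Date(ev$timestamp[sel], tz = "UTC")
    hit <- rep(FALSE, sum(sel))
    for (k in seq_len(nrow(w))) hit <- hit | (d >= w$start[k] & d < w$end[k])
    pre[sel] <- hit
  }
  bins <- diurnal_bin(ev$timestamp)
  expect_gt(mean(bins[pre] == "midnight"), mean(bins[!pre] == "midnight"))
})
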