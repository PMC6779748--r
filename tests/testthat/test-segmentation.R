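test_that("study window spans first admit to last relapse admit", {
  expect_error(study_window(two_admit_hosp(admits = "2017-01-01")),
               "single admission")

  w <- study_window(two_admit_hosp())
  expect_equal(w$start, as.Date("2017-01-01"))
  expect_equal(w$end, as.Date("2017-06-01"))

  w3 <- study_window(two_admit_hosp(admits = c("2016-03-05", "2016-09-10",
                                               "2017-02-20")))
  expect_equal(w3$start, as.Date("2016-03-05"))
  expect_equal(w3$end, as.Date("2017-02-20"))
})

test_that("relapse windows are the 30 days before each non-index admission", {
  rw <- relapse_windows(two_admit_hosp())
  expect_equal(nrow(rw), 1)
  expect_equal(rw$start, as.Date("2017-05-02"))
  expect_equal(rw$end, as.Date("2017-06-01"))
  expect_equal(rw$label, "relapse")
  expect_equal(rw$anchor, as.Date("2017-06-01"))

  # clipped at the previous discharge
  h <- two_admit_hosp(admits = c("2017-05-01", "2017-06-05"),
                      discharges = c("2017-05-20", NA))
  rw <- relapse_windows(h)
  expect_equal(rw$start, as.Date("2017-05-20"))
  expect_equal(rw$end, as.Date("2017-06-05"))

  # window fully swallowed by the previous stay -> dropped with a warning
  h <- two_admit_hosp(admits = c("2017-05-01", "2017-06-05"),
                      discharges = c("2017-06-05", NA))
  expect_warning(rw <- relapse_windows(h), "dropped")
  expect_equal(nrow(rw), 0)

  expect_error(relapse_windows(two_admit_hosp(admits = c("2017-06-01",
                                                         "2017-01-01"))),
               "sorted")
})

test_that("health periods tile maximal runs and drop short remainders", {
  cfg30 <- segmentation_config(health_granularity_days = 30,
                               exclude_inpatient = FALSE)
  win <- list(start = as.Date("2017-01-01"), end = as.Date("2017-01-01") + 150)
  hp <- health_periods(win, NULL, NULL, cfg30)
  expect_equal(nrow(hp), 5)                       # 150 / 30
  expect_equal(as.numeric(hp$end - hp$start), rep(30, 5))
  expect_equal(hp$start[1], win$start)
  expect_equal(hp$end[5], win$end)

  cfg90 <- segmentation_config(health_granularity_days = 90,
                               exclude_inpatient = FALSE)
  win100 <- list(start = as.Date("2017-01-01"), end = as.Date("2017-01-01") + 100)
  hp90 <- health_periods(win100, NULL, NULL, cfg90)
  expect_equal(nrow(hp90), 1)                     # 10-day remainder dropped

  win20 <- list(start = as.Date("2017-01-01"), end = as.Date("2017-01-01") + 20)
  expect_equal(nrow(health_periods(win20, NULL, NULL, cfg30)), 0)
})

test_that("post assignment follows the half-open convention", {
  periods <- data.frame(participant_id = "P1",
                        start = as.Date("2017-01-01"),
                        end = as.Date("2017-01-31"),
                        label = "health", granularity_days = 30L,
                        anchor = as.Date(NA), n_posts = NA_integer_,
                        excluded = FALSE, stringsAsFactors = FALSE)
  ev <- timeline("P1",
                 c("2017-01-01T00:00", "2017-01-30T23:59", "2017-01-31T00:00"),
                 rep("status", 3), rep("x y", 3))
  out <- assign_posts(ev, periods)
  expect_equal(out$n_posts, 2L)          # start included, end excluded
  expect_equal(attr(out, "assignment"), c(1L, 1L, NA_integer_))

  ten <- timeline("P1", sprintf("2017-01-%02dT10:00", 5:14),
                  rep("status", 10), rep("hi", 10))
  expect_equal(assign_posts(ten, periods)$n_posts, 10L)

  overlapping <- rbind(periods, transform(periods, start = start + 10,
                                          end = end + 10))
  expect_error(assign_posts(ev, overlapping), "overlapping")
})

test_that("segmentation recovers the generator's planted structure", {
  co <- small_cohort(seed = 21, n = 6)
  cfg <- segmentation_config()
  ev <- cohort_events(co)
  periods <- segment_cohort(ev, co$hospitalizations, cfg)

  for (pid in names(co$truth)) {
    tr <- co$truth[[pid]]
    rel <- periods[periods$participant_id == pid & periods$label == "relapse", ]
    expect_equal(rel$start, tr$relapse_windows$start)
    expect_equal(rel$end, tr$relapse_windows$end)
    expect_equal(rel$n_posts, tr$window_event_counts)
  }
})

test_that("periods partition the study window and conserve event counts", {
  for (seed in c(2, 3)) {
    co <- small_cohort(seed = seed, n = 5)
    ev <- cohort_events(co)
    for (g in c(30, 60, 90)) {
      cfg <- segmentation_config(health_granularity_days = g)
      periods <- segment_cohort(ev, co$hospitalizations, cfg)
      asg <- attr(periods, "assignment")

      for (pid in unique(periods$participant_id)) {
        p <- periods[periods$participant_id == pid, ]
        p <- p[order(p$start), ]
        # pairwise disjoint and inside the study window
        if (nrow(p) > 1)
          expect_true(all(head(p$end, -1) <= tail(p$start, -1)))
        h <- co$hospitalizations[co$hospitalizations$participant_id == pid, ]
        win <- study_window(h)
        expect_true(all(p$start >= win$start & p$end <= win$end))

        # conservation: assigned + unassigned == events in the study window
        eidx <- which(ev$participant_id == pid)
        edate <- as.Date(ev$timestamp[eidx], tz = "UTC")
        in_win <- sum(edate >= win$start & edate < win$end)
        assigned <- sum(!is.na(asg[eidx]))
        unassigned_in_win <- sum(is.na(asg[eidx]) &
                                   edate >= win$start & edate < win$end)
        expect_equal(assigned + unassigned_in_win, in_win)
        expect_equal(sum(p$n_posts), assigned)
      }
    }
  }
})

test_that("health period count is non-increasing in granularity", {
  co <- small_cohort(seed = 5, n = 6)
  ev <- cohort_events(co)
  counts <- sapply(c(30, 60, 90), function(g) {
    p <- segment_cohort(ev, co$hospitalizations,
                        segmentation_config(health_granularity_days = g))
    sum(p$label == "health")
  })
  expect_true(counts[1] >= counts[2] && counts[2] >= counts[3])
})
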