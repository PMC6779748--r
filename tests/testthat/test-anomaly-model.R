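test_that("inlier splits reproduce round-half-up held-out counts", {
  ids <- function(n) sprintf("id%04d", seq_len(n))
  expect_equal(length(split_inliers(ids(719), 0.9, seed = 1)$heldout), 72)
  expect_equal(length(split_inliers(ids(421), 0.9, seed = 1)$heldout), 42)
  expect_equal(length(split_inliers(ids(312), 0.9, seed = 1)$heldout), 31)

  s1 <- split_inliers(ids(10), 0.9, seed = 7)
  expect_identical(s1, split_inliers(ids(10), 0.9, seed = 7))
  expect_equal(length(s1$heldout), 1)
  expect_setequal(c(s1$train, s1$heldout), ids(10))

  # participant grouping keeps each participant on one side
  pid <- rep(c("A", "B", "C", "D"), each = 5)
  sp <- split_inliers(ids(20), 0.8, seed = 3, grouping = "participant",
                      participants = pid)
  held_pid <- unique(pid[match(sp$heldout, ids(20))])
  train_pid <- unique(pid[match(sp$train, ids(20))])
  expect_length(intersect(held_pid, train_pid), 0)

  expect_error(split_inliers(ids(1)), ">= 2")
  expect_error(split_inliers(ids(10), 1.0), "train_fraction")
})

test_that("one-class SVM honors the nu rejection property and margins", {
  set.seed(11)
  x <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("f", 1:5)))
  fit <- fit_ocsvm(x, nu = 0.1)
  rej <- fit$train_rejection
  expect_gt(rej, 0.04)
  expect_lt(rej, 0.16)

  # a replicated central training point is an inlier; a far point is not
  center <- x[which.min(rowSums(x^2)), , drop = FALSE]
  expect_true(predict(fit, center))
  far <- matrix(10, 1, 5, dimnames = list(NULL, paste0("f", 1:5)))
  expect_false(predict(fit, far))

  # decision sign convention: f >= 0 <=> inlier
  dec <- predict(fit, x, type = "decision")
  expect_equal(dec >= 0, predict(fit, x))

  bad <- build_matrix(data.frame(participant_id = "A",
                                 start = as.Date("2017-01-01"),
                                 end = as.Date("2017-01-31"), label = "relapse",
                                 granularity_days = 30L, anchor = as.Date(NA),
                                 n_posts = 1L, excluded = FALSE),
                      list(c(f = 1)))
  expect_error(fit_ocsvm(bad), "only health")
})

test_that("a degenerate ensemble reproduces the single model and is seeded", {
  set.seed(2)
  x <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, paste0("f", 1:4)))
  single <- fit_ocsvm(x, nu = 0.1)
  ens1 <- fit_ensemble(x, n_members = 1, row_fraction = 1, feature_fraction = 1,
                       seed = 5, nu = 0.1)
  test <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  expect_equal(predict(ens1, test), predict(single, test))

  ens_a <- fit_ensemble(x, n_members = 10, seed = 9)
  ens_b <- fit_ensemble(x, n_members = 10, seed = 9)
  expect_equal(predict(ens_a, test, type = "votes"),
               predict(ens_b, test, type = "votes"))
})

test_that("raising the vote threshold only grows the flagged-outlier set", {
  set.seed(3)
  x <- matrix(rnorm(150 * 4), 150, 4, dimnames = list(NULL, paste0("f", 1:4)))
  test <- matrix(rnorm(60 * 4, sd = 2), 60, 4,
                 dimnames = list(NULL, paste0("f", 1:4)))
  ens <- fit_ensemble(x, n_members = 15, seed = 1)
  votes <- predict(ens, test, type = "votes")
  prev_out <- NULL
  for (thr in c(0.3, 0.5, 0.8, 1.0)) {
    out <- which(!(votes > thr))            # tie -> outlier
    if (!is.null(prev_out)) expect_true(all(prev_out %in% out))
    prev_out <- out
  }
  expect_equal(which(!(votes > 1.0)), seq_along(votes))  # unanimity required
})

test_that("evaluation implements the health=positive convention exactly", {
  labels <- c(rep("health", 4), rep("relapse", 4))
  pred <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  r <- evaluate_predictions(pred, labels)
  expect_equal(c(r$tp, r$fn, r$fp, r$tn), c(3, 1, 1, 3))
  expect_equal(c(r$sensitivity, r$specificity, r$ppv, r$npv),
               rep(0.75, 4))

  all_right <- evaluate_predictions(labels == "health", labels)
  expect_equal(all_right$sensitivity, 1)
  expect_equal(all_right$specificity, 1)

  none <- evaluate_predictions(rep(FALSE, 8), labels)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$fn, 4)
  expect_true(is.na(none$ppv))              # undefined, never 0

  expect_error(evaluate_predictions(TRUE, labels), "length mismatch")
  expect_error(evaluate_predictions(logical(0), character(0)), "empty")
})

test_that("confusion matrices round-trip through prediction lists", {
  set.seed(6)
  for (rep in 1:20) {
    tp <- sample(0:30, 1); fn <- sample(0:30, 1)
    tn <- sample(0:30, 1); fp <- sample(0:30, 1)
    if (tp + fn == 0 || tn + fp == 0) next
    labels <- c(rep("health", tp + fn), rep("relapse", tn + fp))
    pred <- c(rep(TRUE, tp), rep(FALSE, fn), rep(FALSE, tn), rep(TRUE, fp))
    r <- evaluate_predictions(pred, labels)
    expect_equal(c(r$tp, r$fn, r$tn, r$fp), c(tp, fn, tn, fp))
    expect_equal(r$tp + r$fn, tp + fn)
    expect_equal(r$tn + r$fp, tn + fp)
    if (!is.na(r$sensitivity))
      expect_equal(r$sensitivity, tp / (tp + fn))
  }
})

test_that("count reconstruction recovers published predictive values", {
  r <- reconstruct_counts(0.47, 0.65, 71, 49)
  expect_equal(c(r$tp, r$tn, r$fp), c(33, 32, 17))
  expect_equal(round(r$ppv, 2), 0.66)
  expect_equal(round(r$npv, 2), 0.46)

  perfect <- reconstruct_counts(1, 1, 10, 10)
  expect_equal(perfect$ppv, 1)
  expect_equal(perfect$npv, 1)

  e <- reconstruct_counts(0.38, 0.71, 72, 49)
  expect_equal(e$tp, 27)
  expect_equal(e$fn, 45)
})
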