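mk_periods <- function(n, pid = "P1", label = "health") {
  data.frame(participant_id = pid,
             start = as.Date("2017-01-01") + 30 * (seq_len(n) - 1),
             end = as.Date("2017-01-01") + 30 * seq_len(n),
             label = label, granularity_days = 30L, anchor = as.Date(NA),
             n_posts = 1L, excluded = FALSE, stringsAsFactors = FALSE)
}

test_that("feature matrix assembly backfills, orders and rejects duplicates", {
  p <- mk_periods(2)
  fm <- build_matrix(p, list(c(b = 1, a = 2), c(a = 3, c = 4)))
  expect_equal(dim(fm$x), c(2, 3))
  expect_equal(colnames(fm$x), c("a", "b", "c"))      # sorted names
  expect_equal(unname(fm$x[1, ]), c(2, 1, 0))          # absent -> 0
  expect_equal(unname(fm$x[2, ]), c(3, 0, 4))

  dup <- rbind(p, p[1, ])
  expect_error(build_matrix(dup, list(c(a = 1), c(a = 2), c(a = 3))),
               "duplicate period ids")
})

test_that("featurization is deterministic for a fixed cohort", {
  co <- small_cohort(seed = 31, n = 3)
  ev <- cohort_events(co)
  periods <- segment_cohort(ev, co$hospitalizations, segmentation_config())
  f1 <- featurize_periods(ev, periods)
  f2 <- featurize_periods(ev, periods)
  expect_identical(f1$x, f2$x)
})

test_that("CoV statistics match hand computations", {
  x <- cbind(const = c(2, 2, 2), ab = c(1, 3, 2))
  rep1 <- cov_select(x, k_sd = 10)
  expect_equal(unname(rep1$cov["const"]), 0)           # sd 0 -> cov 0

  x2 <- cbind(a = c(1, 3))
  expect_equal(unname(cov_select(cbind(x2, b = c(2, 2)), k_sd = 10)$cov["a"]),
               sqrt(2) / 2, tolerance = 1e-9)          # mean 2, sample sd sqrt(2)

  # three columns with CoVs {0.10, 0.12, 5.00}: only the outlying column falls
  # outside one sample-sd of the mean CoV and is eliminated
  mk_col <- function(cv) {
    z <- c(-1, 0, 1) / sqrt(var(c(-1, 0, 1)))   # mean 0, sample sd 1
    1 + cv * z                                  # mean 1, cov = cv
  }
  x3 <- cbind(f1 = mk_col(0.10), f2 = mk_col(0.12), f3 = mk_col(5.00))
  rep3 <- cov_select(x3)
  expect_equal(unname(rep3$cov), c(0.10, 0.12, 5.00), tolerance = 1e-9)
  expect_equal(rep3$cov_mean, mean(c(0.1, 0.12, 5)), tolerance = 1e-9)
  expect_equal(rep3$cov_sd, sd(c(0.1, 0.12, 5)), tolerance = 1e-9)
  expect_setequal(rep3$retained, c("f1", "f2"))

  inv <- cov_select(x3, mode = "keep_outside")
  expect_setequal(inv$retained, "f3")

  expect_error(cov_select(x3[1, , drop = FALSE]), ">= 2")
})

test_that("CoV is invariant under positive column scaling and deterministic", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(abs(rnorm(60, mean = 3)), 10, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    r1 <- cov_select(x)
    scaled <- sweep(x, 2, runif(6, 0.1, 10), "*")
    r2 <- cov_select(scaled)
    expect_equal(r1$cov, r2$cov, tolerance = 1e-9)
    expect_identical(r1$retained, r2$retained)
    expect_identical(cov_select(x)$retained, r1$retained)
  }
})

test_that("standardization round-trips and respects training statistics", {
  set.seed(8)
  x <- matrix(rnorm(50, 5, 2), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  z <- standardize(x)
  expect_equal(unname(colMeans(z)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, 5), tolerance = 1e-12)

  st <- attr(z, "stats")
  back <- sweep(sweep(unclass(z), 2, st$sd, "*"), 2, st$mean, "+")
  expect_equal(back, x, tolerance = 1e-12, ignore_attr = TRUE)

  xc <- cbind(x, const = 7)
  expect_true(all(standardize(xc)[, "const"] == 0))

  test <- matrix(rnorm(10, 5, 2), 2, 5, dimnames = list(NULL, paste0("f", 1:5)))
  zt <- standardize(test, train_stats(x))
  expect_equal(unclass(zt), sweep(sweep(test, 2, st$mean, "-"), 2, st$sd, "/"),
               tolerance = 1e-12, ignore_attr = TRUE)

  rogue <- matrix(0, 2, 1, dimnames = list(NULL, "new_col"))
  expect_error(standardize(rogue, train_stats(x)), "not in training")
})

test_that("two-pass and streaming column statistics agree", {
  set.seed(99)
  x <- matrix(rnorm(2000), 100, 20)
  stream_mean <- numeric(20); stream_m2 <- numeric(20)
  for (i in 1:100) {
    d <- x[i, ] - stream_mean
    stream_mean <- stream_mean + d / i
    stream_m2 <- stream_m2 + d * (x[i, ] - stream_mean)
  }
  expect_equal(stream_mean, colMeans(x), tolerance = 1e-12)
  expect_equal(sqrt(stream_m2 / 99), apply(x, 2, sd), tolerance = 1e-12)
})
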