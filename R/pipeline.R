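# End-to-end relapse-detection pipeline: segmentation -> features ->
# CoV selection -> standardization -> one-class model -> evaluation on the
# held-out inliers plus all relapse periods.

#' Run the relapse-detection pipeline
#'
#' Segments every participant's study window at the requested health
#' granularity, splits the health periods 90/10 into training and held-out
#' inliers, builds the unigram vocabulary from training-period texts only,
#' featurizes all periods, performs coefficient-of-variation feature
#' selection and z-standardization on training statistics, fits a single or
#' ensemble one-class SVM on the training inliers, and evaluates on the
#' held-out health periods together with all relapse periods (which are
#' never trained on).
#'
#' @param events Row-bound timelines of the cohort (or a single `timeline`).
#' @param hospitalizations Hospitalization table
#'   (see [read_hospitalizations()]).
#' @param lexicon A `lexicon` (default the built-in mini-lexicon).
#' @param granularity_days Health period length: 30, 60 or 90.
#' @param model `"ensemble"` (default) or `"single"`.
#' @param nu,gamma,kernel One-class SVM parameters (see [fit_ocsvm()]).
#' @param k_unigrams Unigram vocabulary size; 0 disables unigram features.
#' @param cov_k_sd,cov_mode CoV selection parameters (see [cov_select()]).
#' @param train_fraction Inlier fraction used for training (default 0.9).
#' @param grouping Split grouping, `"period"` (default) or `"participant"`.
#' @param n_members,row_fraction,feature_fraction,vote_threshold Ensemble
#'   parameters (see [fit_ensemble()]).
#' @param seed Integer seed driving the split and ensemble subsampling.
#' @param cfg A [segmentation_config()]; its granularity is overridden by
#'   `granularity_days`.
#' @return A `relapse_pipeline` object: list with `report` (an
#'   `eval_report`), `model`, `cov` (a `cov_report`), `split`, `features`
#'   (standardized, selected test-set `feature_matrix`), `features_all` (raw
#'   feature matrix over all usable periods, e.g. for [feature_screen()]),
#'   `periods`, `vocabulary`, `heldout_decision` and `heldout_labels`.
#' @export
relapse_pipeline <- function(events, hospitalizations,
                             lexicon = default_lexicon(),
                             granularity_days = 30,
                             model = c("ensemble", "single"),
                             nu = 0.1, gamma = "median",
                             kernel = c("rbf", "linear"),
                             k_unigrams = 200,
                             cov_k_sd = 1,
                             cov_mode = "eliminate_outside",
                             train_fraction = 0.9,
                             grouping = c("period", "participant"),
                             n_members = 25, row_fraction = 0.8,
                             feature_fraction = 0.7, vote_threshold = 0.5,
                             seed = 1,
                             cfg = segmentation_config()) {
  model <- match.arg(model)
  kernel <- match.arg(kernel)
  grouping <- match.arg(grouping)
  cfg$health_granularity_days <- as.integer(granularity_days)

  periods <- segment_cohort(events, hospitalizations, cfg)
  usable <- periods[!periods$excluded, , drop = FALSE]
  ids <- period_id(usable)
  health_ids <- ids[usable$label == "health"]
  relapse_ids <- ids[usable$label == "relapse"]
  if (length(relapse_ids) == 0) stop("no relapse periods with data")

  split <- split_inliers(health_ids, train_fraction = train_fraction,
                         seed = seed, grouping = grouping,
                         participants = usable$participant_id[usable$label == "health"])

  vocabulary <- NULL
  if (k_unigrams > 0) {
    txt <- period_texts(events, periods, split$train)
    txt <- txt[nzchar(txt)]
    if (length(txt)) vocabulary <- build_vocabulary(txt, k_unigrams)
  }

  fm <- featurize_periods(events, periods, lexicon, vocabulary = vocabulary)
  train_fm <- fm_subset(fm, rows = split$train)
  cov <- cov_select(train_fm, k_sd = cov_k_sd, mode = cov_mode)
  train_fm <- fm_subset(train_fm, cols = cov$retained)
  stats <- train_stats(train_fm)
  train_fm <- standardize(train_fm, stats)
  test_ids <- c(split$heldout, relapse_ids)
  test_fm <- standardize(fm_subset(fm, rows = test_ids, cols = cov$retained),
                         stats)

  fit <- if (model == "ensemble") {
    fit_ensemble(train_fm, n_members = n_members, row_fraction = row_fraction,
                 feature_fraction = feature_fraction,
                 vote_threshold = vote_threshold, seed = seed,
                 nu = nu, gamma = gamma, kernel = kernel)
  } else {
    fit_ocsvm(train_fm, nu = nu, gamma = gamma, kernel = kernel)
  }

  pred <- predict(fit, test_fm)
  labels <- test_fm$periods$label
  decision <- if (model == "ensemble") predict(fit, test_fm, type = "votes")
              else predict(fit, test_fm, type = "decision")
  report <- evaluate_predictions(pred, labels)

  structure(list(report = report, model = fit, cov = cov, split = split,
                 features = test_fm, features_all = fm, periods = periods,
                 vocabulary = vocabulary,
                 heldout_decision = decision, heldout_labels = labels,
                 granularity_days = granularity_days, seed = seed,
                 call = match.call()),
            class = "relapse_pipeline")
}

#' @export
print.relapse_pipeline <- function(x, ...) {
  cat(sprintf("<relapse_pipeline> %d-day health periods, %s model, seed %d\n",
              x$granularity_days,
              if (inherits(x$model, "ocsvm_ensemble")) "ensemble" else "single",
              x$seed))
  cat(sprintf("  features: %d retained of %d after CoV selection\n",
              length(x$cov$retained), length(x$cov$cov)))
  cat(sprintf("  train inliers %d | held-out health %d | relapse %d\n",
              length(x$split$train),
              sum(x$heldout_labels == "health"),
              sum(x$heldout_labels == "relapse")))
  print(x$report)
  invisible(x)
}

#' @export
summary.relapse_pipeline <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Plot the test-set decision values by class
#'
#' Strip chart of the model score (ensemble inlier-vote fraction, or the
#' one-class decision value) for held-out health vs relapse periods, with the
#' decision boundary drawn.
#'
#' @param x A `relapse_pipeline`.
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.relapse_pipeline <- function(x, ...) {
  d <- split(x$heldout_decision, x$heldout_labels)
  graphics::stripchart(d, vertical = TRUE, method = "jitter", pch = 16,
                       col = c("#2166ac88", "#b2182b88"),
                       ylab = if (inherits(x$model, "ocsvm_ensemble"))
                         "inlier vote fraction" else "decision value",
                       main = "Test periods: model score by class", ...)
  cut <- if (inherits(x$model, "ocsvm_ensemble")) x$model$vote_threshold else 0
  graphics::abline(h = cut, lty = 2)
  invisible(x)
}
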