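# One-class SVM anomaly models over period features.
#
# Periods of relative health are the positive class (inliers); periods of
# relapse are negative (outliers). Under this convention sensitivity measures
# recognizing health and specificity measures catching relapse. The ensemble
# is a bagging reconstruction: members are one-class SVMs fit on seeded row
# and feature subsamples, combined by majority vote with ties flagged as
# outliers (favoring relapse detection, in line with the emphasis on
# specificity).

#' Train / held-out split of the inlier periods
#'
#' The held-out count is `round((1 - train_fraction) * n)` with round-half-up
#' (so 719/421/312 inliers at `train_fraction = 0.9` hold out 72/42/31
#' periods); the draw is uniform and reproducible from `seed`. With
#' `grouping = "participant"` all periods of a participant land on one side:
#' participants are shuffled and moved to the held-out side until its size
#' first reaches the target count.
#'
#' @param ids Character vector of inlier period ids.
#' @param train_fraction Fraction of inliers used for training (default 0.9).
#' @param seed Integer seed.
#' @param grouping `"period"` (default) or `"participant"`.
#' @param participants Participant id per element of `ids` (required for
#'   participant grouping).
#' @return list with character vectors `train` and `heldout`.
#' @export
split_inliers <- function(ids, train_fraction = 0.9, seed = 1,
                          grouping = c("period", "participant"),
                          participants = NULL) {
  grouping <- match.arg(grouping)
  n <- length(ids)
  if (n < 2) stop("need >= 2 inlier periods to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  k <- round_half_up((1 - train_fraction) * n)
  if (k < 1 || k >= n) stop("split leaves an empty train or held-out side")
  heldout <- with_seed(seed, {
    if (grouping == "period") {
      ids[sample.int(n, k)]
    } else {
      if (is.null(participants) || length(participants) != n)
        stop("participant grouping needs one participant id per period id")
      po <- sample(unique(participants))
      take <- character(0)
      for (p in po) {
        take <- c(take, ids[participants == p])
        if (length(take) >= k) break
      }
      take
    }
  })
  if (length(heldout) >= n) stop("split leaves an empty train side")
  list(train = setdiff(ids, heldout), heldout = heldout)
}

check_health_only <- function(fm) {
  if (inherits(fm, "feature_matrix") && any(fm$periods$label != "health"))
    stop("training input must contain only health-labeled periods")
}

fm_x <- function(fm) if (inherits(fm, "feature_matrix")) fm$x else as.matrix(fm)

resolve_gamma <- function(x, gamma) {
  if (identical(gamma, "median")) {
    # median pairwise squared distance heuristic: the typical point pair sits
    # at kernel value exp(-1), which keeps the boundary from collapsing onto
    # individual training points when features are sparse and heavy-tailed
    d2 <- as.vector(stats::dist(x))^2
    d2 <- d2[d2 > 0]
    m <- if (length(d2)) stats::median(d2) else NA_real_
    if (!is.finite(m) || m <= 0) 1 / ncol(x) else 1 / m
  } else if (identical(gamma, "scale")) {
    v <- stats::var(as.vector(x))
    if (is.na(v) || v <= 0) 1 / ncol(x) else 1 / (ncol(x) * v)
  } else as.numeric(gamma)
}

#' Fit a one-class SVM on health periods
#'
#' Wraps a nu-parameterized one-class support vector machine trained on
#' inlier (health) periods only. `nu` upper-bounds the fraction of training
#' inliers rejected. `gamma = "median"` (the default) sets the RBF width by
#' the median-pairwise-squared-distance heuristic, which keeps held-out
#' inlier rejection close to `nu` on sparse standardized features;
#' `gamma = "scale"` uses `1 / (p * var(x))`. The fitted object exposes a
#' decision function with `f >= 0` meaning inlier.
#'
#' @param fm A `feature_matrix` of health periods (cov-selected,
#'   standardized) or a numeric matrix.
#' @param nu Training inlier-rejection bound in (0, 1] (default 0.1).
#' @param gamma RBF kernel width: a positive number, `"median"` or `"scale"`.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @return An object of class `ocsvm`.
#' @export
fit_ocsvm <- function(fm, nu = 0.1, gamma = "median", kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  check_health_only(fm)
  x <- fm_x(fm)
  g <- resolve_gamma(x, gamma)
  svm_kernel <- if (kernel == "rbf") "radial" else "linear"
  model <- e1071::svm(x, y = NULL, type = "one-classification",
                      kernel = svm_kernel, nu = nu, gamma = g, scale = FALSE)
  # orient the decision function so that f >= 0 <=> predicted inlier
  dec <- attr(stats::predict(model, x, decision.values = TRUE),
              "decision.values")
  pr <- as.logical(stats::predict(model, x))
  flip <- if (any(pr) && any(!pr)) {
    mean(dec[pr]) < mean(dec[!pr])
  } else FALSE
  structure(list(svm = model, columns = colnames(x), nu = nu, gamma = g,
                 kernel = kernel, flip = flip,
                 n_train = nrow(x),
                 train_rejection = mean(!pr)),
            class = "ocsvm")
}

align_columns <- function(newdata, columns) {
  x <- fm_x(newdata)
  miss <- setdiff(columns, colnames(x))
  if (length(miss)) stop("prediction input lacks feature column: ", miss[1])
  x[, columns, drop = FALSE]
}

#' Predict method for one-class SVM fits
#'
#' @param object An `ocsvm` fit.
#' @param newdata A `feature_matrix` or matrix with the training columns.
#' @param type `"class"` for a logical inlier vector, `"decision"` for the
#'   real-valued decision function (`>= 0` means inlier).
#' @param ... Unused.
#' @return Logical or numeric vector, one element per row.
#' @export
predict.ocsvm <- function(object, newdata, type = c("class", "decision"), ...) {
  type <- match.arg(type)
  x <- align_columns(newdata, object$columns)
  dec <- attr(stats::predict(object$svm, x, decision.values = TRUE),
              "decision.values")
  dec <- as.vector(dec)
  if (object$flip) dec <- -dec
  if (type == "decision") dec else dec >= 0
}

#' @export
print.ocsvm <- function(x, ...) {
  cat(sprintf("<ocsvm> %s kernel, nu = %g, gamma = %.4g, %d training periods\n",
              x$kernel, x$nu, x$gamma, x$n_train))
  cat(sprintf("  training inlier rejection: %.3f\n", x$train_rejection))
  invisible(x)
}

#' @export
summary.ocsvm <- function(object, ...) {
  print(object)
  cat(sprintf("  support vectors: %d / %d\n",
              object$svm$tot.nSV, object$n_train))
  invisible(object)
}

#' Fit a bagged ensemble of one-class SVMs
#'
#' Fits `n_members` one-class SVMs, each on a seeded row subsample (fraction
#' `row_fraction`, without replacement) and feature subsample (fraction
#' `feature_fraction`). A point is predicted inlier iff the fraction of
#' members voting inlier strictly exceeds `vote_threshold`; an exact tie is
#' an outlier.
#'
#' @inheritParams fit_ocsvm
#' @param n_members Number of ensemble members (default 25).
#' @param row_fraction Fraction of training periods per member (default 0.8).
#' @param feature_fraction Fraction of features per member (default 0.7).
#' @param vote_threshold Inlier-vote fraction that must be exceeded
#'   (default 0.5).
#' @param seed Integer seed driving all member subsamples.
#' @return An object of class `ocsvm_ensemble`.
#' @export
fit_ensemble <- function(fm, n_members = 25, row_fraction = 0.8,
                         feature_fraction = 0.7, vote_threshold = 0.5,
                         seed = 1, nu = 0.1, gamma = "median",
                         kernel = c("rbf", "linear")) {
  kernel <- match.arg(kernel)
  stopifnot(n_members >= 1, row_fraction > 0, row_fraction <= 1,
            feature_fraction > 0, feature_fraction <= 1,
            vote_threshold > 0, vote_threshold <= 1)
  check_health_only(fm)
  x <- fm_x(fm)
  n <- nrow(x); p <- ncol(x)
  members <- with_seed(seed, {
    lapply(seq_len(n_members), function(i) {
      rows <- sample.int(n, max(2L, round_half_up(row_fraction * n)))
      cols <- colnames(x)[sample.int(p, max(1L, round_half_up(feature_fraction * p)))]
      fit <- tryCatch(
        fit_ocsvm(x[rows, cols, drop = FALSE], nu = nu, gamma = gamma,
                  kernel = kernel),
        error = function(e) stop(sprintf("ensemble member %d failed: %s",
                                         i, conditionMessage(e)), call. = FALSE))
      fit
    })
  })
  structure(list(members = members, n_members = n_members,
                 row_fraction = row_fraction,
                 feature_fraction = feature_fraction,
                 vote_threshold = vote_threshold, seed = seed,
                 nu = nu, kernel = kernel, columns = colnames(x),
                 n_train = n),
            class = "ocsvm_ensemble")
}

#' Predict method for ensemble fits
#'
#' @param object An `ocsvm_ensemble`.
#' @param newdata A `feature_matrix` or matrix carrying the training columns.
#' @param type `"class"` for logical inlier predictions, `"votes"` for the
#'   fraction of members voting inlier.
#' @param ... Unused.
#' @return Logical or numeric vector, one element per row.
#' @export
predict.ocsvm_ensemble <- function(object, newdata,
                                   type = c("class", "votes"), ...) {
  type <- match.arg(type)
  x <- align_columns(newdata, object$columns)
  votes <- vapply(object$members,
                  function(m) as.numeric(predict(m, x)),
                  numeric(nrow(x)))
  if (nrow(x) == 1) votes <- matrix(votes, nrow = 1)
  frac <- rowMeans(votes)
  if (type == "votes") frac else frac > object$vote_threshold
}

#' @export
print.ocsvm_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<ocsvm_ensemble> %d members (rows %.0f%%, features %.0f%%),",
                     " vote threshold %g, nu = %g\n"),
              x$n_members, 100 * x$row_fraction, 100 * x$feature_fraction,
              x$vote_threshold, x$nu))
  invisible(x)
}

#' @export
summary.ocsvm_ensemble <- function(object, ...) {
  print(object)
  rej <- vapply(object$members, `[[`, 0, "train_rejection")
  cat(sprintf("  member training rejection: %.3f (range %.3f-%.3f)\n",
              mean(rej), min(rej), max(rej)))
  invisible(object)
}

mk_rate <- function(num, den) if (den == 0) NA_real_ else num / den

#' Evaluate predictions under the health = positive convention
#'
#' Health predicted inlier is a true positive; health predicted outlier is a
#' false negative; relapse predicted outlier is a true negative; relapse
#' predicted inlier is a false positive. Rates with an undefined denominator
#' are reported as `NA` (never 0).
#'
#' @param inlier_pred Logical vector: TRUE where the model predicts inlier.
#' @param labels Character vector in `{"health", "relapse"}`, aligned with
#'   `inlier_pred`.
#' @return An `eval_report` with counts `tp, fn, tn, fp` and rates
#'   `sensitivity, specificity, ppv, npv`.
#' @export
evaluate_predictions <- function(inlier_pred, labels) {
  if (length(inlier_pred) != length(labels)) stop("length mismatch")
  if (length(labels) == 0) stop("empty evaluation input")
  if (!all(labels %in% c("health", "relapse")))
    stop("labels must be 'health' or 'relapse'")
  inlier_pred <- as.logical(inlier_pred)
  tp <- sum(labels == "health" & inlier_pred)
  fn <- sum(labels == "health" & !inlier_pred)
  tn <- sum(labels == "relapse" & !inlier_pred)
  fp <- sum(labels == "relapse" & inlier_pred)
  new_eval_report(tp, fn, tn, fp)
}

new_eval_report <- function(tp, fn, tn, fp) {
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp,
                 sensitivity = mk_rate(tp, tp + fn),
                 specificity = mk_rate(tn, tn + fp),
                 ppv = mk_rate(tp, tp + fp),
                 npv = mk_rate(tn, tn + fn),
                 convention = "health=positive(inlier), relapse=negative(outlier)"),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat("<eval_report> ", x$convention, "\n", sep = "")
  cat(sprintf("  tp %d  fn %d  tn %d  fp %d\n", x$tp, x$fn, x$tn, x$fp))
  fmt <- function(v) if (is.na(v)) "NA" else format(round(v, digits), nsmall = digits)
  cat(sprintf("  sensitivity %s  specificity %s  ppv %s  npv %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Reconstruct a confusion matrix from printed rates and class counts
#'
#' Given a published sensitivity, specificity and test-set class sizes,
#' rebuilds the integer confusion counts (`tp = round(sens * n_health)`,
#' `tn = round(spec * n_relapse)`, round-half-up, complements for `fn`/`fp`)
#' and the implied PPV/NPV. This makes internal-consistency checks of
#' reported performance tables possible without the underlying data.
#'
#' @param sensitivity,specificity Printed rates in [0, 1].
#' @param n_health,n_relapse Test-set class counts (>= 1).
#' @return An `eval_report`.
#' @export
reconstruct_counts <- function(sensitivity, specificity, n_health, n_relapse) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            n_health >= 1, n_relapse >= 1)
  tp <- round_half_up(sensitivity * n_health)
  tn <- round_half_up(specificity * n_relapse)
  new_eval_report(tp = tp, fn = n_health - tp, tn = tn, fp = n_relapse - tn)
}
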