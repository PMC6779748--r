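# Assembly of the periods x features matrix, coefficient-of-variation feature
# selection, and z-standardization against training statistics.

#' Assemble a feature matrix
#'
#' Rows are periods (sorted by participant then start date, identified by
#' `participant_id|start|end`), columns are the union of all feature names in
#' sorted order; a feature absent for some period is backfilled as 0, so the
#' matrix never contains missing values.
#'
#' @param periods Periods data.frame (one row per feature vector).
#' @param features List of named numeric vectors, one per period row.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `periods`
#'   (the reordered periods data.frame) and `provenance`.
#' @export
build_matrix <- function(periods, features, provenance = NULL) {
  stopifnot(nrow(periods) == length(features))
  ids <- period_id(periods)
  if (anyDuplicated(ids)) stop("duplicate period ids: ",
                               ids[duplicated(ids)][1])
  cols <- sort(unique(unlist(lapply(features, names), use.names = FALSE)))
  x <- matrix(0, nrow(periods), length(cols), dimnames = list(ids, cols))
  for (i in seq_along(features)) {
    f <- features[[i]]
    if (length(f)) x[i, names(f)] <- as.numeric(f)
  }
  ord <- order(periods$participant_id, periods$start)
  periods <- periods[ord, , drop = FALSE]
  rownames(periods) <- NULL
  structure(list(x = x[ord, , drop = FALSE], periods = periods,
                 provenance = provenance),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d periods x %d features (%d relapse, %d health)\n",
              nrow(x$x), ncol(x$x),
              sum(x$periods$label == "relapse"),
              sum(x$periods$label == "health")))
  invisible(x)
}

#' Subset a feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param rows Row ids (character) or indices; NULL keeps all.
#' @param cols Column names; NULL keeps all.
#' @return A `feature_matrix`.
#' @export
fm_subset <- function(fm, rows = NULL, cols = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(fm$x))
  if (is.character(rows)) {
    idx <- match(rows, rownames(fm$x))
    if (anyNA(idx)) stop("unknown period id: ", rows[is.na(idx)][1])
    rows <- idx
  }
  if (is.null(cols)) cols <- colnames(fm$x)
  if (!all(cols %in% colnames(fm$x)))
    stop("unknown feature column: ", setdiff(cols, colnames(fm$x))[1])
  structure(list(x = fm$x[rows, cols, drop = FALSE],
                 periods = fm$periods[rows, , drop = FALSE],
                 provenance = fm$provenance),
            class = "feature_matrix")
}

#' Coefficient-of-variation feature selection
#'
#' For each feature the coefficient of variation is the sample standard
#' deviation over the absolute mean across training periods (0 by convention
#' for zero-mean columns, which are flagged). Under the default
#' `eliminate_outside` mode a feature is retained iff its CoV lies within
#' `k_sd` standard deviations of the mean CoV; `keep_outside` inverts the
#' retention test. The decision is deterministic given the matrix, `k_sd`
#' and mode, and recomputable from the returned report.
#'
#' @param train A `feature_matrix` (training rows only) or numeric matrix
#'   with at least 2 rows.
#' @param k_sd Width of the retention band in CoV standard deviations
#'   (default 1).
#' @param mode `"eliminate_outside"` (default) or `"keep_outside"`.
#' @return A `cov_report`: per-feature `cov`, `cov_mean`, `cov_sd`,
#'   `retained` (ordered feature names), `mode`, `k_sd`, `zero_mean`.
#' @export
cov_select <- function(train, k_sd = 1,
                       mode = c("eliminate_outside", "keep_outside")) {
  mode <- match.arg(mode)
  x <- if (inherits(train, "feature_matrix")) train$x else as.matrix(train)
  if (nrow(x) < 2) stop("cov_select needs >= 2 training rows")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  zero_mean <- m == 0
  if (any(zero_mean & s > 0))
    warning(sum(zero_mean & s > 0),
            " zero-mean column(s) assigned CoV 0 by convention")
  cv <- ifelse(zero_mean, 0, s / abs(m))
  cov_mean <- mean(cv)
  cov_sd <- stats::sd(cv)
  inside <- abs(cv - cov_mean) <= k_sd * cov_sd
  keep <- if (mode == "eliminate_outside") inside else !inside
  retained <- colnames(x)[keep]
  if (length(retained) == 0)
    stop("empty selection: no feature satisfies the CoV retention rule")
  structure(list(cov = stats::setNames(cv, colnames(x)),
                 cov_mean = cov_mean, cov_sd = cov_sd,
                 retained = retained, mode = mode, k_sd = k_sd,
                 zero_mean = colnames(x)[zero_mean]),
            class = "cov_report")
}

#' @export
print.cov_report <- function(x, ...) {
  cat(sprintf("<cov_report> %d/%d features retained (mode %s, k_sd %g)\n",
              length(x$retained), length(x$cov), x$mode, x$k_sd))
  cat(sprintf("  CoV mean %.4f, sd %.4f\n", x$cov_mean, x$cov_sd))
  invisible(x)
}

#' Column statistics for standardization
#'
#' @param train A `feature_matrix` or matrix of training rows.
#' @return list with named `mean` and `sd` vectors (sample sd).
#' @export
train_stats <- function(train) {
  x <- if (inherits(train, "feature_matrix")) train$x else as.matrix(train)
  list(mean = colMeans(x), sd = apply(x, 2, stats::sd))
}

#' Standardize features against training statistics
#'
#' Maps each column to `(x - mean) / sd` using statistics computed on the
#' training split (so held-out rows never influence the scaling); columns
#' with zero training sd map to 0. A column absent from the statistics is a
#' schema error.
#'
#' @param fm A `feature_matrix` or numeric matrix.
#' @param stats Output of [train_stats()]; NULL computes them from `fm`
#'   itself (training use).
#' @return Object of the same class with standardized values and attribute
#'   `stats`.
#' @export
standardize <- function(fm, stats = NULL) {
  is_fm <- inherits(fm, "feature_matrix")
  x <- if (is_fm) fm$x else as.matrix(fm)
  if (is.null(stats)) stats <- train_stats(x)
  unseen <- setdiff(colnames(x), names(stats$mean))
  if (length(unseen)) stop("column not in training statistics: ", unseen[1])
  mu <- stats$mean[colnames(x)]
  sdv <- stats$sd[colnames(x)]
  z <- sweep(x, 2, mu, "-")
  pos <- sdv > 0
  z[, pos] <- sweep(z[, pos, drop = FALSE], 2, sdv[pos], "/")
  z[, !pos] <- 0
  if (is_fm) {
    fm$x <- z
    attr(fm, "stats") <- stats
    fm
  } else structure(z, stats = stats)
}
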