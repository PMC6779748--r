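# Glue from assigned periods to the feature matrix: psycholinguistic
# proportions, structural language measures, unigram usage and behavioral
# activity rates, one row per period.

#' Featurize periods
#'
#' Computes, per period: category proportions over the pooled tokens of its
#' events, structural features (readability, repeatability, mean word
#' length), optional unigram proportions over a training-derived vocabulary,
#' and activity rates by kind and diurnal bin (30-day normalized by default).
#' Periods flagged `excluded` are dropped from the matrix.
#'
#' @param events Row-bound timelines of the cohort.
#' @param periods Periods with assignment state (from [assign_posts()] or
#'   [segment_cohort()]); re-assigned here if the attribute is missing.
#' @param lexicon A `lexicon` (default [default_lexicon()]).
#' @param vocabulary Unigram vocabulary built with [build_vocabulary()] on
#'   training texts only; NULL skips unigram features.
#' @param normalize Normalize activity counts to per-30-day rates.
#' @param min_posts Exclusion threshold forwarded to [assign_posts()] when
#'   assignment must be recomputed.
#' @return A `feature_matrix` over the non-excluded periods.
#' @export
featurize_periods <- function(events, periods, lexicon = default_lexicon(),
                              vocabulary = NULL, normalize = TRUE,
                              min_posts = 1) {
  assignment <- attr(periods, "assignment")
  if (is.null(assignment)) {
    periods <- assign_posts(events, periods, min_posts)
    assignment <- attr(periods, "assignment")
  }
  keep <- which(!periods$excluded)
  if (!length(keep)) stop("all periods excluded; nothing to featurize")

  tokens_by_event <- tokenize_many(events$text)
  # one pass over the unique tokens of the corpus for category matching
  all_tokens <- unlist(tokens_by_event, use.names = FALSE)
  ut <- unique(all_tokens)
  M <- category_matrix(ut, lexicon)
  cat_names <- colnames(M)

  feats <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    ev_idx <- which(assignment == i)
    ev <- events[ev_idx, , drop = FALSE]
    toks <- unlist(tokens_by_event[ev_idx], use.names = FALSE)
    if (length(toks)) {
      cnt <- as.vector(table(factor(toks, levels = ut)))
      lingu <- stats::setNames(as.vector(crossprod(M, cnt)) / length(toks),
                               cat_names)
    } else {
      lingu <- stats::setNames(numeric(length(cat_names)), cat_names)
    }
    f <- c(lingu,
           structural_features(ev$text),
           activity_features(periods[i, , drop = FALSE], ev,
                             normalize = normalize))
    if (!is.null(vocabulary))
      f <- c(f, unigram_features(toks, vocabulary))
    feats[[j]] <- f
  }
  build_matrix(periods[keep, , drop = FALSE], feats,
               provenance = list(normalize = normalize,
                                 k_unigrams = length(vocabulary)))
}

# pooled text of a set of period rows (by id), for vocabulary building
period_texts <- function(events, periods, ids) {
  assignment <- attr(periods, "assignment")
  rows <- match(ids, period_id(periods))
  idx <- which(assignment %in% rows)
  events$text[idx]
}
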