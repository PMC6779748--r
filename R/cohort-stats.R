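# Exploratory cohort screen: per participant, pair one randomly chosen
# relapse period with one health period, then run a paired Wilcoxon
# signed-rank test per feature. The W+ statistic (sum of ranks of positive
# differences) is reported; p-values are exact by sign-flip enumeration up to
# n = 25 effective pairs and normal-approximated (with tie and continuity
# corrections) beyond.

#' Sample one relapse/health period pair per participant
#'
#' For every participant having at least one non-excluded period of each
#' label, draws exactly one relapse and one health period uniformly at
#' random; participants lacking either label are excluded and counted
#' (attribute `n_excluded`). The draw is reproducible from `seed`.
#'
#' @param periods Periods data.frame (excluded periods are ignored).
#' @param seed Integer seed for the paired draw.
#' @return data.frame with `participant_id`, `relapse_id`, `health_id`
#'   (period ids matching feature-matrix row names).
#' @export
sample_pairs <- function(periods, seed = 1) {
  periods <- periods[!periods$excluded, , drop = FALSE]
  ids <- period_id(periods)
  pids <- unique(periods$participant_id)
  out <- list()
  n_excluded <- 0L
  with_seed(seed, {
    for (pid in pids) {
      r <- ids[periods$participant_id == pid & periods$label == "relapse"]
      h <- ids[periods$participant_id == pid & periods$label == "health"]
      if (length(r) == 0 || length(h) == 0) {
        n_excluded <- n_excluded + 1L
        next
      }
      out[[pid]] <- data.frame(participant_id = pid,
                               relapse_id = sample_one(r),
                               health_id = sample_one(h),
                               stringsAsFactors = FALSE)
    }
  })
  if (length(out) == 0) stop("no participant has both a relapse and a health period")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excluded
  res
}

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are discarded (classic Wilcoxon convention); tied
#' absolute differences receive mid-ranks. The statistic is W+, the sum of
#' ranks of positive differences. For up to 25 effective pairs the two-sided
#' p-value is exact, computed over all `2^n` equiprobable sign assignments
#' (as `2 * min(P(W <= w), P(W >= w))`, capped at 1); beyond that a normal
#' approximation with tie correction and continuity correction is used. All
#' differences zero gives `statistic = 0, p = 1`.
#'
#' @param x,y Paired numeric vectors of equal length >= 1.
#' @return list with `statistic` (W+), `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), and `n_effective` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 1) stop("need at least one pair")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, method = "exact", n_effective = 0L))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25) {
    # exact null distribution of W+ by convolution over doubled (integer) ranks
    dr <- as.integer(round(2 * r))
    S <- sum(dr)
    g <- numeric(S + 1)          # g[s+1] = number of sign assignments with 2*W = s
    g[1] <- 1
    for (ri in dr) {
      shifted <- c(numeric(ri), g[seq_len(S + 1 - ri)])
      g <- g + shifted
    }
    total <- 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(g[seq_len(w2 + 1)]) / total
    p_ge <- sum(g[(w2 + 1):(S + 1)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = W, p_value = p, method = "exact", n_effective = n)
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    list(statistic = W, p_value = p, method = "normal_approx", n_effective = n)
  }
}

#' Per-feature Wilcoxon screen over sampled pairs
#'
#' Runs [wilcoxon_signed_rank()] on every feature column across the sampled
#' relapse/health pairs and reports class means, W+ and the p-value, sorted
#' by p ascending. p-values are reported raw; Benjamini-Hochberg q-values can
#' be added as an extra column.
#'
#' @param fm A `feature_matrix` containing every period referenced in `pairs`.
#' @param pairs Output of [sample_pairs()].
#' @param adjust Add a BH `q_value` column (default FALSE).
#' @return data.frame with one row per feature: `feature`, `n_pairs`,
#'   `mean_relapse`, `mean_health`, `statistic`, `p_value`, `method`
#'   (and `q_value` when requested).
#' @export
feature_screen <- function(fm, pairs, adjust = FALSE) {
  ri <- match(pairs$relapse_id, rownames(fm$x))
  hi <- match(pairs$health_id, rownames(fm$x))
  if (anyNA(ri) || anyNA(hi))
    stop("pair period missing from the feature matrix")
  cols <- colnames(fm$x)
  res <- vector("list", length(cols))
  for (j in seq_along(cols)) {
    xr <- fm$x[ri, j]
    xh <- fm$x[hi, j]
    w <- wilcoxon_signed_rank(xr, xh)
    res[[j]] <- data.frame(feature = cols[j],
                           n_pairs = length(xr),
                           mean_relapse = mean(xr),
                           mean_health = mean(xh),
                           statistic = w$statistic,
                           p_value = w$p_value,
                           method = w$method,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (adjust) out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
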