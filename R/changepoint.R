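# Changepoint detection for per-user daily context series: binary
# segmentation with a CUSUM-type two-sample statistic, accepted only when a
# permutation test rejects homogeneity.

cusum_stat <- function(x, min_segment) {
  n <- length(x)
  t_range <- seq(min_segment, n - min_segment)
  cs <- cumsum(x)
  tot <- cs[n]
  mean_l <- cs[t_range] / t_range
  mean_r <- (tot - cs[t_range]) / (n - t_range)
  stat <- sqrt(t_range * (n - t_range) / n) * abs(mean_l - mean_r)
  list(stat = max(stat), at = t_range[which.max(stat)])
}

#' Detect a changepoint in a daily context series
#'
#' Finds the split maximising the between-segment difference in means
#' (weighted CUSUM statistic) and accepts it only if a permutation test
#' rejects homogeneity at level \code{alpha}. Missing days are allowed and
#' simply skipped; segment-length requirements count observed days.
#'
#' @param phi Numeric vector of daily context ratios (may contain
#'   \code{NA}).
#' @param days Optional integer day indices aligned with \code{phi};
#'   defaults to \code{seq_along(phi)}.
#' @param min_segment Minimum observed days on each side of a candidate
#'   changepoint (default 10).
#' @param n_perm Number of permutations (default 999).
#' @param alpha Significance level (default 0.01).
#' @return The day index of the first post-change observation, or
#'   \code{NA} if no significant changepoint is found (with a warning when
#'   the series is too short to test).
#' @examples
#' x <- c(rnorm(40, 0.08, 0.02), rnorm(40, 0.25, 0.02))
#' detect_context_changepoint(x)
#' @export
detect_context_changepoint <- function(phi, days = seq_along(phi),
                                       min_segment = 10L, n_perm = 999L,
                                       alpha = 0.01) {
  keep <- !is.na(phi)
  x <- phi[keep]
  d <- days[keep]
  n <- length(x)
  if (n < 2L * min_segment) {
    warn(sprintf("series has %d observed days, fewer than 2 x min_segment = %d: no changepoint test.",
                 n, 2L * min_segment))
    return(NA_integer_)
  }
  if (sd(x) < 1e-12) return(NA_integer_)
  obs <- cusum_stat(x, min_segment)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- cusum_stat(sample(x), min_segment)
    if (perm$stat >= obs$stat) exceed <- exceed + 1L
  }
  p_val <- (1 + exceed) / (n_perm + 1)
  if (p_val > alpha) return(NA_integer_)
  as.integer(d[obs$at + 1L])
}

#' Classify a context transition at the Low/High threshold
#'
#' Pre- and post-change mean context ratios are each labelled Low
#' (\eqn{\phi \le} threshold) or High (\eqn{\phi >} threshold); a mean of
#' exactly the threshold is Low. Returns one of \code{"LL"}, \code{"LH"},
#' \code{"HL"}, \code{"HH"}.
#'
#' @param pre_mean,post_mean Mean context ratios before/after the change.
#' @param threshold Low/High boundary (default 0.13).
#' @return Character group label (vectorised).
#' @examples
#' classify_transition(0.10, 0.20)
#' @export
classify_transition <- function(pre_mean, post_mean, threshold = 0.13) {
  lab <- function(m) ifelse(m > threshold, "H", "L")
  paste0(lab(pre_mean), lab(post_mean))
}

#' Detect habitual-context transitions for every user
#'
#' Runs [detect_context_changepoint()] on each user's daily pre-lunch
#' context series (daily mean \eqn{\phi}) and classifies significant
#' changes with [classify_transition()].
#'
#' @param contexts Lunch decision contexts (or any context tibble with
#'   \code{user_id}, \code{day}, \code{phi_context}).
#' @param threshold Low/High boundary (default 0.13).
#' @inheritParams detect_context_changepoint
#' @return A tibble of transitions: \code{user_id}, \code{change_day},
#'   \code{pre_mean_phi}, \code{post_mean_phi}, \code{group}.
#' @export
detect_transitions <- function(contexts, threshold = 0.13,
                               min_segment = 10L, n_perm = 999L,
                               alpha = 0.01) {
  daily <- contexts %>%
    group_by(.data$user_id, .data$day) %>%
    summarise(phi = mean(.data$phi_context), .groups = "drop") %>%
    arrange(.data$user_id, .data$day)
  res <- daily %>%
    group_by(.data$user_id) %>%
    dplyr::group_modify(function(df, key) {
      cd <- suppressWarnings(
        detect_context_changepoint(df$phi, df$day, min_segment = min_segment,
                                   n_perm = n_perm, alpha = alpha))
      if (is.na(cd)) return(tibble())
      pre <- mean(df$phi[df$day < cd])
      post <- mean(df$phi[df$day >= cd])
      tibble(change_day = cd, pre_mean_phi = pre, post_mean_phi = post)
    }) %>%
    ungroup()
  if (nrow(res) == 0) {
    return(tibble(user_id = integer(), change_day = integer(),
                  pre_mean_phi = numeric(), post_mean_phi = numeric(),
                  group = character()))
  }
  res$group <- classify_transition(res$pre_mean_phi, res$post_mean_phi,
                                   threshold)
  res
}
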