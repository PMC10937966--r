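# Event-time pooling of fast-food visit fractions around each user's
# context-change day. Calendar-day effects are absorbed by comparing
# treated groups (Low->High, High->Low) with control groups that also
# changed location but stayed in a similar food environment (Low->Low,
# High->High), aligned the same way.

#' Build per-group aligned visit-fraction series
#'
#' Pools lunch decisions across each transition group's users by aligned
#' day (day minus the user's change day; negative = pre-change). The
#' group-level fraction is (fast-food lunch visits) / (all lunch food
#' visits) pooled over users -- equivalently, a visit-count-weighted mean
#' of per-user fractions; \code{method = "per_user"} instead averages
#' per-user daily fractions unweighted.
#'
#' @param transitions Tibble from [detect_transitions()] (or generative
#'   truth with the same columns).
#' @param contexts Lunch decision contexts with outcomes.
#' @param window_days Aligned-day window half-width (default 50).
#' @param method Pooling rule: \code{"pooled"} (default) or
#'   \code{"per_user"}.
#' @return A tibble: \code{group}, \code{aligned_day}, \code{frac},
#'   \code{n} (decisions pooled). Groups with no users are omitted with a
#'   warning.
#' @export
build_group_series <- function(transitions, contexts, window_days = 50L,
                               method = c("pooled", "per_user")) {
  method <- match.arg(method)
  if (nrow(transitions) == 0) abort("no transitions supplied.")
  missing_groups <- setdiff(c("LL", "LH", "HL", "HH"),
                            unique(transitions$group))
  if (length(missing_groups) > 0)
    warn(sprintf("empty transition group(s) omitted: %s",
                 paste(missing_groups, collapse = ", ")))
  dat <- contexts %>%
    filter(!is.na(.data$outcome)) %>%
    inner_join(transitions %>% select("user_id", "change_day", "group"),
               by = "user_id") %>%
    mutate(aligned_day = .data$day - .data$change_day) %>%
    filter(abs(.data$aligned_day) <= window_days)
  if (method == "pooled") {
    dat %>%
      group_by(.data$group, .data$aligned_day) %>%
      summarise(frac = mean(.data$outcome), n = n(), .groups = "drop")
  } else {
    dat %>%
      group_by(.data$group, .data$aligned_day, .data$user_id) %>%
      summarise(u_frac = mean(.data$outcome), .groups = "drop") %>%
      group_by(.data$group, .data$aligned_day) %>%
      summarise(frac = mean(.data$u_frac), n = n(), .groups = "drop")
  }
}
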