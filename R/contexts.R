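# Decision contexts: the location a user occupied immediately before a
# food-outlet decision, its environment ratio phi, and the binary outcome
# (1 = fast food). Three context kinds: pre-lunch ("lunch"), every stay
# ("fullday"), and DMV stays ("dmv").
#
# Conventions (applied consistently and tested at the boundaries):
#   * the context stay must START strictly before the cutoff (11:30); the
#     stay itself may extend past it;
#   * "within 2 hours" windows are half-open on the left and closed on the
#     right: (stay_end, stay_end + 120];
#   * when several food visits fall in a window, the first by timestamp
#     defines the outcome;
#   * a context is retained only when its environment contains both outlet
#     types (some fast food and some non-fast food).

# phi + both-types filter columns for a set of context locations
context_env <- function(ctx, pois, cfg) {
  st <- config_env(ctx, pois, cfg)
  ctx$phi_context <- st$phi
  ctx$n_fo <- st$n_fo
  ctx$n_ffo <- st$n_ffo
  ctx
}

# both-types filter: environment must offer FFO and non-FFO alternatives
filter_both_types <- function(ctx) {
  ctx %>% filter(!is.na(.data$phi_context),
                 .data$n_ffo > 0, .data$n_ffo < .data$n_fo)
}

first_visit_in <- function(visits, pois, keys, left_closed = FALSE) {
  # first FO visit per context key; windows are [lo, hi) when left_closed
  # (clock windows like lunch) and (lo, hi] otherwise (post-stay windows).
  # visits are food visits already, but re-check against the POI table
  fo_ids <- pois$poi_id[pois$is_food_outlet]
  v <- visits %>%
    filter(.data$poi_id %in% fo_ids) %>%
    inner_join(keys, by = c("user_id", "day"))
  v <- if (left_closed) {
    v %>% filter(.data$minute >= .data$.lo, .data$minute < .data$.hi)
  } else {
    v %>% filter(.data$minute > .data$.lo, .data$minute <= .data$.hi)
  }
  v %>%
    arrange(.data$.ctx_id, .data$minute) %>%
    distinct(.data$.ctx_id, .keep_all = TRUE)
}

#' Extract pre-lunch decision contexts
#'
#' For every user-day, the context is the last stay starting strictly
#' before the cutoff (default 11:30); the outcome is 1 if the first
#' food-outlet visit inside the lunch window (default 11:30-14:00,
#' half-open) is a fast-food outlet, 0 if non-fast-food, and the row is
#' dropped when no lunch food visit occurred. Contexts whose environment
#' lacks either outlet type are dropped (no real choice existed).
#'
#' @param stays,visits,pois Tables from the generator (or equivalent
#'   observational data in the same schema).
#' @param config A [sim_config()].
#' @return A tibble of decision contexts: \code{user_id}, \code{day},
#'   \code{x}, \code{y}, \code{phi_context}, \code{outcome},
#'   \code{context_kind}, \code{decision_minute}, and the environment
#'   counts \code{n_fo}, \code{n_ffo}. (Area membership is attached later
#'   by the intervention layer via [assign_area()].) Attribute
#'   \code{"filter_log"} records row counts after each filtering rule.
#' @export
extract_lunch_contexts <- function(stays, visits, pois, config) {
  cfg <- validate_sim_config(config)
  cutoff <- cfg$context_cutoff
  lw <- cfg$lunch_window

  ctx <- stays %>%
    filter(.data$start_min < cutoff) %>%
    arrange(.data$user_id, .data$day, dplyr::desc(.data$start_min)) %>%
    distinct(.data$user_id, .data$day, .keep_all = TRUE) %>%
    select("user_id", "day", "x", "y")
  n_ctx <- nrow(ctx)
  ctx$.ctx_id <- seq_len(n_ctx)
  ctx$.lo <- lw[1]
  ctx$.hi <- lw[2]

  fv <- first_visit_in(visits, pois,
                       keys = ctx %>% select("user_id", "day", ".ctx_id",
                                             ".lo", ".hi"),
                       left_closed = TRUE)
  ctx <- ctx %>%
    inner_join(fv %>% select(".ctx_id", "minute", "is_ffo"), by = ".ctx_id")
  n_with_outcome <- nrow(ctx)

  ctx <- context_env(ctx, pois, cfg)
  out <- filter_both_types(ctx)
  n_final <- nrow(out)

  res <- tibble(
    user_id = out$user_id, day = out$day, x = out$x, y = out$y,
    phi_context = out$phi_context, outcome = as.integer(out$is_ffo),
    context_kind = "lunch", decision_minute = out$minute,
    n_fo = out$n_fo, n_ffo = out$n_ffo
  )
  attr(res, "filter_log") <- c(contexts = n_ctx,
                               with_lunch_visit = n_with_outcome,
                               both_types = n_final)
  res
}

#' Extract full-day decision contexts
#'
#' Treats every stay as a context and looks for a food visit within the
#' two hours after the stay ends (window half-open left, closed right).
#' The outcome is \code{NA} when no food visit falls in the window; the
#' both-outlet-types environment filter is applied as for lunch contexts.
#'
#' @inheritParams extract_lunch_contexts
#' @return A tibble as in [extract_lunch_contexts()], with
#'   \code{context_kind = "fullday"} and possibly missing outcomes.
#' @export
extract_fullday_contexts <- function(stays, visits, pois, config) {
  cfg <- validate_sim_config(config)
  ctx <- stays %>%
    mutate(.end = .data$start_min + .data$duration_min) %>%
    select("user_id", "day", "x", "y", ".end")
  n_ctx <- nrow(ctx)
  ctx$.ctx_id <- seq_len(n_ctx)
  ctx$.lo <- ctx$.end
  ctx$.hi <- ctx$.end + 120

  fv <- first_visit_in(visits, pois,
                       keys = ctx %>% select("user_id", "day", ".ctx_id",
                                             ".lo", ".hi"))
  ctx <- ctx %>%
    left_join(fv %>% select(".ctx_id", "minute", "is_ffo"), by = ".ctx_id")

  ctx <- context_env(ctx, pois, cfg)
  out <- filter_both_types(ctx)

  res <- tibble(
    user_id = out$user_id, day = out$day, x = out$x, y = out$y,
    phi_context = out$phi_context, outcome = as.integer(out$is_ffo),
    context_kind = "fullday", decision_minute = out$minute,
    n_fo = out$n_fo, n_ffo = out$n_ffo
  )
  attr(res, "filter_log") <- c(contexts = n_ctx, both_types = nrow(out))
  res
}

#' Extract DMV decision contexts
#'
#' The DMV stay is the context of a food visit occurring within two hours
#' after the stay ends (a visit at exactly 120 minutes counts). User-days
#' with no such visit produce no row: people who ate before or after their
#' DMV errand are thereby filtered out, so the model conditions on a food
#' outing having happened.
#'
#' @param dmv_stays DMV stay table from [simulate_dmv_visits()].
#' @inheritParams extract_lunch_contexts
#' @return A tibble as in [extract_lunch_contexts()], with
#'   \code{context_kind = "dmv"}.
#' @export
extract_dmv_contexts <- function(dmv_stays, visits, pois, config) {
  cfg <- validate_sim_config(config)
  ctx <- dmv_stays %>%
    mutate(.end = .data$start_min + .data$duration_min) %>%
    select("user_id", "day", "x", "y", ".end")
  ctx$.ctx_id <- seq_len(nrow(ctx))
  ctx$.lo <- ctx$.end
  ctx$.hi <- ctx$.end + 120

  fv <- first_visit_in(visits, pois,
                       keys = ctx %>% select("user_id", "day", ".ctx_id",
                                             ".lo", ".hi"))
  ctx <- ctx %>%
    inner_join(fv %>% select(".ctx_id", "minute", "is_ffo"), by = ".ctx_id")

  ctx <- context_env(ctx, pois, cfg)
  out <- filter_both_types(ctx)

  res <- tibble(
    user_id = out$user_id, day = out$day, x = out$x, y = out$y,
    phi_context = out$phi_context, outcome = as.integer(out$is_ffo),
    context_kind = "dmv", decision_minute = out$minute,
    n_fo = out$n_fo, n_ffo = out$n_ffo
  )
  attr(res, "filter_log") <- c(contexts = nrow(dmv_stays),
                               with_visit_2h = nrow(ctx),
                               both_types = nrow(res))
  res
}
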