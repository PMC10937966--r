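# Per-user exposure profiles: home environment phi_h = phi(h_i), mobile
# exposure phi_m = duration-weighted mean of phi over all stays, and the
# fast-food visit fraction mu_i = (FFO visits) / (all FO visits).

#' Compute per-user exposure profiles
#'
#' \code{phi_home} is the environment ratio at the user's home;
#' \code{phi_mobile} is the stay-duration-weighted mean of \eqn{\phi} over
#' all the user's stays (food-related or not), with stays whose environment
#' is undefined (no food outlet in range) dropped together with their
#' weight; \code{mu} is the fraction of the user's food-outlet visits that
#' are to fast-food outlets, \code{NA} for users with no food visits.
#' Users with no stays are omitted with a warning.
#'
#' @param users User table from [generate_users()] (needs \code{user_id},
#'   \code{home_x}, \code{home_y}).
#' @param stays Stay table from [simulate_mobility()].
#' @param visits Food-visit table from [simulate_food_decisions()].
#' @param pois POI table.
#' @param config A [sim_config()]; supplies the environment definition.
#' @return A tibble: \code{user_id}, \code{phi_home}, \code{phi_mobile},
#'   \code{mu}, \code{n_food_visits}.
#' @export
compute_exposure_profiles <- function(users, stays, visits, pois, config) {
  cfg <- validate_sim_config(config)
  no_stays <- setdiff(users$user_id, unique(stays$user_id))
  if (length(no_stays) > 0)
    warn(sprintf("%d user(s) without stays omitted from exposure profiles.",
                 length(no_stays)))
  keep <- users[!users$user_id %in% no_stays, , drop = FALSE]

  phi_home <- config_env(
    tibble(x = keep$home_x, y = keep$home_y), pois, cfg)$phi

  stays$phi <- config_env(stays, pois, cfg)$phi
  mob <- stays %>%
    filter(!is.na(.data$phi)) %>%
    group_by(.data$user_id) %>%
    summarise(phi_mobile = sum(.data$duration_min * .data$phi) /
                sum(.data$duration_min), .groups = "drop")

  mu_tab <- visits %>%
    group_by(.data$user_id) %>%
    summarise(mu = mean(.data$is_ffo), n_food_visits = n(),
              .groups = "drop")

  tibble(user_id = keep$user_id, phi_home = phi_home) %>%
    left_join(mob, by = "user_id") %>%
    left_join(mu_tab, by = "user_id") %>%
    mutate(n_food_visits = dplyr::coalesce(.data$n_food_visits, 0L))
}
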