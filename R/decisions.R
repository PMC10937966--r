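# Generative food-visit decisions. Conditional on a lunch outing, the
# visited outlet is fast food with probability
#   logit^-1(beta0 + alpha_i + delta_t + beta * phi(c_it)),
# where c_it is the last pre-cutoff stay of the user-day. Outing occurrence
# itself is an exogenous Bernoulli draw; days whose context has no food
# outlet in range produce no outing and are logged.

#' Simulate lunch (and DMV) food-visit decisions
#'
#' For every user-day whose pre-lunch context has a defined food
#' environment, a lunch outing occurs with probability \code{outing_prob};
#' the outlet type is drawn from the generative fixed-effects logistic
#' model, and a concrete outlet of that type is sampled among food outlets
#' within the environment radius of the context (nearest outlet of the type
#' as fallback). Day effects \eqn{\delta_t} are drawn once per day. When
#' \code{dmv_stays} is supplied, those user-days use the DMV stay as
#' context and the visit lands within two hours after the DMV stay ends.
#'
#' The generative truth (per-decision \eqn{\phi}, linear predictor, and
#' probability) is attached as attribute \code{"truth"}; the number of
#' user-days skipped for lack of any food outlet in range is attached as
#' \code{"n_skipped_no_fo"}.
#'
#' @param config A [sim_config()].
#' @param users,stays,pois Tables from the upstream generator stages.
#' @param dmv_stays Optional DMV stay table from [simulate_dmv_visits()].
#' @return A tibble of food visits: \code{user_id}, \code{day},
#'   \code{minute}, \code{poi_id}, \code{is_ffo}.
#' @export
simulate_food_decisions <- function(config, users, stays, pois,
                                    dmv_stays = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, 5L))
  cutoff <- cfg$context_cutoff
  lw <- cfg$lunch_window

  ctx <- stays %>%
    filter(.data$start_min < cutoff) %>%
    arrange(.data$user_id, .data$day, dplyr::desc(.data$start_min)) %>%
    distinct(.data$user_id, .data$day, .keep_all = TRUE) %>%
    select("user_id", "day", "x", "y")
  ctx$context_kind <- "lunch"

  if (!is.null(dmv_stays) && nrow(dmv_stays) > 0) {
    dmv_ctx <- dmv_stays %>%
      mutate(end_min = .data$start_min + .data$duration_min) %>%
      select("user_id", "day", "x", "y", "end_min")
    dmv_ctx$context_kind <- "dmv"
    ctx <- ctx %>%
      anti_join(dmv_ctx, by = c("user_id", "day")) %>%
      bind_rows(dmv_ctx)
  }

  st <- config_env(ctx, pois, cfg)
  ctx$phi <- st$phi
  ctx$n_fo <- st$n_fo
  no_fo <- is.na(ctx$phi) | ctx$n_fo == 0
  n_skipped <- sum(no_fo)
  ctx <- ctx[!no_fo, , drop = FALSE]

  delta <- if (cfg$delta_sd > 0) rnorm(cfg$n_days, 0, cfg$delta_sd) else
    rep(0, cfg$n_days)
  outing <- runif(nrow(ctx)) < cfg$outing_prob
  dec <- ctx[outing, , drop = FALSE]
  alpha <- users$alpha[match(dec$user_id, users$user_id)]
  eta <- cfg$beta0 + alpha + delta[dec$day] + cfg$beta * dec$phi
  p <- plogis(eta)
  y <- runif(nrow(dec)) < p
  # degenerate cities: if one outlet type does not exist at all, decisions
  # can only realise the other type
  fo_all <- pois[pois$is_food_outlet, , drop = FALSE]
  if (!any(fo_all$is_ffo)) y[] <- FALSE
  if (all(fo_all$is_ffo)) y[] <- TRUE

  # concrete outlet: uniform among in-radius food outlets of the drawn
  # type; nearest outlet of the type anywhere as fallback
  dec$poi_id <- pick_outlet(dec, y, pois, cfg)

  is_dmv <- dec$context_kind == "dmv"
  minute <- numeric(nrow(dec))
  minute[!is_dmv] <- floor(runif(sum(!is_dmv), lw[1], lw[2]))
  if (any(is_dmv))
    minute[is_dmv] <- floor(dec$end_min[is_dmv] + runif(sum(is_dmv), 1, 120))
  visits <- tibble(
    user_id = dec$user_id, day = dec$day, minute = minute,
    poi_id = dec$poi_id, is_ffo = y
  ) %>% arrange(.data$user_id, .data$day, .data$minute)

  outcome_flag <- y
  truth <- tibble(
    user_id = dec$user_id, day = dec$day, kind = dec$context_kind,
    x = dec$x, y = dec$y, phi = dec$phi, eta = eta, p = p,
    ffo = outcome_flag
  )
  attr(visits, "truth") <- truth
  attr(visits, "n_skipped_no_fo") <- n_skipped
  visits
}

# For each decision row, sample a food outlet of the drawn type near the
# context. Grouped by unique (context location, type) for speed.
pick_outlet <- function(dec, y, pois, cfg) {
  fo <- pois[pois$is_food_outlet, , drop = FALSE]
  key <- paste(dec$x, dec$y, sep = "\r")
  uk <- which(!duplicated(key))
  out <- integer(nrow(dec))
  r2 <- cfg$env_radius_m^2
  for (i in uk) {
    rows <- which(key == key[i])
    d2 <- (fo$x - dec$x[i])^2 + (fo$y - dec$y[i])^2
    for (type in c(TRUE, FALSE)) {
      rr <- rows[y[rows] == type]
      if (length(rr) == 0) next
      cand <- which(d2 <= r2 & fo$is_ffo == type)
      if (length(cand) == 0) {
        of_type <- which(fo$is_ffo == type)
        cand <- of_type[which.min(d2[of_type])]
      }
      out[rr] <- fo$poi_id[cand[sample.int(length(cand), length(rr),
                                           replace = TRUE)]]
    }
  }
  out
}
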