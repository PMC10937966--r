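# Synthetic user population: homes, habitual morning anchors, latent
# fast-food preferences, and a small fraction of habitual-context changers.

#' Generate synthetic users
#'
#' Homes are uniform over the city extent. Each user has a habitual morning
#' anchor at a non-food POI, biased towards commercial (office/mall/airport)
#' areas. Latent preferences are \eqn{\alpha_i \sim N(0,
#' \mathrm{alpha\_sd}^2)}. A fraction \code{context_change_fraction} of users
#' relocates its anchor on a mid-study day; changers are assigned round-robin
#' to the four transition cells (Low/High fast-food exposure before and
#' after, threshold 0.13) so that every cell is populated when enough
#' changers exist. Income quantile derives from the home area's income rank.
#'
#' @param config A [sim_config()].
#' @param areas,pois City tables from [generate_city()].
#' @return A tibble with one row per user: home and anchor coordinates,
#'   anchor POI ids, \code{alpha}, \code{anchor_change_day} (NA for
#'   non-changers), post-change anchor, target transition cell, and
#'   \code{income_quantile} (1 = lowest).
#' @export
generate_users <- function(config, areas, pois) {
  cfg <- validate_sim_config(config)
  if (nrow(areas) == 0) abort("`areas` must be non-empty.")
  set.seed(stage_seed(cfg$seed, 2L))
  n <- cfg$n_users
  extent <- cfg$city_extent_m

  users <- tibble(
    user_id = seq_len(n),
    home_x = runif(n, 0, extent),
    home_y = runif(n, 0, extent),
    alpha = if (cfg$alpha_sd > 0) rnorm(n, 0, cfg$alpha_sd) else rep(0, n)
  )

  # anchor candidates: non-food, non-DMV POIs, weighted toward commercial areas
  cand <- pois %>% filter(!.data$is_food_outlet, .data$category != "dmv")
  if (nrow(cand) == 0) abort("no non-food POIs available as anchors.")
  cand_profile <- areas$profile[match(cand$area_id, areas$area_id)]
  wgt <- ifelse(cand_profile == "residential", 1, 4)
  pick <- sample.int(nrow(cand), n, replace = TRUE, prob = wgt)
  users$anchor_x <- cand$x[pick]
  users$anchor_y <- cand$y[pick]
  users$anchor_poi <- cand$poi_id[pick]

  # context-change cohort with stratified pre/post anchors
  users$anchor_change_day <- NA_integer_
  users$post_anchor_x <- NA_real_
  users$post_anchor_y <- NA_real_
  users$post_anchor_poi <- NA_integer_
  users$change_target <- NA_character_
  is_changer <- runif(n) < cfg$context_change_fraction
  n_ch <- sum(is_changer)
  if (n_ch > 0) {
    st_cand <- config_env(cand, pois, cfg)
    phi_cand <- st_cand$phi
    # changers are planted at anchors whose environment offers both outlet
    # types, so their pre/post context days survive the choice filter
    ok <- !is.na(phi_cand) & st_cand$n_ffo > 0 & st_cand$n_ffo < st_cand$n_fo
    low_pool <- which(ok & phi_cand < 0.10)
    high_pool <- which(ok & phi_cand > 0.20)
    if (length(low_pool) == 0) low_pool <- which(ok & phi_cand <= 0.13)
    if (length(high_pool) == 0) high_pool <- which(ok & phi_cand > 0.13)
    if (length(low_pool) == 0) low_pool <- which.min(phi_cand)
    if (length(high_pool) == 0) high_pool <- which.max(phi_cand)
    pools <- list(L = low_pool, H = high_pool)
    targets <- rep(c("LH", "HL", "LL", "HH"), length.out = n_ch)
    ch_idx <- which(is_changer)
    d_lo <- ceiling(0.2 * cfg$n_days)
    d_hi <- floor(0.8 * cfg$n_days)
    for (j in seq_len(n_ch)) {
      u <- ch_idx[j]
      tg <- targets[j]
      pre <- pools[[substr(tg, 1, 1)]]
      post <- pools[[substr(tg, 2, 2)]]
      pre_pick <- pre[sample.int(length(pre), 1L)]
      post_pick <- post[sample.int(length(post), 1L)]
      if (length(post) > 1 && post_pick == pre_pick)
        post_pick <- post[post != pre_pick][sample.int(length(post) - 1L, 1L)]
      users$anchor_x[u] <- cand$x[pre_pick]
      users$anchor_y[u] <- cand$y[pre_pick]
      users$anchor_poi[u] <- cand$poi_id[pre_pick]
      users$post_anchor_x[u] <- cand$x[post_pick]
      users$post_anchor_y[u] <- cand$y[post_pick]
      users$post_anchor_poi[u] <- cand$poi_id[post_pick]
      users$anchor_change_day[u] <- sample(seq(d_lo, d_hi), 1L)
      users$change_target[u] <- tg
    }
  }

  home_area <- assign_area(tibble(x = users$home_x, y = users$home_y), areas)
  users$home_area_id <- home_area
  area_quint <- ntile(areas$median_income, 5)
  users$income_quantile <- area_quint[match(home_area, areas$area_id)]
  users
}
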