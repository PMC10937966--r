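# Activity-based daily stay trajectories. Every user-day follows the same
# skeleton: overnight at home, a morning block at the habitual anchor that
# spans the pre-lunch cutoff, on some days a late-morning errand at a nearby
# POI (which then becomes the last pre-lunch stay -- the decision context),
# an afternoon block back at the anchor, and an evening at home. The errand
# days supply the within-user variation in context phi without which the
# environment coefficient would be absorbed by the user fixed effects.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate daily stay trajectories
#'
#' Emits one stay sequence per user-day. All stays last at least
#' \code{stay_min_duration_min} minutes and carry the id of the closest POI.
#' Users with an \code{anchor_change_day} switch to their post-change anchor
#' from that day on.
#'
#' @param config A [sim_config()].
#' @param users User table from [generate_users()].
#' @param pois POI table from [generate_city()].
#' @return A tibble of stays: \code{user_id}, \code{day}, \code{start_min},
#'   \code{duration_min}, \code{x}, \code{y}, \code{poi_id}, \code{kind}.
#' @export
simulate_mobility <- function(config, users, pois) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, 3L))
  n_u <- nrow(users)
  cutoff <- cfg$context_cutoff
  min_dur <- cfg$stay_min_duration_min

  home_poi <- nearest_poi(tibble(x = users$home_x, y = users$home_y), pois)

  # errand pools: POIs within 2 km of each distinct anchor POI (excluding
  # the anchor itself); fallback to the 5 nearest POIs. Pools are keyed by
  # anchor so changers draw errands near whichever anchor is active.
  anchor_ids <- unique(c(users$anchor_poi,
                         users$post_anchor_poi[!is.na(users$post_anchor_poi)]))
  pool <- vector("list", length(anchor_ids))
  names(pool) <- as.character(anchor_ids)
  for (a in seq_along(anchor_ids)) {
    arow <- match(anchor_ids[a], pois$poi_id)
    d2 <- (pois$x - pois$x[arow])^2 + (pois$y - pois$y[arow])^2
    near <- which(d2 <= 3000^2 & pois$poi_id != anchor_ids[a])
    if (length(near) < 2) near <- order(d2)[2:6]
    pool[[a]] <- near
  }

  ud <- tidyr::expand_grid(u = seq_len(n_u), day = seq_len(cfg$n_days))
  n <- nrow(ud)
  changed <- !is.na(users$anchor_change_day[ud$u]) &
    ud$day >= users$anchor_change_day[ud$u]
  ax <- ifelse(changed, users$post_anchor_x[ud$u], users$anchor_x[ud$u])
  ay <- ifelse(changed, users$post_anchor_y[ud$u], users$anchor_y[ud$u])
  apoi <- ifelse(changed, users$post_anchor_poi[ud$u], users$anchor_poi[ud$u])

  has_errand <- runif(n) < cfg$errand_prob
  err_row <- rep(NA_integer_, n)
  err_row[has_errand] <- vapply(which(has_errand), function(i) {
    p <- pool[[as.character(apoi[i])]]
    p[sample.int(length(p), 1L)]
  }, integer(1))

  anchor_start <- clip(rnorm(n, 500, 20), 455, 620)
  errand_start <- clip(rnorm(n, cutoff - 45, 12), anchor_start + 10, cutoff - 5)
  anchor_end <- ifelse(has_errand, errand_start,
                       cutoff + 60 + abs(rnorm(n, 0, 20)))
  errand_end <- cutoff + 25 + abs(rnorm(n, 0, 15))

  home_dur <- clip(rnorm(n, 420, 20), 360, anchor_start - 10)
  pm_start <- clip(rnorm(n, 855, 15), 845, 900)
  pm_end <- pm_start + clip(rnorm(n, 170, 25), 60, 240)
  eve_start <- clip(rnorm(n, 1070, 30), 1010, 1200)

  mk <- function(start, dur, x, y, poi, kind, keep = rep(TRUE, n)) {
    tibble(user_id = ud$u[keep], day = ud$day[keep],
           start_min = start[keep], duration_min = dur[keep],
           x = x[keep], y = y[keep], poi_id = poi[keep], kind = kind)
  }
  hx <- users$home_x[ud$u]; hy <- users$home_y[ud$u]; hpoi <- home_poi[ud$u]
  ex <- pois$x[err_row]; ey <- pois$y[err_row]
  epoi <- pois$poi_id[err_row]

  stays <- bind_rows(
    mk(rep(0, n), home_dur, hx, hy, hpoi, "home"),
    mk(anchor_start, anchor_end - anchor_start, ax, ay, apoi, "anchor"),
    mk(errand_start, errand_end - errand_start, ex, ey, epoi, "errand",
       keep = has_errand),
    mk(pm_start, pm_end - pm_start, ax, ay, apoi, "afternoon"),
    mk(eve_start, 1440 - eve_start, hx, hy, hpoi, "evening")
  )
  stays$duration_min <- pmax(stays$duration_min, min_dur)
  stays %>% arrange(.data$user_id, .data$day, .data$start_min)
}

#' Simulate quasi-random DMV visits
#'
#' A random subset of users receives exactly one stay at a uniformly chosen
#' DMV office on a random study day. The office choice is independent of the
#' user's home, mimicking quasi-random assignment of users to unfamiliar
#' food environments.
#'
#' @inheritParams simulate_mobility
#' @return A tibble of DMV stays in the same schema as [simulate_mobility()].
#' @export
simulate_dmv_visits <- function(config, users, pois) {
  cfg <- validate_sim_config(config)
  dmv <- pois %>% filter(.data$category == "dmv")
  if (cfg$dmv_count < 1 || nrow(dmv) == 0)
    abort("DMV simulation requested but no DMV POIs exist (`dmv_count` = 0).")
  set.seed(stage_seed(cfg$seed, 4L))
  sel <- which(runif(nrow(users)) < cfg$dmv_user_fraction)
  n <- length(sel)
  if (n == 0) {
    return(tibble(user_id = integer(), day = integer(), start_min = numeric(),
                  duration_min = numeric(), x = numeric(), y = numeric(),
                  poi_id = integer(), kind = character()))
  }
  pick <- sample.int(nrow(dmv), n, replace = TRUE)
  tibble(
    user_id = users$user_id[sel],
    day = sample.int(cfg$n_days, n, replace = TRUE),
    start_min = clip(rnorm(n, 600, 50), 480, 750),
    duration_min = clip(rnorm(n, 60, 15), 30, 150),
    x = dmv$x[pick], y = dmv$y[pick], poi_id = dmv$poi_id[pick],
    kind = "dmv"
  )
}
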