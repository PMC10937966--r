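# Synthetic city: a regular grid of area units with census-like covariates,
# plus a clustered POI point process with planted non-food category profiles
# (mall-, office-, residential-, airport-like) and spatially autocorrelated
# fast-food flags so that food swamps exist.

food_categories <- function() {
  c("fast_food", "restaurant", "cafe", "grocery", "supermarket", "convenience")
}

area_profiles <- function() c("mall", "office", "residential", "airport")

# Non-food taxonomy: each category belongs to one planted area profile.
nonfood_taxonomy <- function(n_categories) {
  base <- tibble(
    category = c("shopping_mall", "clothing_store", "electronics_store",
                 "department_store",
                 "office", "bank", "coworking_space",
                 "school", "park", "hair_salon", "pharmacy",
                 "airport_terminal", "hotel", "car_rental"),
    profile = c(rep("mall", 4), rep("office", 3),
                rep("residential", 4), rep("airport", 3))
  )
  n_nonfood <- n_categories - length(food_categories())
  if (n_nonfood <= nrow(base)) {
    # keep at least one category per profile by interleaving profiles
    ord <- order(ave(seq_len(nrow(base)), base$profile, FUN = seq_along))
    base[sort(ord[seq_len(n_nonfood)]), ]
  } else {
    extra <- n_nonfood - nrow(base)
    bind_rows(base, tibble(
      category = sprintf("specialty_%02d", seq_len(extra)),
      profile = rep(area_profiles(), length.out = extra)
    ))
  }
}

# Smooth random field evaluated at (x, y): a few Gaussian bumps.
random_bump_field <- function(x, y, extent, n_bumps = 4, width = extent / 3) {
  cx <- runif(n_bumps, 0, extent); cy <- runif(n_bumps, 0, extent)
  amp <- rnorm(n_bumps)
  z <- rep(0, length(x))
  for (b in seq_len(n_bumps)) {
    z <- z + amp[b] * exp(-((x - cx[b])^2 + (y - cy[b])^2) / (2 * width^2))
  }
  z
}

#' Generate a synthetic city: area units and points of interest
#'
#' Tiles the square city extent with a regular grid of area units carrying
#' demographic covariates, health-prevalence estimates, and a low-food-access
#' flag (a synthetic analogue of low-income/low-supermarket-access
#' classification). POIs are placed by a clustered point process (dense
#' commercial hotspots over a uniform background); food outlets receive
#' fast-food flags with spatial autocorrelation so that area-level
#' \eqn{\phi} varies and food swamps exist; non-food categories follow
#' planted per-area profiles (mall-, office-, residential-, airport-like)
#' so that topic recovery is testable. \code{dmv_count} DMV offices are
#' appended as additional non-food POIs.
#'
#' @param config A [sim_config()].
#' @return A list with tibbles \code{areas} and \code{pois}.
#' @examples
#' city <- generate_city(sim_config(n_areas = 4, city_extent_m = 2000,
#'                                  n_pois = 80, n_users = 5, n_days = 5))
#' nrow(city$areas)
#' @export
generate_city <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg$seed, 1L))
  extent <- cfg$city_extent_m
  g <- as.integer(round(sqrt(cfg$n_areas)))
  w <- extent / g

  ix <- rep(seq_len(g) - 1L, times = g)
  iy <- rep(seq_len(g) - 1L, each = g)
  areas <- tibble(
    area_id = seq_len(cfg$n_areas),
    xmin = ix * w, xmax = (ix + 1L) * w,
    ymin = iy * w, ymax = (iy + 1L) * w
  )
  areas$cx <- (areas$xmin + areas$xmax) / 2
  areas$cy <- (areas$ymin + areas$ymax) / 2

  # demographics: a smooth income field plus noise; other covariates are
  # correlated with income but carry independent noise so no pair is collinear
  z_inc <- random_bump_field(areas$cx, areas$cy, extent)
  z_inc <- as.numeric(scale(z_inc + rnorm(nrow(areas), 0, 0.4)))
  nse <- function(s = 0.5) rnorm(nrow(areas), 0, s)
  areas$median_income <- round(exp(log(60000) + 0.35 * z_inc + nse(0.15)))
  areas$pct_black <- plogis(-1.2 - 0.8 * z_inc + nse())
  areas$pct_long_commute <- plogis(-0.8 - 0.3 * z_inc + nse())
  areas$pct_public_transit <- plogis(-1.6 - 0.5 * z_inc + nse())
  areas$pct_employed <- plogis(1.4 + 0.4 * z_inc + nse())
  areas$pct_higher_ed <- plogis(-0.4 + 0.9 * z_inc + nse())
  areas$pct_low_skill <- plogis(-1.0 - 0.9 * z_inc + nse())
  areas$obesity_prev <- pmin(pmax(0.30 - 0.05 * z_inc + rnorm(nrow(areas), 0, 0.03), 0.05), 0.6)
  areas$diabetes_prev <- pmin(pmax(0.10 - 0.02 * z_inc + rnorm(nrow(areas), 0, 0.015), 0.02), 0.3)

  # hotspot centers and area profiles: areas containing a hotspot get a
  # commercial profile, the rest are residential-like
  hs_x <- runif(cfg$n_hotspots, 0.1 * extent, 0.9 * extent)
  hs_y <- runif(cfg$n_hotspots, 0.1 * extent, 0.9 * extent)
  hs_area <- assign_area(tibble(x = hs_x, y = hs_y), areas)
  profiles <- rep("residential", nrow(areas))
  commercial <- rep(c("office", "mall", "airport"), length.out = cfg$n_hotspots)
  profiles[hs_area] <- commercial
  areas$profile <- profiles

  # POI placement: 60% clustered around hotspots, 40% uniform background
  n <- cfg$n_pois
  clustered <- runif(n) < 0.6
  hs_pick <- sample.int(cfg$n_hotspots, n, replace = TRUE)
  px <- ifelse(clustered, hs_x[hs_pick] + rnorm(n, 0, 0.04 * extent), runif(n, 0, extent))
  py <- ifelse(clustered, hs_y[hs_pick] + rnorm(n, 0, 0.04 * extent), runif(n, 0, extent))
  px <- pmin(pmax(px, 0), extent - 1e-9)
  py <- pmin(pmax(py, 0), extent - 1e-9)
  pois <- tibble(poi_id = seq_len(n), x = px, y = py)
  pois$area_id <- assign_area(pois, areas)

  # food outlets and spatially autocorrelated fast-food propensity; the
  # propensity field is rougher than the demographic field so that phi
  # varies at the km scale (food swamps a short errand away)
  pois$is_food_outlet <- runif(n) < cfg$fo_fraction
  zf <- random_bump_field(pois$x, pois$y, extent, n_bumps = 12,
                          width = extent / 8)
  wgt <- exp(0.6 * as.numeric(scale(zf)))
  idx_fo <- which(pois$is_food_outlet)
  p_ffo <- if (length(idx_fo) > 0 && cfg$ffo_fraction > 0) {
    pmin(cfg$ffo_fraction * wgt[idx_fo] / mean(wgt[idx_fo]), 0.95)
  } else rep(0, length(idx_fo))
  pois$is_ffo <- FALSE
  pois$is_ffo[idx_fo] <- runif(length(idx_fo)) < p_ffo

  # categories: fast food by flag; other food categories uniform; non-food
  # categories drawn from the home area's planted profile mixture
  taxonomy <- nonfood_taxonomy(cfg$poi_category_count)
  pois$category <- NA_character_
  pois$category[pois$is_ffo] <- "fast_food"
  other_food <- setdiff(food_categories(), "fast_food")
  n_of <- sum(pois$is_food_outlet & !pois$is_ffo)
  pois$category[pois$is_food_outlet & !pois$is_ffo] <-
    sample(other_food, n_of, replace = TRUE)
  nf_idx <- which(!pois$is_food_outlet)
  area_profile <- areas$profile[pois$area_id[nf_idx]]
  own_share <- 0.75
  pois$category[nf_idx] <- vapply(area_profile, function(pr) {
    own <- taxonomy$category[taxonomy$profile == pr]
    if (length(own) == 0 || runif(1) > own_share) {
      sample(taxonomy$category, 1L)
    } else sample(own, 1L)
  }, character(1))

  # DMV offices appended as extra POIs
  if (cfg$dmv_count > 0) {
    dmv <- tibble(
      poi_id = n + seq_len(cfg$dmv_count),
      x = runif(cfg$dmv_count, 0.1 * extent, 0.9 * extent),
      y = runif(cfg$dmv_count, 0.1 * extent, 0.9 * extent)
    )
    dmv$area_id <- assign_area(dmv, areas)
    dmv$is_food_outlet <- FALSE
    dmv$is_ffo <- FALSE
    dmv$category <- "dmv"
    pois <- bind_rows(pois, dmv)
  }

  # low food access: bottom income tertile with few supermarkets/groceries
  grocery_n <- pois %>%
    filter(.data$category %in% c("grocery", "supermarket")) %>%
    count(.data$area_id)
  areas <- areas %>%
    left_join(grocery_n, by = "area_id") %>%
    mutate(n_grocery = dplyr::coalesce(.data$n, 0L)) %>%
    select(-"n")
  inc_cut <- quantile(areas$median_income, 1 / 3)
  gro_cut <- median(areas$n_grocery)
  areas$low_food_access_flag <-
    areas$median_income <= inc_cut & areas$n_grocery <= gro_cut

  pois <- pois %>%
    select("poi_id", "x", "y", "category", "is_food_outlet", "is_ffo", "area_id")
  list(areas = areas, pois = pois)
}

#' Assign planar locations to grid area units
#'
#' Maps each point to the area unit whose cell contains it. Points exactly on
#' a shared edge resolve to the adjacent cell with the lowest \code{area_id};
#' points outside the extent are clamped to the nearest cell.
#'
#' @param locations Data frame with \code{x}, \code{y} columns, meters.
#' @param areas Area table from [generate_city()].
#' @return Integer vector of \code{area_id}s.
#' @export
assign_area <- function(locations, areas) {
  loc <- as.data.frame(locations)
  g <- as.integer(round(sqrt(nrow(areas))))
  w <- max(areas$xmax) / g
  cell <- function(v) pmin(pmax(ceiling(v / w) - 1L, 0L), g - 1L)
  idx <- cell(loc$y) * g + cell(loc$x) + 1L
  areas$area_id[idx]
}

# Nearest POI id for each location (brute force, chunked).
nearest_poi <- function(locations, pois, chunk = 1024L) {
  loc <- as.data.frame(locations)[, c("x", "y")]
  n <- nrow(loc)
  out <- integer(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- outer(loc$x[i0:i1], pois$x, function(a, b) (a - b)^2) +
      outer(loc$y[i0:i1], pois$y, function(a, b) (a - b)^2)
    out[i0:i1] <- pois$poi_id[max.col(-d2, ties.method = "first")]
  }
  out
}
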