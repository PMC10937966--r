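#' Simulation configuration for a synthetic city study
#'
#' Bundles every tunable constant behind the synthetic-city generator and the
#' downstream exposure/decision machinery. The generative visit model is the
#' fixed-effects logistic
#' \deqn{\Pr(y_{it}=1) = \mathrm{logit}^{-1}\left[\beta_0 + \alpha_i +
#'   \delta_t + \beta\,\phi(c_{it})\right],}
#' where \eqn{\phi(c_{it})} is the fast-food ratio of the environment around
#' the pre-lunch context. Defaults encode the study conditions the package is
#' calibrated for: a 20 km planar city, 60 observation days, a generative
#' slope of 1.87, a 5-minute minimum stay, and a 0.46\% habitual-context
#' change rate.
#'
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @param n_areas Number of area units (must be a perfect square; the city is
#'   tiled by a regular \eqn{\sqrt{n} \times \sqrt{n}} grid).
#' @param city_extent_m Side of the square city, meters.
#' @param n_pois Number of points of interest.
#' @param fo_fraction Fraction of POIs that are food outlets (FO).
#' @param ffo_fraction Expected share of fast-food outlets (FFO) among FO.
#' @param poi_category_count Number of distinct POI category labels
#'   (minimum 10: 6 food categories plus at least one non-food category per
#'   planted area profile).
#' @param n_users Number of simulated users.
#' @param n_days Number of observation days (at least 2).
#' @param beta0 Generative intercept \eqn{\beta_0}.
#' @param beta Generative environment coefficient \eqn{\beta}.
#' @param alpha_sd Standard deviation of latent user preferences
#'   \eqn{\alpha_i \sim N(0, \mathrm{alpha\_sd}^2)}.
#' @param delta_sd Standard deviation of day effects \eqn{\delta_t}.
#' @param outing_prob Probability that a user-day with a defined context
#'   produces a lunch food outing.
#' @param errand_prob Probability that the last pre-lunch stay of a user-day
#'   is a morning errand at a nearby POI rather than the habitual anchor.
#'   Must be positive: day-to-day context variation within user is what
#'   identifies \eqn{\beta} once user fixed effects absorb everything
#'   user-constant.
#' @param stay_min_duration_min Minimum stay duration in minutes (stops
#'   shorter than this are never emitted).
#' @param context_change_fraction Fraction of users whose habitual morning
#'   anchor relocates mid-study.
#' @param dmv_count Number of DMV offices placed in the city.
#' @param dmv_user_fraction Fraction of users who make one DMV visit.
#' @param lunch_window Half-open pair of clock minutes \code{[start, end)}
#'   during which lunch food visits occur; default \code{c(690, 840)},
#'   i.e. 11:30-14:00.
#' @param context_cutoff Clock minute before which the context stay must
#'   start (default 690 = 11:30).
#' @param env_radius_m Radius, meters, of the circular food environment.
#' @param env_knn Number of nearest food outlets for the k-NN environment.
#' @param env_method Which environment definition drives the generator and
#'   context extraction: \code{"radius"} (default) or \code{"knn"}.
#' @param n_hotspots Number of commercial hotspot centers used by the
#'   clustered POI point process.
#'
#' @return A list of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config(seed = 1, n_areas = 4, city_extent_m = 2000,
#'                   n_pois = 60, n_users = 10, n_days = 10)
#' cfg$beta
#' @export
sim_config <- function(seed = 1L,
                       n_areas = 100L,
                       city_extent_m = 20000,
                       n_pois = 2000L,
                       fo_fraction = 0.4,
                       ffo_fraction = 0.15,
                       poi_category_count = 20L,
                       n_users = 500L,
                       n_days = 60L,
                       beta0 = -2.2,
                       beta = 1.87,
                       alpha_sd = 1.0,
                       delta_sd = 0.2,
                       outing_prob = 0.6,
                       errand_prob = 0.5,
                       stay_min_duration_min = 5,
                       context_change_fraction = 0.0046,
                       dmv_count = 3L,
                       dmv_user_fraction = 0.05,
                       lunch_window = c(690, 840),
                       context_cutoff = 690,
                       env_radius_m = 1000,
                       env_knn = 25L,
                       env_method = c("radius", "knn"),
                       n_hotspots = 5L) {
  env_method <- match.arg(env_method)
  cfg <- list(
    seed = as.integer(seed), n_areas = as.integer(n_areas),
    city_extent_m = city_extent_m, n_pois = as.integer(n_pois),
    fo_fraction = fo_fraction, ffo_fraction = ffo_fraction,
    poi_category_count = as.integer(poi_category_count),
    n_users = as.integer(n_users), n_days = as.integer(n_days),
    beta0 = beta0, beta = beta, alpha_sd = alpha_sd, delta_sd = delta_sd,
    outing_prob = outing_prob, errand_prob = errand_prob,
    stay_min_duration_min = stay_min_duration_min,
    context_change_fraction = context_change_fraction,
    dmv_count = as.integer(dmv_count),
    dmv_user_fraction = dmv_user_fraction,
    lunch_window = lunch_window, context_cutoff = context_cutoff,
    env_radius_m = env_radius_m, env_knn = as.integer(env_knn),
    env_method = env_method, n_hotspots = as.integer(n_hotspots)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk_prop <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      abort(sprintf("`%s` must be a proportion in [0, 1].", nm))
  }
  chk_prop(cfg$fo_fraction, "fo_fraction")
  chk_prop(cfg$ffo_fraction, "ffo_fraction")
  chk_prop(cfg$outing_prob, "outing_prob")
  chk_prop(cfg$errand_prob, "errand_prob")
  chk_prop(cfg$context_change_fraction, "context_change_fraction")
  chk_prop(cfg$dmv_user_fraction, "dmv_user_fraction")
  if (cfg$n_days < 2) abort("`n_days` must be at least 2.")
  if (cfg$env_radius_m <= 0) abort("`env_radius_m` must be positive.")
  if (cfg$alpha_sd < 0 || cfg$delta_sd < 0)
    abort("`alpha_sd` and `delta_sd` must be non-negative.")
  if (length(cfg$lunch_window) != 2 ||
      cfg$lunch_window[1] >= cfg$lunch_window[2])
    abort("`lunch_window` must be an increasing pair of clock minutes.")
  g <- round(sqrt(cfg$n_areas))
  if (g * g != cfg$n_areas)
    abort("`n_areas` must be a perfect square (regular grid tiling).")
  if (cfg$n_pois < cfg$env_knn)
    abort(sprintf(
      "`n_pois` (%d) is smaller than `env_knn` (%d): k-NN environment undefined.",
      cfg$n_pois, cfg$env_knn))
  if (cfg$poi_category_count < 10)
    abort("`poi_category_count` must be at least 10.")
  if (cfg$stay_min_duration_min <= 0)
    abort("`stay_min_duration_min` must be positive.")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  city: %d areas, %.0f m extent, %d POIs (FO %.0f%%, FFO|FO %.0f%%)\n",
              x$n_areas, x$city_extent_m, x$n_pois,
              100 * x$fo_fraction, 100 * x$ffo_fraction))
  cat(sprintf("  panel: %d users x %d days, seed %d\n",
              x$n_users, x$n_days, x$seed))
  cat(sprintf("  model: beta0 %.2f, beta %.2f, alpha_sd %.2f, delta_sd %.2f\n",
              x$beta0, x$beta, x$alpha_sd, x$delta_sd))
  cat(sprintf("  environment: %s (radius %.0f m / k = %d)\n",
              x$env_method, x$env_radius_m, x$env_knn))
  invisible(x)
}

# Deterministic per-stage child seeds: Knuth multiplicative hash of the
# global seed and a stage counter, folded into the positive 32-bit range.
stage_seed <- function(seed, stage) {
  x <- (as.double(seed) * 2654435761 + 97 * stage) %% 2147483647
  as.integer(x) + 1L
}
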