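# Orchestration: one config and one seed drive simulate -> expose -> fit ->
# natural experiment -> interventions, with a manifest of stage seeds,
# filter logs, and content hashes for reproducibility.

#' Run all generator stages of a configuration
#'
#' Convenience wrapper producing the full synthetic dataset: city, users,
#' stays (including DMV stays), and food visits.
#'
#' @param config A [sim_config()].
#' @param dmv Include the DMV natural experiment (default TRUE when
#'   \code{dmv_count > 0}).
#' @return A list: \code{config}, \code{areas}, \code{pois}, \code{users},
#'   \code{stays}, \code{dmv_stays}, \code{visits}.
#' @export
simulate_scenario <- function(config, dmv = config$dmv_count > 0) {
  cfg <- validate_sim_config(config)
  city <- generate_city(cfg)
  users <- generate_users(cfg, city$areas, city$pois)
  stays <- simulate_mobility(cfg, users, city$pois)
  dmv_stays <- if (dmv) simulate_dmv_visits(cfg, users, city$pois) else
    stays[0, ]
  visits <- simulate_food_decisions(cfg, users, stays, city$pois,
                                    dmv_stays = if (dmv) dmv_stays else NULL)
  list(config = cfg, areas = city$areas, pois = city$pois, users = users,
       stays = bind_rows(stays, dmv_stays) %>%
         arrange(.data$user_id, .data$day, .data$start_min),
       dmv_stays = dmv_stays, visits = visits)
}

#' Bundled fixture scenarios
#'
#' Small, fully reproducible datasets for examples and tests:
#' \describe{
#'   \item{tiny}{4 areas, 80 POIs, 20 users, 20 days -- sub-second;}
#'   \item{recovery}{300 users x 40 days, moderate city -- parameter
#'     recovery at reduced scale;}
#'   \item{changers}{a cohort with a high context-change fraction so all
#'     four Low/High transition cells are populated;}
#'   \item{dmv}{half the users visit a DMV office.}
#' }
#'
#' @param profile One of \code{"tiny"}, \code{"recovery"},
#'   \code{"changers"}, \code{"dmv"}.
#' @param seed Seed override (default 101).
#' @return The [simulate_scenario()] list for the profile's config.
#' @export
make_fixture <- function(profile = c("tiny", "recovery", "changers", "dmv"),
                         seed = 101L) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    tiny = sim_config(seed = seed, n_areas = 4L, city_extent_m = 2000,
                      n_pois = 80L, n_users = 20L, n_days = 20L,
                      n_hotspots = 2L, env_radius_m = 600,
                      dmv_count = 1L, dmv_user_fraction = 0.2,
                      outing_prob = 0.8),
    recovery = sim_config(seed = seed, n_areas = 36L, city_extent_m = 12000,
                          n_pois = 900L, n_users = 300L, n_days = 40L,
                          n_hotspots = 4L),
    changers = sim_config(seed = seed, n_areas = 36L, city_extent_m = 12000,
                          n_pois = 900L, n_users = 160L, n_days = 90L,
                          n_hotspots = 4L, context_change_fraction = 0.5,
                          outing_prob = 0.8),
    dmv = sim_config(seed = seed, n_areas = 36L, city_extent_m = 12000,
                     n_pois = 900L, n_users = 400L, n_days = 30L,
                     n_hotspots = 4L, dmv_count = 3L,
                     dmv_user_fraction = 0.5)
  )
  simulate_scenario(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate, exposure, context extraction, model fitting, the
#' natural experiment (when enough transition users exist), intervention
#' comparison, and topic profiling, from a single config and seed. When
#' \code{out_dir} is given, all tables, the fit, the strategy results, and
#' a manifest with content hashes are written there (see
#' [write_run()]).
#'
#' @param config A [sim_config()].
#' @param out_dir Optional output directory.
#' @param budget Intervention budget (number of areas; default one tenth
#'   of the areas).
#' @param n_topics Topics for area profiling (default 20, reduced to the
#'   category count if needed).
#' @return A list of class \code{"foodscape_run"} with every intermediate
#'   product, a \code{report} list of headline numbers, and a
#'   \code{manifest}.
#' @export
run_end_to_end <- function(config, out_dir = NULL, budget = NULL,
                           n_topics = 20L) {
  cfg <- validate_sim_config(config)
  scen <- run_stage("simulate", simulate_scenario(cfg))
  exposure <- run_stage("expose", suppressWarnings(
    compute_exposure_profiles(scen$users, scen$stays, scen$visits,
                              scen$pois, cfg)))
  lunch_ctx <- run_stage("contexts",
    extract_lunch_contexts(scen$stays, scen$visits, scen$pois, cfg))
  fullday_ctx <- run_stage("contexts",
    extract_fullday_contexts(scen$stays, scen$visits, scen$pois, cfg))
  fit <- run_stage("fit", fit_fe_logit(lunch_ctx))

  dmv_fit <- NULL
  if (nrow(scen$dmv_stays) > 0) {
    dmv_ctx <- run_stage("contexts",
      extract_dmv_contexts(scen$dmv_stays, scen$visits, scen$pois, cfg))
    if (nrow(dmv_ctx) >= 10 && length(unique(dmv_ctx$outcome)) == 2) {
      dmv_fit <- tryCatch(fit_dmv_logit(dmv_ctx, exposure),
                          error = function(e) NULL)
    }
  }

  # natural experiment: only when the generative design provides changers
  natexp <- NULL
  truth_changers <- scen$users %>% filter(!is.na(.data$anchor_change_day))
  if (nrow(truth_changers) >= 8) {
    transitions <- run_stage("natexp", detect_transitions(lunch_ctx))
    series <- NULL; cf <- NULL
    if (nrow(transitions) > 0 &&
        all(c("LH", "LL") %in% transitions$group)) {
      series <- build_group_series(transitions, lunch_ctx)
      wide <- series %>%
        filter(.data$group %in% c("LH", "LL")) %>%
        select("group", "aligned_day", "frac") %>%
        tidyr::pivot_wider(names_from = "group", values_from = "frac") %>%
        filter(!is.na(.data$LH), !is.na(.data$LL))
      if (sum(wide$aligned_day < 0) >= 20) {
        cf <- estimate_counterfactual(wide$LH, wide$LL, wide$aligned_day,
                                      seed = stage_seed(cfg$seed, 7L))
      }
    }
    natexp <- list(transitions = transitions, series = series,
                   counterfactual = cf)
  }

  if (is.null(budget)) budget <- max(1L, cfg$n_areas %/% 10L)
  scores <- run_stage("intervene",
    score_areas(scen$areas, fullday_ctx, fit, scen$pois))
  strat <- run_stage("intervene",
    evaluate_strategies(scores, fullday_ctx, fit, scen$users, scen$areas,
                        budget = budget))
  nt <- min(n_topics, length(unique(scen$pois$category)))
  lda <- run_stage("topics",
    fit_poi_topics(scen$pois, n_topics = nt,
                   seed = stage_seed(cfg$seed, 8L)))
  enrich <- topic_enrichment(
    lda, attr(strat, "selections")$behavior_environment)

  report <- list(
    n_users = cfg$n_users,
    n_stays = nrow(scen$stays),
    n_food_visits = nrow(scen$visits),
    median_phi_mobile = median(exposure$phi_mobile, na.rm = TRUE),
    iqr_phi_mobile = unname(quantile(exposure$phi_mobile, c(0.25, 0.75),
                                     na.rm = TRUE)),
    median_phi_home = median(exposure$phi_home, na.rm = TRUE),
    median_mu = median(exposure$mu, na.rm = TRUE),
    cor_mobile_home = cor(exposure$phi_mobile, exposure$phi_home,
                          use = "complete.obs"),
    cor_mobile_mu = cor(exposure$phi_mobile, exposure$mu,
                        use = "complete.obs"),
    cor_home_mu = cor(exposure$phi_home, exposure$mu,
                      use = "complete.obs"),
    beta_hat = fit$beta,
    se_beta_clustered = fit$se_beta_clustered,
    odds_change_10pct = odds_change(fit$beta, 0.1),
    dmv_beta_hat = if (!is.null(dmv_fit)) dmv_fit$beta else NA_real_,
    strategy_totals = setNames(strat$total_delta_ffo, strat$strategy)
  )

  manifest <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    stage_seeds = setNames(
      vapply(1:8, function(k) stage_seed(cfg$seed, k), integer(1)),
      c("city", "users", "mobility", "dmv", "decisions", "exposure",
        "counterfactual", "topics")),
    filter_logs = list(lunch = attr(lunch_ctx, "filter_log"),
                       fullday = attr(fullday_ctx, "filter_log")),
    digests = c(
      pois = rlang::hash(scen$pois), users = rlang::hash(scen$users),
      stays = rlang::hash(scen$stays), visits = rlang::hash(scen$visits),
      strategy = rlang::hash(strat$total_delta_ffo))
  )

  run <- list(config = cfg, scenario = scen, exposure = exposure,
              lunch_contexts = lunch_ctx, fullday_contexts = fullday_ctx,
              fit = fit, dmv_fit = dmv_fit, natexp = natexp,
              area_scores = scores, strategies = strat, lda = lda,
              topic_enrichment = enrich, report = report,
              manifest = manifest)
  class(run) <- "foodscape_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.foodscape_run <- function(x, ...) {
  r <- x$report
  cat("<foodscape_run>\n")
  cat(sprintf("  %d users, %d stays, %d food visits\n",
              r$n_users, r$n_stays, r$n_food_visits))
  cat(sprintf("  median phi_mobile %.3f, median phi_home %.3f, median mu %.3f\n",
              r$median_phi_mobile, r$median_phi_home, r$median_mu))
  cat(sprintf("  rho(phi_m, mu) = %.3f vs rho(phi_h, mu) = %.3f\n",
              r$cor_mobile_mu, r$cor_home_mu))
  cat(sprintf("  beta_hat = %.3f (SE %.3f): +10pp fast food in context -> %+.1f%% odds\n",
              r$beta_hat, r$se_beta_clustered, r$odds_change_10pct))
  if (!is.na(r$dmv_beta_hat))
    cat(sprintf("  DMV beta_hat = %.3f\n", r$dmv_beta_hat))
  cat("  strategy totals (delta FFO visits):\n")
  for (s in names(r$strategy_totals))
    cat(sprintf("    %-22s %.4f\n", s, r$strategy_totals[[s]]))
  invisible(x)
}
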