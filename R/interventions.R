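# Intervention scoring and ranking. A unit intervention in area Omega
# shifts the local environment ratio by dphi/dI (default -1/n_Omega, one
# fewer fast-food outlet among the area's n_Omega food outlets); under the
# fitted decision model, the predicted change in fast-food visits is
#   dFFO(Omega) = sum_{c_it in Omega} beta * p_it (1 - p_it) * dphi/dI,
# summed over full-day decision contexts whose location falls in the area
# (e^X/(1+e^X)^2 = p(1-p)). Four selection strategies are compared.

intervention_strategies <- function() {
  c("food_swamp", "low_food_access", "food_hotspots", "behavior_environment")
}

#' Predicted change in fast-food visits for one area
#'
#' Sums the model's marginal effect \eqn{\beta\,p(1-p)\,\delta\phi/\delta I}
#' over the decision contexts located in the area. Fitted users only;
#' days unseen by the fit use the constrained mean \eqn{\delta = 0}.
#'
#' @param area_id The area to score.
#' @param contexts Full-day decision contexts with an \code{area_id}
#'   column (see [score_areas()] for the assignment) and observed
#'   outcomes.
#' @param fit A [fit_fe_logit()] object.
#' @param dphi Environment shift per unit intervention for this area.
#' @return The predicted change in fast-food visits (same sign as
#'   \code{dphi} for positive \code{beta}); 0 when the area has no
#'   decision contexts.
#' @export
area_delta_ffo <- function(area_id, contexts, fit, dphi) {
  ctx <- contexts %>%
    filter(.data$area_id == !!area_id, !is.na(.data$outcome)) %>%
    semi_join(fit$user_effects, by = "user_id")
  if (nrow(ctx) == 0) return(0)
  p <- predict_visit_probability(fit, ctx, new_day = "zero")
  sum(fit$beta * p * (1 - p) * dphi)
}

#' Score all areas for intervention
#'
#' Computes, per area: the area-level environment ratio \code{mean_phi}
#' (fast-food share of the area's food outlets), the number of food
#' outlets \eqn{n_\Omega}, the number of decisions made in the area, and
#' the predicted change in fast-food visits \code{delta_ffo} under the
#' default derivative \eqn{\delta\phi/\delta I = -1/n_\Omega}. Areas with
#' no food outlet have an undefined derivative, get \code{NA}, and are
#' skipped by ranking (their ids are recorded in attribute
#' \code{"skipped_areas"}). Contexts of users absent from the fit are
#' excluded and logged in attribute \code{"context_coverage"}.
#'
#' @param areas Area table from [generate_city()].
#' @param contexts Full-day decision contexts from
#'   [extract_fullday_contexts()].
#' @param fit A [fit_fe_logit()] object.
#' @param pois POI table.
#' @param dphi Optional fixed environment shift; default \code{NULL} uses
#'   \eqn{-1/n_\Omega} per area.
#' @return A tibble of area scores.
#' @export
score_areas <- function(areas, contexts, fit, pois, dphi = NULL) {
  ctx <- contexts %>% filter(!is.na(.data$outcome))
  n_all <- nrow(ctx)
  ctx <- ctx %>% semi_join(fit$user_effects, by = "user_id")
  coverage <- if (n_all > 0) nrow(ctx) / n_all else NA_real_
  ctx$area_id <- assign_area(ctx, areas)
  ctx$p <- predict_visit_probability(fit, ctx, new_day = "zero")
  ctx$susc <- fit$beta * ctx$p * (1 - ctx$p)

  poi_cnt <- pois %>%
    group_by(.data$area_id) %>%
    summarise(n_fo = sum(.data$is_food_outlet),
              n_ffo_outlets = sum(.data$is_ffo), .groups = "drop")
  dec <- ctx %>%
    group_by(.data$area_id) %>%
    summarise(n_decisions = n(), susc_sum = sum(.data$susc),
              .groups = "drop")
  scores <- areas %>%
    select("area_id", "low_food_access_flag") %>%
    left_join(poi_cnt, by = "area_id") %>%
    left_join(dec, by = "area_id") %>%
    mutate(
      n_fo = dplyr::coalesce(.data$n_fo, 0L),
      n_ffo_outlets = dplyr::coalesce(.data$n_ffo_outlets, 0L),
      n_decisions = dplyr::coalesce(.data$n_decisions, 0L),
      susc_sum = dplyr::coalesce(.data$susc_sum, 0),
      mean_phi = ifelse(.data$n_fo > 0,
                        .data$n_ffo_outlets / .data$n_fo, NA_real_),
      dphi = if (is.null(dphi)) ifelse(.data$n_fo > 0, -1 / .data$n_fo,
                                       NA_real_) else dphi,
      delta_ffo = ifelse(is.na(.data$dphi), NA_real_,
                         .data$susc_sum * .data$dphi)
    ) %>%
    select("area_id", "mean_phi", "n_fo", "n_decisions", "delta_ffo",
           "dphi", "low_food_access_flag")
  attr(scores, "skipped_areas") <- scores$area_id[is.na(scores$delta_ffo)]
  attr(scores, "context_coverage") <- coverage
  attr(scores, "baseline_pred_ffo") <- sum(ctx$p)
  scores
}

#' Select areas under an intervention strategy
#'
#' \describe{
#'   \item{food_swamp}{largest area-level \code{mean_phi};}
#'   \item{low_food_access}{largest \code{mean_phi} among areas flagged as
#'     low food access;}
#'   \item{food_hotspots}{most decision contexts;}
#'   \item{behavior_environment}{largest predicted visit change
#'     \eqn{|\Delta^{FFO}|}.}
#' }
#' Ties break by ascending \code{area_id}; areas with an undefined
#' derivative are never selected.
#'
#' @param strategy One of the four strategy names.
#' @param scores Area scores from [score_areas()].
#' @param budget Number of areas to select (default 100); all eligible
#'   areas if fewer exist.
#' @return The selected rows of \code{scores}, in selection order.
#' @export
rank_areas <- function(strategy = intervention_strategies(), scores,
                       budget = 100L) {
  strategy <- match.arg(strategy)
  elig <- scores %>% filter(!is.na(.data$delta_ffo))
  if (strategy == "low_food_access") {
    elig <- elig %>% filter(.data$low_food_access_flag)
    if (nrow(elig) == 0)
      abort("no areas flagged as low food access: strategy undefined.")
  }
  key <- switch(strategy,
    food_swamp = elig$mean_phi,
    low_food_access = elig$mean_phi,
    food_hotspots = elig$n_decisions,
    behavior_environment = abs(elig$delta_ffo)
  )
  elig[order(-key, elig$area_id), ][seq_len(min(budget, nrow(elig))), ]
}

#' Evaluate and compare intervention strategies
#'
#' Runs every requested strategy at the same budget, totalling the
#' predicted change in fast-food visits and expressing it as the fraction
#' of baseline model-predicted fast-food decisions averted. Averted
#' decisions are decomposed by the deciding user's income quantile and by
#' the tertile of their home area's obesity prevalence.
#'
#' @param scores Area scores from [score_areas()] (default derivative).
#' @param contexts Full-day decision contexts.
#' @param fit A [fit_fe_logit()] object.
#' @param users User table (income quantile, home area).
#' @param areas Area table (health prevalences).
#' @param budget Areas per strategy (default 100).
#' @param strategies Character vector of strategies (default all four).
#' @return A tibble of class \code{"strategy_comparison"}: one row per
#'   strategy with totals, averted fraction, and breakdown list-columns;
#'   selections are kept in attribute \code{"selections"}.
#' @export
evaluate_strategies <- function(scores, contexts, fit, users, areas,
                                budget = 100L,
                                strategies = intervention_strategies()) {
  ctx <- contexts %>%
    filter(!is.na(.data$outcome)) %>%
    semi_join(fit$user_effects, by = "user_id")
  ctx$area_id <- assign_area(ctx, areas)
  ctx$p <- predict_visit_probability(fit, ctx, new_day = "zero")
  dphi_tab <- scores %>% select("area_id", "dphi")
  ctx <- ctx %>%
    left_join(dphi_tab, by = "area_id") %>%
    mutate(averted = -fit$beta * .data$p * (1 - .data$p) * .data$dphi) %>%
    left_join(users %>% select("user_id", "income_quantile",
                               "home_area_id"), by = "user_id")
  ob_tert <- ntile(areas$obesity_prev, 3)
  ctx$health_stratum <- ob_tert[match(ctx$home_area_id, areas$area_id)]
  baseline <- sum(ctx$p)

  selections <- list()
  rows <- purrr::map(strategies, function(st) {
    sel <- rank_areas(st, scores, budget = budget)
    selections[[st]] <<- sel$area_id
    in_sel <- ctx %>% filter(.data$area_id %in% sel$area_id)
    total <- sum(sel$delta_ffo)
    tibble(
      strategy = st,
      n_selected = nrow(sel),
      total_delta_ffo = total,
      averted_fraction = abs(total) / baseline,
      by_income = list(in_sel %>%
                         group_by(income_quantile = .data$income_quantile) %>%
                         summarise(averted = sum(abs(.data$averted)),
                                   .groups = "drop")),
      by_health = list(in_sel %>%
                         group_by(health_stratum = .data$health_stratum) %>%
                         summarise(averted = sum(abs(.data$averted)),
                                   .groups = "drop"))
    )
  }) %>% bind_rows()
  attr(rows, "selections") <- selections
  attr(rows, "baseline_pred_ffo") <- baseline
  class(rows) <- c("strategy_comparison", class(rows))
  rows
}

#' Bar chart of total strategy effects with income decomposition
#'
#' @param object A [evaluate_strategies()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.strategy_comparison <- function(object, ...) {
  dat <- object %>%
    select("strategy", "by_income") %>%
    tidyr::unnest("by_income") %>%
    mutate(income_quantile = factor(.data$income_quantile))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$strategy, y = .data$averted,
                                    fill = .data$income_quantile)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Blues",
                               name = "income quantile") +
    ggplot2::labs(x = NULL, y = "predicted fast-food visits averted") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20,
                                                       hjust = 1))
}
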