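# Readers and writers for the pipeline's on-disk layout. Everything is
# plain text: GeoJSON for area polygons, CSV for tables, JSON for the fit,
# strategy results, and the manifest.

#' Write area polygons as GeoJSON
#'
#' Each area becomes a Polygon feature (closed ring, counter-clockwise)
#' with its demographic columns as properties.
#'
#' @param areas Area table from [generate_city()].
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_areas_geojson <- function(areas, path) {
  features <- purrr::pmap(areas, function(xmin, xmax, ymin, ymax, ...) {
    props <- list(...)
    props$cx <- NULL; props$cy <- NULL
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(list(
          c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
          c(xmin, ymax), c(xmin, ymin)
        ))
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read area polygons from GeoJSON
#'
#' Inverse of [write_areas_geojson()] for the regular-grid layout this
#' package writes (rectangular rings).
#'
#' @param path GeoJSON file.
#' @return An area tibble.
#' @export
read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    c(list(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys),
           cx = mean(range(xs)), cy = mean(range(ys))),
      f$properties)
  }) %>%
    purrr::map(as_tibble) %>%
    bind_rows() %>%
    arrange(.data$area_id)
}

#' Write a pipeline run to disk
#'
#' Writes \code{areas.geojson}, CSV tables (\code{pois}, \code{users},
#' \code{stays}, \code{visits}, \code{exposure}, \code{contexts},
#' \code{area_scores}, and natural-experiment outputs when present),
#' \code{fit.json}, \code{strategy_results.json}, \code{topics.csv}, and
#' \code{manifest.json}.
#'
#' @param run A [run_end_to_end()] result.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_areas_geojson(run$scenario$areas, p("areas.geojson"))
  readr::write_csv(run$scenario$pois, p("pois.csv"))
  readr::write_csv(run$scenario$users, p("users.csv"))
  readr::write_csv(run$scenario$stays, p("stays.csv"))
  readr::write_csv(run$scenario$visits, p("visits.csv"))
  readr::write_csv(run$exposure, p("exposure.csv"))
  readr::write_csv(bind_rows(run$lunch_contexts, run$fullday_contexts),
                   p("contexts.csv"))
  readr::write_csv(run$area_scores, p("area_scores.csv"))
  if (!is.null(run$natexp)) {
    readr::write_csv(run$natexp$transitions, p("transitions.csv"))
    if (!is.null(run$natexp$series))
      readr::write_csv(run$natexp$series, p("group_series.csv"))
    if (!is.null(run$natexp$counterfactual))
      readr::write_csv(run$natexp$counterfactual$series,
                       p("counterfactual_LH_LL.csv"))
  }
  fit <- run$fit
  jsonlite::write_json(
    list(beta = fit$beta, beta0 = fit$beta0,
         se_beta_clustered = fit$se_beta_clustered,
         user_effects = fit$user_effects, day_effects = fit$day_effects,
         n_decisions = fit$n_decisions, n_dropped = fit$n_dropped,
         log_likelihood = fit$log_likelihood,
         identification = "sum-to-zero user and day effects"),
    p("fit.json"), auto_unbox = TRUE, digits = NA)
  strat <- run$strategies
  jsonlite::write_json(
    list(budget = strat$n_selected[1],
         strategies = purrr::map(seq_len(nrow(strat)), function(i) {
           list(strategy = strat$strategy[i],
                total_delta_ffo = strat$total_delta_ffo[i],
                averted_fraction = strat$averted_fraction[i],
                selected_areas =
                  attr(strat, "selections")[[strat$strategy[i]]])
         })),
    p("strategy_results.json"), auto_unbox = TRUE, digits = NA)
  readr::write_csv(tidy(run$lda, "theta"), p("topics.csv"))
  jsonlite::write_json(run$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read the generator tables of a written run
#'
#' @param dir Directory written by [write_run()].
#' @return A list with \code{areas}, \code{pois}, \code{users},
#'   \code{stays}, \code{visits}.
#' @export
read_city <- function(dir) {
  need <- c("areas.geojson", "pois.csv", "users.csv", "stays.csv",
            "visits.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0)
    abort(sprintf("stage 'load': missing input file(s): %s",
                  paste(missing, collapse = ", ")))
  list(
    areas = read_areas_geojson(file.path(dir, "areas.geojson")),
    pois = readr::read_csv(file.path(dir, "pois.csv"),
                           show_col_types = FALSE),
    users = readr::read_csv(file.path(dir, "users.csv"),
                            show_col_types = FALSE),
    stays = readr::read_csv(file.path(dir, "stays.csv"),
                            show_col_types = FALSE),
    visits = readr::read_csv(file.path(dir, "visits.csv"),
                             show_col_types = FALSE)
  )
}

#' Map of the synthetic city
#'
#' Tile map of area-level fast-food ratio with POIs overlaid.
#'
#' @param areas,pois City tables.
#' @return A ggplot object.
#' @export
plot_city <- function(areas, pois) {
  fo <- pois %>% filter(.data$is_food_outlet)
  phi_area <- fo %>%
    group_by(.data$area_id) %>%
    summarise(phi = mean(.data$is_ffo), .groups = "drop")
  dat <- areas %>% left_join(phi_area, by = "area_id")
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$phi), colour = "white") +
    ggplot2::geom_point(data = fo,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$is_ffo),
                        size = 0.6, alpha = 0.6) +
    ggplot2::scale_fill_viridis_c(name = "area phi", na.value = "grey90") +
    ggplot2::scale_shape_manual(values = c(1, 17), name = "fast food") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}
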