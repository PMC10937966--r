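# Intervention scoring, ranking, strategy comparison, and topic profiling.

fit_fullday_fixture <- function(profile = "recovery") {
  fx <- get_fixture(profile)
  ctx <- extract_lunch_contexts(fx$stays, fx$visits, fx$pois, fx$config)
  fit <- suppressWarnings(fit_fe_logit(ctx))
  fullday <- extract_fullday_contexts(fx$stays, fx$visits, fx$pois,
                                      fx$config)
  list(fx = fx, fit = fit, fullday = fullday)
}

test_that("area scores implement the marginal-effect sum", {
  z <- fit_fullday_fixture()
  scores <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois)
  expect_equal(nrow(scores), nrow(z$fx$areas))
  # no decisions -> zero effect
  expect_true(all(scores$delta_ffo[scores$n_decisions == 0] == 0,
                  na.rm = TRUE))
  # fast-food-reducing derivative makes every score non-positive
  expect_true(all(scores$delta_ffo <= 0, na.rm = TRUE))

  # finite-difference oracle: perturbing phi by +h changes the summed
  # predicted probabilities by delta_ffo / dphi * h (relative error < 1%)
  ctx <- z$fullday %>% dplyr::filter(!is.na(outcome)) %>%
    dplyr::semi_join(z$fit$user_effects, by = "user_id")
  ctx$area_id <- assign_area(ctx, z$fx$areas)
  h <- 1e-4
  for (a in head(scores$area_id[!is.na(scores$delta_ffo) &
                                  scores$n_decisions > 0], 10)) {
    sub <- ctx[ctx$area_id == a, ]
    p0 <- predict_visit_probability(z$fit, sub, new_day = "zero")
    sub2 <- sub; sub2$phi_context <- sub$phi_context + h
    p1 <- predict_visit_probability(z$fit, sub2, new_day = "zero")
    fd <- sum(p1 - p0) / h
    dphi <- scores$dphi[scores$area_id == a]
    got <- scores$delta_ffo[scores$area_id == a]
    expect_lt(abs(got - fd * dphi) / abs(fd * dphi), 0.01)
    # direct single-area recomputation agrees
    expect_equal(got, area_delta_ffo(a, ctx, z$fit, dphi))
  }
})

test_that("a zero slope nullifies every area effect", {
  z <- fit_fullday_fixture()
  fit0 <- z$fit
  fit0$beta <- 0
  scores <- score_areas(z$fx$areas, z$fullday, fit0, z$fx$pois)
  expect_true(all(scores$delta_ffo == 0, na.rm = TRUE))
})

test_that("the effect is additive over areas and linear in dphi", {
  z <- fit_fullday_fixture()
  scores <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois)
  ctx <- z$fullday %>% dplyr::filter(!is.na(outcome)) %>%
    dplyr::semi_join(z$fit$user_effects, by = "user_id")
  ctx$area_id <- assign_area(ctx, z$fx$areas)
  ids <- scores$area_id[!is.na(scores$delta_ffo)]
  # union of disjoint areas = sum of parts (fixed dphi so areas share units)
  u3 <- sum(vapply(ids[1:3], function(a)
    area_delta_ffo(a, ctx, z$fit, -0.01), numeric(1)))
  all3 <- area_delta_ffo_union <- sum(
    vapply(ids[1:3], function(a) area_delta_ffo(a, ctx, z$fit, -0.01),
           numeric(1)))
  merged <- ctx
  merged$area_id[merged$area_id %in% ids[1:3]] <- ids[1]
  expect_equal(area_delta_ffo(ids[1], merged, z$fit, -0.01), u3)
  # doubling dphi doubles the score exactly
  s1 <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois, dphi = -0.01)
  s2 <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois, dphi = -0.02)
  expect_equal(s2$delta_ffo, 2 * s1$delta_ffo)
})

test_that("strategy ranking keys and tie-breaks are honoured", {
  scores <- tibble::tibble(
    area_id = 1:6,
    mean_phi = c(0.4, 0.4, 0.1, 0.3, NA, 0.2),
    n_fo = c(5L, 5L, 5L, 5L, 0L, 5L),
    n_decisions = c(10L, 0L, 50L, 5L, 3L, 2L),
    delta_ffo = c(-0.5, -0.1, -2, -0.4, NA, -0.2),
    dphi = -0.2,
    low_food_access_flag = c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  # budget covering everything selects all eligible areas
  expect_equal(sort(rank_areas("food_swamp", scores, budget = 99)$area_id),
               c(1, 2, 3, 4, 6))
  # swamp: by mean_phi, tie between areas 1 and 2 broken by lower id
  expect_equal(rank_areas("food_swamp", scores, budget = 2)$area_id, c(1, 2))
  # independent sort oracle
  elig <- scores[!is.na(scores$delta_ffo), ]
  expect_equal(rank_areas("food_swamp", scores, budget = 3)$area_id,
               elig$area_id[order(-elig$mean_phi, elig$area_id)][1:3])
  # low food access restricted to flagged areas
  expect_equal(rank_areas("low_food_access", scores, budget = 1)$area_id, 2)
  expect_error(rank_areas("low_food_access",
                          dplyr::mutate(scores, low_food_access_flag = FALSE),
                          budget = 1),
               "low food access")
  # hotspots by decisions, behaviour by |delta|
  expect_equal(rank_areas("food_hotspots", scores, budget = 2)$area_id,
               c(3, 1))
  expect_equal(rank_areas("behavior_environment", scores, budget = 2)$area_id,
               c(3, 1))
  # behaviour selection maximises the total over all size-k subsets
  all_subsets <- combn(elig$area_id, 2)
  best <- max(apply(all_subsets, 2, function(ids)
    sum(abs(elig$delta_ffo[elig$area_id %in% ids]))))
  got <- sum(abs(rank_areas("behavior_environment", scores,
                            budget = 2)$delta_ffo))
  expect_equal(got, best)
})

test_that("behaviour-environment dominates every other strategy", {
  for (profile in c("recovery", "changers")) {
    z <- fit_fullday_fixture(profile)
    scores <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois)
    strat <- evaluate_strategies(scores, z$fullday, z$fit, z$fx$users,
                                 z$fx$areas, budget = 5)
    be <- strat$total_delta_ffo[strat$strategy == "behavior_environment"]
    for (other in setdiff(strat$strategy, "behavior_environment")) {
      expect_gte(abs(be), abs(strat$total_delta_ffo[strat$strategy == other]))
    }
    expect_true(all(strat$averted_fraction >= 0 &
                      strat$averted_fraction <= 1))
    # identical selections force identical totals
    sel <- attr(strat, "selections")
    full <- evaluate_strategies(scores, z$fullday, z$fit, z$fx$users,
                                z$fx$areas, budget = nrow(z$fx$areas),
                                strategies = c("food_swamp",
                                               "behavior_environment"))
    expect_equal(full$total_delta_ffo[1], full$total_delta_ffo[2])
  }
})

test_that("income and health decompositions partition the averted total", {
  z <- fit_fullday_fixture()
  scores <- score_areas(z$fx$areas, z$fullday, z$fit, z$fx$pois)
  strat <- evaluate_strategies(scores, z$fullday, z$fit, z$fx$users,
                               z$fx$areas, budget = 5)
  for (i in seq_len(nrow(strat))) {
    expect_equal(sum(strat$by_income[[i]]$averted),
                 abs(strat$total_delta_ffo[i]), tolerance = 1e-8)
    expect_equal(sum(strat$by_health[[i]]$averted),
                 abs(strat$total_delta_ffo[i]), tolerance = 1e-8)
  }
})

test_that("LDA recovers planted area profiles", {
  set.seed(9)
  profiles <- list(
    mall = c("shopping_mall", "clothing_store", "department_store"),
    office = c("office", "bank", "coworking_space"),
    park = c("school", "park", "pharmacy"))
  pois <- purrr::map2_dfr(names(profiles), seq_along(profiles),
    function(pr, block) {
      n_area <- 12
      purrr::map_dfr(seq_len(n_area), function(a) {
        tibble::tibble(
          poi_id = 1L, category = sample(profiles[[pr]], 60, TRUE),
          area_id = (block - 1L) * n_area + a,
          x = 0, y = 0, is_food_outlet = FALSE, is_ffo = FALSE)
      })
    })
  lda <- fit_poi_topics(pois, n_topics = 3, seed = 4)
  # proportions normalise
  expect_equal(unname(rowSums(lda$theta)), rep(1, nrow(lda$theta)),
               tolerance = 1e-9)
  # match each planted profile to its best topic by cosine similarity
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (pr in names(profiles)) {
    target <- as.numeric(lda$categories %in% profiles[[pr]]) / 3
    best <- max(apply(lda$terms, 1, cosine, b = target))
    expect_gt(best, 0.8)
  }
  expect_error(fit_poi_topics(pois, n_topics = 30), "exceeds")
  # default topic count follows the 20-group convention
  expect_equal(eval(formals(fit_poi_topics)$n_topics), 20L)
})

test_that("topic enrichment is a ratio of mean weights", {
  theta <- rbind(c(0.8, 0.2, 0), c(0.6, 0.4, 0), c(0.1, 0.3, 0.6),
                 c(0.2, 0.2, 0.6))
  rownames(theta) <- 1:4
  # selecting everything gives ratio one for every topic
  all_sel <- topic_enrichment(theta, 1:4)
  expect_equal(all_sel$relative_frequency, rep(1, 3))
  # selection with zero weight on topic 3
  sel <- topic_enrichment(theta, 1:2)
  expect_equal(sel$relative_frequency[3], 0)
  # matches direct recomputation
  expect_equal(sel$relative_frequency,
               colMeans(theta[1:2, ]) / colMeans(theta))
})
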