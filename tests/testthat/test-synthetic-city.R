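# Synthetic city, users, mobility, and generative decisions.

test_that("config validation rejects malformed study designs", {
  expect_error(sim_config(n_areas = 5), "perfect square")
  expect_error(sim_config(n_days = 1), "n_days")
  expect_error(sim_config(ffo_fraction = 1.2), "proportion")
  expect_error(sim_config(n_pois = 10, env_knn = 25), "k-NN")
  expect_error(sim_config(lunch_window = c(840, 690)), "lunch_window")
})

test_that("areas tile the extent as a regular grid", {
  city <- generate_city(sim_config(n_areas = 4, city_extent_m = 2000,
                                   n_pois = 60, n_users = 5, n_days = 5,
                                   n_hotspots = 2))
  expect_equal(nrow(city$areas), 4)
  expect_true(all(city$areas$xmax - city$areas$xmin == 1000))
  expect_true(all(city$areas$ymax - city$areas$ymin == 1000))
  # tiles cover the extent without overlap
  expect_equal(sum((city$areas$xmax - city$areas$xmin) *
                     (city$areas$ymax - city$areas$ymin)), 2000^2)
  # POI area membership is consistent with point-in-cell containment
  with(city$pois, {
    a <- city$areas[match(area_id, city$areas$area_id), ]
    expect_true(all(x >= a$xmin & x <= a$xmax & y >= a$ymin & y <= a$ymax))
  })
})

test_that("fast-food share among food outlets matches the configured rate", {
  cfg <- sim_config(seed = 7, n_pois = 5000, ffo_fraction = 0.2,
                    n_users = 5, n_days = 5)
  city <- generate_city(cfg)
  fo <- city$pois[city$pois$is_food_outlet, ]
  # independent direct recount against exact binomial 99% bounds
  n_ffo <- sum(city$pois$is_ffo & city$pois$is_food_outlet)
  expect_equal(sum(fo$is_ffo), n_ffo)
  bb <- binom_bounds(nrow(fo), 0.2)
  expect_gte(n_ffo, bb[1])
  expect_lte(n_ffo, bb[2])
  # flags are consistent: fast food implies food outlet
  expect_true(all(!city$pois$is_ffo | city$pois$is_food_outlet))
})

test_that("degenerate fractions produce degenerate cities", {
  cfg <- sim_config(seed = 2, n_pois = 500, ffo_fraction = 0,
                    n_users = 5, n_days = 5)
  city <- generate_city(cfg)
  expect_false(any(city$pois$is_ffo))
})

test_that("the generator is deterministic for a fixed config", {
  cfg <- sim_config(seed = 42, n_users = 30, n_days = 10, n_areas = 16,
                    city_extent_m = 6000, n_pois = 300)
  s1 <- simulate_scenario(cfg)
  s2 <- simulate_scenario(cfg)
  expect_identical(s1$pois, s2$pois)
  expect_identical(s1$users, s2$users)
  expect_identical(s1$stays, s2$stays)
  expect_identical(s1$visits, s2$visits)
})

test_that("user generation honours preference and changer settings", {
  cfg0 <- sim_config(seed = 3, n_users = 50, n_days = 20, alpha_sd = 0,
                     context_change_fraction = 0)
  city <- generate_city(cfg0)
  u0 <- generate_users(cfg0, city$areas, city$pois)
  expect_true(all(u0$alpha == 0))
  expect_true(all(is.na(u0$anchor_change_day)))
  expect_true(all(u0$income_quantile %in% 1:5))

  cfg1 <- sim_config(seed = 3, n_users = 10000, n_days = 20,
                     context_change_fraction = 0.0046)
  u1 <- generate_users(cfg1, city$areas, city$pois)
  n_ch <- sum(!is.na(u1$anchor_change_day))
  bb <- binom_bounds(10000, 0.0046)
  expect_gte(n_ch, bb[1])
  expect_lte(n_ch, bb[2])
  # change days leave usable pre/post windows
  cd <- u1$anchor_change_day[!is.na(u1$anchor_change_day)]
  expect_true(all(cd >= 0.2 * cfg1$n_days & cd <= 0.8 * cfg1$n_days))
})

test_that("stays respect the minimum duration and anchor conventions", {
  fx <- get_fixture("tiny")
  expect_true(all(fx$stays$duration_min >= fx$config$stay_min_duration_min))
  # every user-day has a stay spanning the context cutoff
  cutoff <- fx$config$context_cutoff
  anchors <- dplyr::filter(fx$stays, kind %in% c("anchor", "errand"))
  span <- anchors %>%
    dplyr::group_by(user_id, day) %>%
    dplyr::summarise(ok = any(start_min < cutoff &
                                start_min + duration_min > cutoff),
                     .groups = "drop")
  expect_true(all(span$ok))
})

test_that("changers relocate their anchor on the configured day", {
  fx <- get_fixture("changers")
  ch <- dplyr::filter(fx$users, !is.na(anchor_change_day))
  expect_gt(nrow(ch), 0)
  anchors <- dplyr::filter(fx$stays, kind == "anchor")
  for (i in head(seq_len(nrow(ch)), 5)) {
    u <- ch[i, ]
    a <- dplyr::filter(anchors, user_id == u$user_id)
    pre <- dplyr::filter(a, day < u$anchor_change_day)
    post <- dplyr::filter(a, day >= u$anchor_change_day)
    expect_true(all(pre$x == u$anchor_x))
    expect_true(all(post$x == u$post_anchor_x))
    expect_false(u$anchor_x == u$post_anchor_x)
  }
})

test_that("decision outcomes follow the generative logistic model", {
  # neutral model: logit^-1(0) = 1/2 fast-food share
  cfg <- sim_config(seed = 8, n_users = 400, n_days = 20, beta = 0,
                    beta0 = 0, alpha_sd = 0, delta_sd = 0,
                    n_areas = 36, city_extent_m = 12000, n_pois = 900)
  scen <- simulate_scenario(cfg, dmv = FALSE)
  n <- nrow(scen$visits)
  bb <- binom_bounds(n, 0.5)
  expect_gte(sum(scen$visits$is_ffo), bb[1])
  expect_lte(sum(scen$visits$is_ffo), bb[2])

  # saturated intercept: essentially no fast-food visits
  cfg2 <- sim_config(seed = 8, n_users = 100, n_days = 10, beta = 0,
                     beta0 = -20, alpha_sd = 0, delta_sd = 0,
                     n_areas = 36, city_extent_m = 12000, n_pois = 900)
  scen2 <- simulate_scenario(cfg2, dmv = FALSE)
  expect_equal(sum(scen2$visits$is_ffo), 0)
})

test_that("simulated fast-food share matches the stored generative probabilities", {
  cfg <- sim_config(seed = 9, n_users = 1000, n_days = 40,
                    n_areas = 64, city_extent_m = 16000, n_pois = 1600)
  scen <- simulate_scenario(cfg, dmv = FALSE)
  truth <- attr(scen$visits, "truth")
  expect_gte(nrow(truth), 15000)
  p_bar <- mean(truth$p)
  se <- sqrt(p_bar * (1 - p_bar) / nrow(truth))
  expect_lt(abs(mean(truth$ffo) - p_bar), 3 * se)
})

test_that("food visits reference existing food outlets", {
  fx <- get_fixture("tiny")
  v <- dplyr::left_join(fx$visits, fx$pois, by = "poi_id")
  expect_true(all(v$is_food_outlet))
  # visit-level flag agrees with the POI catalogue
  expect_identical(v$is_ffo.x, v$is_ffo.y)
})

test_that("DMV stays are one per selected user, uniform across offices", {
  cfg <- sim_config(seed = 12, n_users = 4000, n_days = 30, dmv_count = 4,
                    dmv_user_fraction = 0.5)
  city <- generate_city(cfg)
  users <- generate_users(cfg, city$areas, city$pois)
  dmv <- simulate_dmv_visits(cfg, users, city$pois)
  expect_true(all(table(dmv$user_id) == 1))
  counts <- table(dmv$poi_id)
  expect_equal(length(counts), 4)
  bb <- binom_bounds(nrow(dmv), 1 / 4)
  expect_true(all(counts >= bb[1] & counts <= bb[2]))

  expect_error(
    simulate_dmv_visits(sim_config(dmv_count = 0), users, city$pois),
    "DMV")
})

test_that("post-DMV food visits land within two hours of the DMV stay", {
  fx <- get_fixture("dmv")
  dmv <- fx$dmv_stays
  joined <- dplyr::inner_join(
    fx$visits, dmv %>%
      dplyr::transmute(user_id, day, dmv_end = start_min + duration_min),
    by = c("user_id", "day"))
  expect_gt(nrow(joined), 0)
  expect_true(all(joined$minute > joined$dmv_end))
  expect_true(all(joined$minute <= joined$dmv_end + 120))
})
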