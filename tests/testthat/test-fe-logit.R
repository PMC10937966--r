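# Fixed-effects logistic model: likelihood optimum, identifiability,
# clustered errors, prediction, and the DMV / demographic side models.

# small deterministic decision panel, balanced so that every phi value
# carries both outcomes (no separation), and every user and day does too
toy_contexts <- function() {
  tibble::tibble(
    user_id = rep(1:4, each = 6),
    day = rep(1:6, times = 4),
    phi_context = c(0.1, 0.2, 0.3, 0.1, 0.2, 0.3,
                    0.3, 0.1, 0.2, 0.3, 0.1, 0.2,
                    0.2, 0.3, 0.1, 0.2, 0.3, 0.1,
                    0.1, 0.3, 0.2, 0.2, 0.1, 0.3),
    outcome = c(0L, 1L, 0L, 1L, 0L, 1L,
                1L, 0L, 1L, 0L, 1L, 0L,
                0L, 0L, 1L, 1L, 1L, 0L,
                1L, 1L, 0L, 0L, 0L, 1L)
  )
}

toy_loglik <- function(beta0, beta, alpha, delta, dat) {
  a <- c(0, alpha)[match(dat$user_id, 1:4)]
  d <- c(0, delta)[match(dat$day, 1:6)]
  eta <- beta0 + a + d + beta * dat$phi_context
  sum(dat$outcome * eta - log1p(exp(eta)))
}

test_that("the optimizer beats a dense grid with profiled effects", {
  dat <- toy_contexts()
  fit <- fit_fe_logit(dat, bias_correction = "none")
  # profile alpha/delta at each (beta0, beta) grid point with optim
  grid <- expand.grid(beta0 = seq(-3, 3, length.out = 9),
                      beta = seq(-6, 6, length.out = 9))
  prof <- apply(grid, 1, function(g) {
    optim(rep(0, 8), function(th) {
      -toy_loglik(g[1], g[2], th[1:3], th[4:8], dat)
    }, method = "BFGS")$value * -1
  })
  expect_gte(fit$log_likelihood, max(prof) - 1e-4)
  # likelihood trace is monotone
  expect_true(all(diff(fit$ll_trace) >= -1e-8))
})

test_that("fitted probabilities are invariant to the alpha/beta0 shift", {
  dat <- toy_contexts()
  fit <- fit_fe_logit(dat, bias_correction = "none")
  p1 <- predict_visit_probability(fit, dat)
  shifted <- fit
  shifted$user_effects$alpha <- fit$user_effects$alpha + 0.7
  shifted$beta0 <- fit$beta0 - 0.7
  p2 <- predict_visit_probability(shifted, dat)
  expect_equal(p1, p2, tolerance = 1e-12)
  # reported parameterisation is pinned by sum-to-zero constraints
  expect_equal(mean(fit$user_effects$alpha), 0, tolerance = 1e-10)
  expect_equal(mean(fit$day_effects$delta), 0, tolerance = 1e-10)
})

test_that("two-way clustered SE equals the textbook sandwich on a tiny instance", {
  dat <- toy_contexts()
  fit <- fit_fe_logit(dat, bias_correction = "none")
  # explicit dense computation from the same MLE
  X <- model.matrix(~ phi_context + factor(user_id) + factor(day), data = dat)
  a_raw <- fit$user_effects$alpha - fit$user_effects$alpha[1]
  d_raw <- fit$day_effects$delta - fit$day_effects$delta[1]
  b0_raw <- fit$beta0 + fit$user_effects$alpha[1] + fit$day_effects$delta[1]
  coefs <- c(b0_raw, fit$beta, a_raw[-1], d_raw[-1])
  p <- plogis(as.numeric(X %*% coefs))
  W <- diag(p * (1 - p))
  B <- solve(t(X) %*% W %*% X)
  meat <- function(cl) {
    s <- rowsum(X * (dat$outcome - p), cl)
    g <- nrow(s)
    (t(s) %*% s) * g / (g - 1)
  }
  V <- B %*% (meat(dat$user_id) + meat(dat$day) -
                meat(paste(dat$user_id, dat$day))) %*% B
  expect_equal(fit$se_beta_clustered, sqrt(V[2, 2]), tolerance = 1e-6)
  expect_gt(fit$se_beta_clustered, 0)
})

test_that("degenerate designs are rejected", {
  dat <- toy_contexts()
  dat$phi_context <- 0.2
  expect_error(fit_fe_logit(dat), "unidentified")
  one_user <- toy_contexts()[1:6, ]
  expect_error(fit_fe_logit(one_user), "at least 2|inclusion filter")
})

test_that("the inclusion filter drops users and days without both outcomes", {
  dat <- toy_contexts()
  extra <- tibble::tibble(user_id = 9L, day = 1:5,
                          phi_context = seq(0.1, 0.3, length.out = 5),
                          outcome = 1L)  # never non-fast-food: excluded
  fit <- fit_fe_logit(dplyr::bind_rows(dat, extra), bias_correction = "none")
  expect_false(9L %in% fit$included_users)
  expect_equal(fit$n_dropped, 5L)
})

test_that("visit probability prediction matches hand-computed logits", {
  dat <- toy_contexts()
  fit <- fit_fe_logit(dat, bias_correction = "none")
  set.seed(2)
  ctx <- tibble::tibble(
    user_id = sample(1:4, 20, TRUE), day = sample(1:6, 20, TRUE),
    phi_context = runif(20))
  p <- predict_visit_probability(fit, ctx)
  a <- fit$user_effects$alpha[ctx$user_id]
  d <- fit$day_effects$delta[ctx$day]
  expect_equal(p, plogis(fit$beta0 + a + d + fit$beta * ctx$phi_context))
  expect_true(all(p > 0 & p < 1))
  # monotone in phi for positive beta
  stopifnot(fit$beta > 0)
  ctx2 <- ctx; ctx2$phi_context <- ctx$phi_context + 0.1
  expect_true(all(predict_visit_probability(fit, ctx2) > p))
  # unseen days: reject unless the zero fallback is requested
  ctx3 <- ctx; ctx3$day <- 99L
  expect_error(predict_visit_probability(fit, ctx3), "days")
  p3 <- predict_visit_probability(fit, ctx3, new_day = "zero")
  expect_equal(p3, plogis(fit$beta0 + a + fit$beta * ctx3$phi_context))
  ctx4 <- ctx; ctx4$user_id <- 99L
  expect_error(predict_visit_probability(fit, ctx4), "users")
})

test_that("odds_change implements (e^(beta dphi) - 1) x 100", {
  expect_equal(odds_change(1.87, 0.1), 20.563, tolerance = 1e-3)
  expect_equal(odds_change(1.87, 0), 0)
  expect_equal(odds_change(0, 0.5), 0)
  expect_equal(odds_change(-1, 0.1), (exp(-0.1) - 1) * 100)
})

test_that("a null environment effect is not spuriously detected", {
  hits <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 300 + s, n_users = 150, n_days = 25, beta = 0,
                      n_areas = 36, city_extent_m = 12000, n_pois = 700,
                      outing_prob = 0.7)
    scen <- simulate_scenario(cfg, dmv = FALSE)
    ctx <- extract_lunch_contexts(scen$stays, scen$visits, scen$pois, cfg)
    fit <- fit_fe_logit(ctx)
    if (abs(fit$beta) < 3 * fit$se_beta_clustered) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("the DMV model recovers a positive environment effect", {
  fx <- get_fixture("dmv")
  prof <- suppressWarnings(compute_exposure_profiles(
    fx$users, fx$stays, fx$visits, fx$pois, fx$config))
  ctx <- extract_dmv_contexts(fx$dmv_stays, fx$visits, fx$pois, fx$config)
  fit_free <- suppressWarnings(fit_dmv_logit(ctx, prof, mu_mode = "free"))
  fit_off <- suppressWarnings(fit_dmv_logit(ctx, prof, mu_mode = "offset"))
  expect_s3_class(fit_free, "dmv_logit_fit")
  expect_equal(fit_off$mu_coefficient, 1)
  expect_gt(fit_free$se_beta_clustered, 0)
  expect_equal(fit_free$n_decisions, nrow(dplyr::semi_join(
    ctx, prof[!is.na(prof$mu), ], by = "user_id")))

  # separation and constant-phi rejections
  sep <- ctx; sep$outcome <- 1L
  expect_error(suppressWarnings(fit_dmv_logit(sep, prof)), "separated|identical")
  const <- ctx; const$phi_context <- 0.2
  expect_error(suppressWarnings(fit_dmv_logit(const, prof)), "constant")
})

test_that("demographic OLS recovers noiseless coefficients exactly", {
  fx <- get_fixture("recovery")
  areas <- fx$areas
  users <- fx$users
  preds <- foodscape:::demographic_predictors()
  z <- scale(as.matrix(areas[preds]))
  resp_area <- as.numeric(0.3 + z %*% c(0.2, -0.1, 0.05, 0, 0.1, -0.2, 0.15))
  prof <- tibble::tibble(
    user_id = users$user_id,
    phi_mobile = resp_area[match(users$home_area_id, areas$area_id)],
    phi_home = 0.1, mu = 0.2, n_food_visits = 1L)
  fit <- suppressWarnings(   # perfect fit by construction
    regress_exposure_on_demographics(prof, users, areas, "phi_mobile"))
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)

  # matches the closed-form normal-equations solution
  dat <- prof %>%
    dplyr::left_join(users[, c("user_id", "home_area_id")], by = "user_id") %>%
    dplyr::left_join(areas[, c("area_id", preds)],
                     by = c(home_area_id = "area_id"))
  Xz <- scale(as.matrix(dat[preds]))
  X <- cbind(1, Xz)
  bhat <- solve(t(X) %*% X, t(X) %*% dat$phi_mobile)
  got <- fit$coefficients$estimate
  expect_equal(unname(got), unname(as.numeric(bhat)), tolerance = 1e-8)
  # CI half-width is 1.96 SE
  expect_equal(fit$coefficients$conf.high - fit$coefficients$estimate,
               1.96 * fit$coefficients$std.error)
})

test_that("collinear predictors are rejected by name", {
  fx <- get_fixture("recovery")
  areas <- fx$areas
  areas$pct_black <- areas$pct_low_skill   # exact collinearity
  prof <- tibble::tibble(user_id = fx$users$user_id, phi_mobile = runif(
    nrow(fx$users)), phi_home = 0.1, mu = 0.2, n_food_visits = 1L)
  expect_error(
    regress_exposure_on_demographics(prof, fx$users, areas, "phi_mobile"),
    "collinear.*pct")
})

test_that("the DMV model recovers the generative slope across seeds", {
  ok <- 0
  for (s in 1:10) {
    cfg <- sim_config(seed = 900 + s, n_users = 1600, n_days = 30,
                      dmv_count = 10L, dmv_user_fraction = 1,
                      n_areas = 64, city_extent_m = 16000, n_pois = 1600)
    scen <- simulate_scenario(cfg)
    prof <- suppressWarnings(compute_exposure_profiles(
      scen$users, scen$stays, scen$visits, scen$pois, cfg))
    ctx <- extract_dmv_contexts(scen$dmv_stays, scen$visits, scen$pois, cfg)
    fit <- suppressWarnings(fit_dmv_logit(ctx, prof))
    if (fit$beta > 0 &&
        abs(fit$beta - cfg$beta) <= 3 * fit$se_beta_clustered) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
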