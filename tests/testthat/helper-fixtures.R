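# Shared fixtures, generated once per test run and cached.

fixture_cache <- new.env(parent = emptyenv())

get_fixture <- function(profile, seed = 101L) {
  key <- paste(profile, seed, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_fixture(profile, seed = seed)
  }
  fixture_cache[[key]]
}

# a small hand-built POI table with known geometry: food outlets on a line,
# fast-food flags chosen per test
line_pois <- function(xs, ffo, food = TRUE) {
  tibble::tibble(
    poi_id = seq_along(xs), x = xs, y = 0,
    category = ifelse(ffo, "fast_food", "restaurant"),
    is_food_outlet = food, is_ffo = ffo, area_id = 1L
  )
}

# exact binomial 99% acceptance bounds
binom_bounds <- function(n, p, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p))
}

# brute-force environment oracles, kept deliberately naive
oracle_phi_radius <- function(loc, pois, radius) {
  fo <- pois[pois$is_food_outlet, ]
  d <- sqrt((fo$x - loc[1])^2 + (fo$y - loc[2])^2)
  inside <- d <= radius
  if (!any(inside)) return(NA_real_)
  sum(fo$is_ffo[inside]) / sum(inside)
}

oracle_phi_knn <- function(loc, pois, k) {
  fo <- pois[pois$is_food_outlet, ]
  fo <- fo[order(fo$poi_id), ]
  d <- sqrt((fo$x - loc[1])^2 + (fo$y - loc[2])^2)
  nn <- order(d)[seq_len(k)]
  mean(fo$is_ffo[nn])
}

# paired treated/control group-fraction series for counterfactual tests:
# a shared day-level component plus independent sampling noise, with an
# optional post-change step added to the treated series
simulate_pair <- function(seed, step = 0, n_pre = 60, n_post = 50,
                          base = 0.16, noise = 0.025, common = 0.02) {
  set.seed(seed)
  n <- n_pre + n_post
  s <- rnorm(n, 0, common)
  control <- base + s + rnorm(n, 0, noise)
  treated <- base + s + rnorm(n, 0, noise) + step * (seq_len(n) > n_pre)
  list(treated = treated, control = control,
       aligned_day = seq(-n_pre, n_post - 1))
}
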