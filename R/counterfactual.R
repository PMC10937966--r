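# Counterfactual estimation for the natural experiment: a structural
# time-series model
#     y_t  = mu_t + gamma * x_t + eps_t,   eps_t ~ N(0, s_eps^2)
#     mu_t+1 = mu_t + eta_t,               eta_t ~ N(0, s_eta^2)
# fit to the treated group's PRE-change series with the control group's
# series as regression covariate, by maximum likelihood with Kalman
# filtering. Post-change predictions come from posterior-predictive
# simulation at the MLE; intervals widen with horizon because the local
# level is a random walk. A difference-in-means fallback handles series
# too short for state-space estimation.

kalman_loglik <- function(par, y, x) {
  s_eps2 <- exp(2 * par[1]); s_eta2 <- exp(2 * par[2]); gamma <- par[3]
  n <- length(y)
  a <- y[1] - gamma * x[1]
  P <- 1e4
  ll <- 0
  for (t in 2:n) {
    P <- P + s_eta2
    f <- a + gamma * x[t]
    Fv <- P + s_eps2
    v <- y[t] - f
    ll <- ll - 0.5 * (log(2 * pi * Fv) + v^2 / Fv)
    K <- P / Fv
    a <- a + K * v
    P <- P * (1 - K)
  }
  ll
}

kalman_filter_final <- function(par, y, x) {
  s_eps2 <- exp(2 * par[1]); s_eta2 <- exp(2 * par[2]); gamma <- par[3]
  n <- length(y)
  a <- y[1] - gamma * x[1]
  P <- 1e4
  pred <- numeric(n); pred[1] <- y[1]
  for (t in 2:n) {
    P <- P + s_eta2
    pred[t] <- a + gamma * x[t]
    Fv <- P + s_eps2
    K <- P / Fv
    a <- a + K * (y[t] - pred[t])
    P <- P * (1 - K)
  }
  list(a = a, P = P, pred = pred, s_eps2 = s_eps2, s_eta2 = s_eta2,
       gamma = gamma)
}

#' Estimate the counterfactual trajectory after a context change
#'
#' Fits a local-level state-space model with the control series as a
#' regression covariate to the treated group's pre-change series, then
#' simulates the post-change counterfactual with 95\% posterior-predictive
#' intervals (\code{n_draws} paths at the maximum-likelihood parameters).
#' The pointwise effect is observed minus predicted; the cumulative effect
#' is its running sum (zero at the change day by definition) with
#' intervals propagated through the draws.
#'
#' @param treated,control Numeric series of group visit fractions on a
#'   common aligned-day grid.
#' @param aligned_day Integer aligned days (negative = pre-change); the
#'   post period starts at 0.
#' @param n_draws Posterior-predictive draws (default 1000).
#' @param min_pre Minimum pre-period length for the state-space model
#'   (default 20); shorter pre-periods fall back to a difference-in-means
#'   counterfactual.
#' @param seed Seed for the predictive simulation.
#' @return An object of class \code{"counterfactual"} whose \code{series}
#'   tibble holds observed, predicted, 95\% interval, pointwise and
#'   cumulative effects per aligned day.
#' @export
estimate_counterfactual <- function(treated, control, aligned_day,
                                    n_draws = 1000L, min_pre = 20L,
                                    seed = 1L) {
  stopifnot(length(treated) == length(control),
            length(treated) == length(aligned_day))
  ord <- order(aligned_day)
  treated <- treated[ord]; control <- control[ord]
  aligned_day <- aligned_day[ord]
  pre <- aligned_day < 0
  post <- !pre
  if (any(is.na(control[post])))
    abort("control series missing post-period days: counterfactual undefined.")
  keep_pre <- pre & !is.na(treated) & !is.na(control)
  n_pre <- sum(keep_pre)
  n_post <- sum(post)
  if (n_post == 0) abort("no post-period days.")
  set.seed(seed)

  if (n_pre >= min_pre) {
    y <- treated[keep_pre]; x <- control[keep_pre]
    g0 <- if (sd(x) > 1e-10) coef(lm(y ~ x))[2] else 0
    r0 <- sd(y - g0 * x)
    par0 <- c(log(max(r0 * 0.8, 1e-4)), log(max(r0 * 0.3, 1e-4)), g0)
    opt <- optim(par0, function(p) -kalman_loglik(p, y, x),
                 method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
    kf <- kalman_filter_final(opt$par, y, x)
    method <- "state_space"

    x_post <- control[post]
    h <- length(x_post)
    draws <- matrix(0, n_draws, h)
    for (s in seq_len(n_draws)) {
      level <- rnorm(1, kf$a, sqrt(kf$P))
      lev_path <- level + cumsum(rnorm(h, 0, sqrt(kf$s_eta2)))
      draws[s, ] <- lev_path + kf$gamma * x_post +
        rnorm(h, 0, sqrt(kf$s_eps2))
    }
    pred_post <- colMeans(draws)
    lo_post <- apply(draws, 2, quantile, 0.025)
    hi_post <- apply(draws, 2, quantile, 0.975)
    pred_pre <- rep(NA_real_, length(treated))
    pred_pre[keep_pre] <- kf$pred
    model <- list(sigma_eps = sqrt(kf$s_eps2), sigma_eta = sqrt(kf$s_eta2),
                  gamma = kf$gamma, loglik = -opt$value)
  } else {
    # difference-in-means fallback: counterfactual = control + pre-period
    # mean gap, with a constant normal interval
    gap <- treated[keep_pre] - control[keep_pre]
    m <- mean(gap); s <- sd(gap) / sqrt(max(n_pre, 1))
    if (!is.finite(s)) s <- 0
    x_post <- control[post]
    pred_post <- x_post + m
    se_tot <- sqrt(s^2 + var(gap) * (n_pre > 1))
    lo_post <- pred_post - 1.96 * se_tot
    hi_post <- pred_post + 1.96 * se_tot
    draws <- matrix(rnorm(n_draws * length(x_post), rep(pred_post,
                                                        each = n_draws),
                          se_tot), n_draws)
    pred_pre <- rep(NA_real_, length(treated))
    pred_pre[keep_pre] <- control[keep_pre] + m
    method <- "diff_in_means"
    model <- list(gap_mean = m, gap_sd = sd(gap))
    warn(sprintf("pre-period has %d days (< %d): difference-in-means fallback used.",
                 n_pre, min_pre))
  }

  obs_post <- treated[post]
  eff_draws <- sweep(-draws, 2, obs_post, "+")
  cum_draws <- t(apply(eff_draws, 1, cumsum))
  if (length(obs_post) == 1) cum_draws <- t(cum_draws)
  # the change day itself is the reference: cumulative effect is 0 there
  # and accumulates from the following day on
  ref0 <- which(aligned_day[post] == 0)
  if (length(ref0) == 1) {
    cum_draws <- cum_draws - cum_draws[, ref0]
  }

  series <- tibble(
    aligned_day = aligned_day,
    observed = treated,
    control = control,
    predicted = pred_pre,
    pred_lower = NA_real_, pred_upper = NA_real_,
    effect = NA_real_, cum_effect = NA_real_,
    cum_lower = NA_real_, cum_upper = NA_real_
  )
  series$predicted[post] <- pred_post
  series$pred_lower[post] <- lo_post
  series$pred_upper[post] <- hi_post
  series$effect[post] <- obs_post - pred_post
  cum_pt <- cumsum(obs_post - pred_post)
  if (length(ref0) == 1) cum_pt <- cum_pt - cum_pt[ref0]
  series$cum_effect[post] <- cum_pt
  series$cum_lower[post] <- apply(cum_draws, 2, quantile, 0.025)
  series$cum_upper[post] <- apply(cum_draws, 2, quantile, 0.975)

  out <- list(series = series, method = method, model = model,
              n_pre = n_pre, n_post = n_post, n_draws = n_draws)
  class(out) <- "counterfactual"
  out
}

#' @export
print.counterfactual <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  cat(sprintf("<counterfactual> method: %s, %d pre / %d post days\n",
              x$method, x$n_pre, x$n_post))
  cat(sprintf("  mean pointwise effect: %.4f\n",
              mean(x$series$effect, na.rm = TRUE)))
  cat(sprintf("  cumulative effect at day %d: %.3f [%.3f, %.3f]\n",
              last$aligned_day, last$cum_effect, last$cum_lower,
              last$cum_upper))
  invisible(x)
}

#' @export
tidy.counterfactual <- function(x, ...) x$series

#' @export
glance.counterfactual <- function(x, ...) {
  last <- x$series[nrow(x$series), ]
  tibble(
    method = x$method,
    mean_effect = mean(x$series$effect, na.rm = TRUE),
    cum_effect = last$cum_effect,
    cum_lower = last$cum_lower, cum_upper = last$cum_upper,
    n_pre = x$n_pre, n_post = x$n_post
  )
}

#' Plot a counterfactual analysis
#'
#' @param object A \code{counterfactual} object.
#' @param panel \code{"fraction"} (observed vs predicted with 95\% ribbon)
#'   or \code{"cumulative"} (cumulative effect with interval).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.counterfactual <- function(object,
                                    panel = c("fraction", "cumulative"),
                                    ...) {
  panel <- match.arg(panel)
  s <- object$series
  if (panel == "fraction") {
    ggplot2::ggplot(s, ggplot2::aes(x = .data$aligned_day)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lower,
                                        ymax = .data$pred_upper),
                           fill = "grey80", na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                         linetype = 2, na.rm = TRUE) +
      ggplot2::geom_line(ggplot2::aes(y = .data$observed), na.rm = TRUE) +
      ggplot2::geom_vline(xintercept = 0, linetype = 3) +
      ggplot2::labs(x = "days since context change",
                    y = "fraction of fast-food visits") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(dplyr::filter(s, !is.na(.data$cum_effect)),
                    ggplot2::aes(x = .data$aligned_day)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cum_lower,
                                        ymax = .data$cum_upper),
                           fill = "grey80") +
      ggplot2::geom_line(ggplot2::aes(y = .data$cum_effect)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 3) +
      ggplot2::labs(x = "days since context change",
                    y = "cumulative difference in fast-food visits") +
      ggplot2::theme_minimal()
  }
}
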