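# Fixed-effects logistic visit model. The probability that decision (i, t)
# lands on a fast-food outlet is
#   Pr(y_it = 1) = logit^-1(beta0 + alpha_i + delta_t + beta * phi(c_it)),
# estimated by maximum likelihood on a sparse indicator design (Newton/IRLS)
# with two-way cluster-robust errors (user and day) for beta.
#
# Identifiability: the raw fit uses reference coding (first included user
# and day pinned to zero); reported effects are re-centred to sum-to-zero
# over included users and days, with the grand mean folded into beta0.
# Predicted probabilities are invariant to this re-parameterisation.

#' Fit the fixed-effects logistic visit model
#'
#' Estimates \eqn{\beta}, \eqn{\beta_0}, user effects \eqn{\alpha_i}, and
#' day effects \eqn{\delta_t} from decision contexts with observed binary
#' outcomes. Before fitting, users without both a fast-food and a
#' non-fast-food outcome are dropped (they carry no within-user contrast),
#' and likewise days; the filter is iterated to a fixed point. The
#' environment slope's standard error is two-way cluster-robust by user and
#' day via the inclusion-exclusion rule (user + day - user x day cells),
#' with a G/(G-1) small-sample factor per component.
#'
#' The reported slope applies a split-panel jackknife by default: the
#' unconditional dummy-variable MLE carries incidental-parameter bias of
#' order \eqn{1/T_i} in the per-user decision count, noticeable on
#' desk-scale panels. The correction splits the panel into odd and even
#' days, estimates the bias delta on the users fittable in the full panel
#' and in both halves, and subtracts it from the full-panel MLE
#' (\code{beta_mle} is always retained). \code{bias_correction = "none"}
#' reports the plain MLE.
#'
#' @param contexts A decision-context tibble (see
#'   [extract_lunch_contexts()]) with non-missing \code{outcome}.
#' @param tol Convergence tolerance on the maximum absolute score
#'   (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param bias_correction \code{"split_panel"} (default) or \code{"none"}.
#' @return An object of class \code{"fe_logit_fit"}: estimates, re-centred
#'   user/day effects, clustered and model-based standard errors for
#'   \code{beta}, log-likelihood trace, and an inclusion log.
#' @examples
#' \donttest{
#' fx <- make_fixture("tiny")
#' ctx <- extract_lunch_contexts(fx$stays, fx$visits, fx$pois, fx$config)
#' fit <- fit_fe_logit(ctx)
#' tidy(fit)
#' }
#' @export
fit_fe_logit <- function(contexts, tol = 1e-8, max_iter = 100L,
                         bias_correction = c("split_panel", "none")) {
  bias_correction <- match.arg(bias_correction)
  dat <- contexts %>% filter(!is.na(.data$outcome))
  if (nrow(dat) == 0) abort("no contexts with observed outcomes.")

  # inclusion filter: users and days must each show both outcomes
  n0 <- nrow(dat)
  repeat {
    ok_u <- dat %>% group_by(.data$user_id) %>%
      summarise(ok = any(.data$outcome == 1) && any(.data$outcome == 0),
                .groups = "drop")
    ok_d <- dat %>% group_by(.data$day) %>%
      summarise(ok = any(.data$outcome == 1) && any(.data$outcome == 0),
                .groups = "drop")
    dat2 <- dat %>%
      semi_join(ok_u %>% filter(.data$ok), by = "user_id") %>%
      semi_join(ok_d %>% filter(.data$ok), by = "day")
    if (nrow(dat2) == nrow(dat)) break
    dat <- dat2
    if (nrow(dat) == 0) abort("inclusion filter removed all decisions.")
  }
  users <- sort(unique(dat$user_id))
  days <- sort(unique(dat$day))
  if (length(users) < 2 || length(days) < 2)
    abort("need at least 2 users and 2 days after the inclusion filter.")
  if (stats::sd(dat$phi_context) < 1e-12)
    abort("phi is constant across retained contexts: beta unidentified.")

  y <- dat$outcome
  n <- length(y)
  ui <- match(dat$user_id, users)
  di <- match(dat$day, days)
  nu <- length(users); nd <- length(days)

  # sparse design: intercept, phi, user dummies 2..nu, day dummies 2..nd
  p_fix <- 2L
  ncol_x <- p_fix + (nu - 1L) + (nd - 1L)
  ii <- c(seq_len(n), seq_len(n),
          which(ui > 1L), which(di > 1L))
  jj <- c(rep(1L, n), rep(2L, n),
          p_fix + ui[ui > 1L] - 1L,
          p_fix + (nu - 1L) + di[di > 1L] - 1L)
  xx <- c(rep(1, n), dat$phi_context,
          rep(1, sum(ui > 1L)), rep(1, sum(di > 1L)))
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, ncol_x))

  beta_hat <- numeric(ncol_x)
  beta_hat[1] <- qlogis(mean(y))
  eta <- as.numeric(X %*% beta_hat)
  ll <- sum(y * eta - log1p(exp(eta)))
  ll_trace <- ll
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    p <- plogis(eta)
    score <- as.numeric(Matrix::crossprod(X, y - p))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-10)
    H <- Matrix::crossprod(X, X * w)
    step <- as.numeric(Matrix::solve(H, score))
    # step-halving: likelihood must not decrease
    lam <- 1
    repeat {
      cand <- beta_hat + lam * step
      eta_c <- as.numeric(X %*% cand)
      ll_c <- sum(y * eta_c - log1p(exp(eta_c)))
      if (ll_c >= ll - 1e-12 || lam < 1e-6) break
      lam <- lam / 2
    }
    beta_hat <- cand
    eta <- eta_c
    ll <- ll_c
    ll_trace <- c(ll_trace, ll)
  }
  if (!converged) {
    p <- plogis(eta)
    score <- as.numeric(Matrix::crossprod(X, y - p))
    if (max(abs(score)) < 1e-4) {
      converged <- TRUE
    } else {
      abort(sprintf(
        "IRLS did not converge in %d iterations (max |score| = %.3g, log-lik = %.4f).",
        max_iter, max(abs(score)), ll))
    }
  }

  p <- plogis(eta)
  w <- pmax(p * (1 - p), 1e-10)
  H <- Matrix::crossprod(X, X * w)

  # cluster-robust variance for beta without forming the full inverse:
  # se^2 = u' M u with u = H^-1 e_beta, M the two-way meat
  e_beta <- numeric(ncol_x); e_beta[2] <- 1
  u <- as.numeric(Matrix::solve(H, e_beta))
  v <- as.numeric(X %*% u) * (y - p)   # per-observation u's_i
  cl_var <- function(cl) {
    g <- length(unique(cl))
    s <- tapply(v, cl, sum)
    sum(s^2) * g / max(g - 1, 1)
  }
  var_user <- cl_var(ui)
  var_day <- cl_var(di)
  var_int <- cl_var(paste(ui, di))
  var_two <- var_user + var_day - var_int
  if (var_two <= 0) {
    warn("two-way clustered variance non-positive; falling back to max of one-way components.")
    var_two <- max(var_user, var_day)
  }
  se_beta_cl <- sqrt(var_two)
  se_beta_model <- sqrt(u[2])

  # re-centre to sum-to-zero effects
  alpha_raw <- c(0, beta_hat[p_fix + seq_len(nu - 1L)])
  delta_raw <- c(0, beta_hat[p_fix + (nu - 1L) + seq_len(nd - 1L)])
  a_bar <- mean(alpha_raw); d_bar <- mean(delta_raw)

  beta_mle <- beta_hat[2]
  beta_report <- beta_mle
  if (bias_correction == "split_panel") {
    delta_bias <- tryCatch(
      split_panel_bias(dat, tol = tol, max_iter = max_iter),
      error = function(e) {
        warn(sprintf(
          "split-panel bias correction unavailable (%s); reporting the plain MLE.",
          conditionMessage(e)))
        NA_real_
      })
    if (is.na(delta_bias)) bias_correction <- "none" else
      beta_report <- beta_mle - delta_bias
  }

  fit <- list(
    beta = beta_report,
    beta_mle = beta_mle,
    bias_correction = bias_correction,
    beta0 = beta_hat[1] + a_bar + d_bar,
    user_effects = tibble(user_id = users, alpha = alpha_raw - a_bar),
    day_effects = tibble(day = days, delta = delta_raw - d_bar),
    se_beta_clustered = se_beta_cl,
    se_beta_model = se_beta_model,
    vcov_components = c(user = var_user, day = var_day,
                        intersection = var_int),
    n_decisions = n,
    n_users = nu, n_days = nd,
    included_users = users, included_days = days,
    n_dropped = n0 - n,
    log_likelihood = ll,
    ll_trace = ll_trace,
    iterations = length(ll_trace) - 1L,
    converged = converged
  )
  class(fit) <- "fe_logit_fit"
  fit
}

#' @export
print.fe_logit_fit <- function(x, ...) {
  cat("<fe_logit_fit>\n")
  cat(sprintf("  beta  = %.4f  (two-way clustered SE %.4f%s)\n",
              x$beta, x$se_beta_clustered,
              if (x$bias_correction == "split_panel")
                sprintf(", split-panel corrected; MLE %.4f", x$beta_mle)
              else ""))
  cat(sprintf("  beta0 = %.4f\n", x$beta0))
  cat(sprintf("  %d decisions, %d users, %d days (%d rows dropped by inclusion filter)\n",
              x$n_decisions, x$n_users, x$n_days, x$n_dropped))
  cat(sprintf("  log-likelihood %.2f after %d Newton iterations\n",
              x$log_likelihood, x$iterations))
  invisible(x)
}

#' Predict fast-food visit probabilities from a fitted model
#'
#' Evaluates \eqn{\mathrm{logit}^{-1}(\beta_0 + \alpha_i + \delta_t +
#' \beta\phi)} for each context row. Users must be part of the fit; days
#' not seen in the fit either raise an error (default) or use
#' \eqn{\delta = 0}, the constrained mean, when \code{new_day = "zero"} --
#' the fallback the full-day intervention evaluation relies on.
#'
#' @param fit A [fit_fe_logit()] object.
#' @param contexts Tibble with \code{user_id}, \code{day},
#'   \code{phi_context}.
#' @param new_day Either \code{"error"} or \code{"zero"}.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_visit_probability <- function(fit, contexts,
                                      new_day = c("error", "zero")) {
  new_day <- match.arg(new_day)
  stopifnot(inherits(fit, "fe_logit_fit"))
  a <- fit$user_effects$alpha[match(contexts$user_id,
                                    fit$user_effects$user_id)]
  if (anyNA(a))
    abort("contexts contain users not present in the fit.")
  d <- fit$day_effects$delta[match(contexts$day, fit$day_effects$day)]
  if (anyNA(d)) {
    if (new_day == "error")
      abort("contexts contain days not present in the fit (set new_day = \"zero\" to use the constrained mean).")
    d[is.na(d)] <- 0
  }
  plogis(fit$beta0 + a + d + fit$beta * contexts$phi_context)
}

#' Percent change in fast-food visit odds for a shift in phi
#'
#' Converts a logistic slope into the percent change in the odds of a
#' fast-food visit when the context's fast-food ratio increases by
#' \code{delta_phi}: \eqn{(e^{\beta\,\Delta\phi} - 1)\times 100}.
#'
#' @param beta Logistic slope on \eqn{\phi}.
#' @param delta_phi Change in the environment ratio (e.g. 0.1 for ten
#'   percentage points more fast food).
#' @return Percent change in odds.
#' @examples
#' odds_change(1.87, 0.1)
#' @export
odds_change <- function(beta, delta_phi) {
  (exp(beta * delta_phi) - 1) * 100
}

#' @export
tidy.fe_logit_fit <- function(x, effects = c("fixed", "user", "day"), ...) {
  effects <- match.arg(effects)
  if (effects == "user") {
    return(x$user_effects %>% rename(estimate = "alpha"))
  }
  if (effects == "day") {
    return(x$day_effects %>% rename(estimate = "delta"))
  }
  tibble(
    term = c("beta", "beta0"),
    estimate = c(x$beta, x$beta0),
    std.error = c(x$se_beta_clustered, NA_real_),
    conf.low = c(x$beta - 1.96 * x$se_beta_clustered, NA_real_),
    conf.high = c(x$beta + 1.96 * x$se_beta_clustered, NA_real_)
  )
}

#' @export
glance.fe_logit_fit <- function(x, ...) {
  tibble(
    n_decisions = x$n_decisions, n_users = x$n_users, n_days = x$n_days,
    n_dropped = x$n_dropped, log_likelihood = x$log_likelihood,
    iterations = x$iterations, converged = x$converged
  )
}

# Incidental-parameter bias delta for the slope via an odd/even-day
# split-panel jackknife, evaluated on the users fittable in the full panel
# and in both halves (half panels drop far more users through the
# inclusion filter; holding the population fixed isolates the 1/T bias).
split_panel_bias <- function(dat, tol, max_iter) {
  days <- sort(unique(dat$day))
  if (length(days) < 8)
    abort("fewer than 8 decision days")
  h1 <- dat[dat$day %in% days[seq_along(days) %% 2 == 1], , drop = FALSE]
  h2 <- dat[dat$day %in% days[seq_along(days) %% 2 == 0], , drop = FALSE]
  fittable <- function(d) {
    t <- tapply(d$outcome, d$user_id,
                function(z) any(z == 1) && any(z == 0))
    names(t)[t]
  }
  common <- intersect(intersect(fittable(h1), fittable(h2)), fittable(dat))
  if (length(common) < 10)
    abort("fewer than 10 users fittable in both half panels")
  keep <- function(d) d[as.character(d$user_id) %in% common, , drop = FALSE]
  b_full <- fit_fe_logit(keep(dat), tol, max_iter,
                         bias_correction = "none")$beta
  b1 <- fit_fe_logit(keep(h1), tol, max_iter,
                     bias_correction = "none")$beta
  b2 <- fit_fe_logit(keep(h2), tol, max_iter,
                     bias_correction = "none")$beta
  (b1 + b2) / 2 - b_full
}
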