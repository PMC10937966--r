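# DMV natural-experiment model: logistic regression of the fast-food
# outcome on the DMV context's phi, with each user's overall fast-food
# visit fraction mu_i standing in for the preference fixed effect (users
# typically visit the DMV once, so alpha_i is not estimable) and no day
# effects. mu_i enters with a free slope by default; a constrained
# unit-slope offset mode is also provided.

#' Fit the DMV-context visit model
#'
#' @param dmv_contexts DMV decision contexts from [extract_dmv_contexts()].
#' @param exposure_profiles Per-user profiles from
#'   [compute_exposure_profiles()]; supplies \eqn{\mu_i}.
#' @param mu_mode \code{"free"} (default): \eqn{\mu_i} enters as a
#'   covariate with its own slope; \code{"offset"}: \eqn{\mu_i} enters as
#'   a fixed unit-slope offset on the logit scale.
#' @return An object of class \code{"dmv_logit_fit"} with the environment
#'   slope \code{beta}, its user-clustered standard error, and the
#'   underlying \code{glm}.
#' @export
fit_dmv_logit <- function(dmv_contexts, exposure_profiles,
                          mu_mode = c("free", "offset")) {
  mu_mode <- match.arg(mu_mode)
  dat <- dmv_contexts %>%
    filter(!is.na(.data$outcome)) %>%
    left_join(exposure_profiles %>% select("user_id", "mu"), by = "user_id")
  if (anyNA(dat$mu)) {
    warn(sprintf("%d DMV context(s) dropped: user mu undefined (no food visits).",
                 sum(is.na(dat$mu))))
    dat <- dat %>% filter(!is.na(.data$mu))
  }
  if (nrow(dat) < 3) abort("too few DMV decisions to fit.")
  if (length(unique(dat$outcome)) < 2)
    abort("all DMV outcomes identical: model separated, beta unidentified.")
  if (stats::sd(dat$phi_context) < 1e-12)
    abort("phi constant across DMV contexts: beta unidentified.")

  fit <- if (mu_mode == "free") {
    glm(outcome ~ phi_context + mu, family = binomial(), data = dat)
  } else {
    glm(outcome ~ phi_context + offset(mu), family = binomial(), data = dat)
  }
  vc <- sandwich::vcovCL(fit, cluster = dat$user_id)
  out <- list(
    beta = unname(coef(fit)["phi_context"]),
    se_beta_clustered = sqrt(vc["phi_context", "phi_context"]),
    mu_mode = mu_mode,
    mu_coefficient = if (mu_mode == "free") unname(coef(fit)["mu"]) else 1,
    n_decisions = nrow(dat),
    glm_fit = fit
  )
  class(out) <- "dmv_logit_fit"
  out
}

#' @export
print.dmv_logit_fit <- function(x, ...) {
  cat("<dmv_logit_fit>\n")
  cat(sprintf("  beta = %.4f (user-clustered SE %.4f), mu mode: %s\n",
              x$beta, x$se_beta_clustered, x$mu_mode))
  cat(sprintf("  %d DMV decisions\n", x$n_decisions))
  invisible(x)
}

#' @export
tidy.dmv_logit_fit <- function(x, ...) {
  tibble(
    term = c("beta", if (x$mu_mode == "free") "mu"),
    estimate = c(x$beta, if (x$mu_mode == "free") x$mu_coefficient),
    std.error = c(x$se_beta_clustered,
                  if (x$mu_mode == "free") NA_real_)
  )
}

#' @export
glance.dmv_logit_fit <- function(x, ...) {
  tibble(n_decisions = x$n_decisions, mu_mode = x$mu_mode,
         deviance = x$glm_fit$deviance)
}
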