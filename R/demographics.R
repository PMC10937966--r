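# Area-demographic associations of exposure and behaviour: OLS of a
# per-user response (mobile exposure, home exposure, or fast-food visit
# fraction) on the z-standardised demographics of the user's home area.

demographic_predictors <- function() {
  c("pct_low_skill", "pct_long_commute", "pct_public_transit",
    "pct_employed", "pct_higher_ed", "median_income", "pct_black")
}

#' Regress an exposure response on home-area demographics
#'
#' Ordinary least squares of \code{phi_mobile}, \code{phi_home}, or
#' \code{mu} on the z-standardised demographic covariates of each user's
#' home area. Coefficients are therefore comparable across predictors;
#' 95\% confidence intervals are \eqn{\pm 1.96} standard errors.
#'
#' @param exposure_profiles From [compute_exposure_profiles()].
#' @param users User table (supplies \code{home_area_id}).
#' @param areas Area table with demographic columns.
#' @param response One of \code{"phi_mobile"}, \code{"phi_home"},
#'   \code{"mu"}.
#' @return An object of class \code{"exposure_ols"} wrapping the
#'   \code{lm} fit, with a tidy coefficient table and \eqn{R^2}.
#' @export
regress_exposure_on_demographics <- function(exposure_profiles, users, areas,
                                             response = c("phi_mobile",
                                                          "phi_home", "mu")) {
  response <- match.arg(response)
  preds <- demographic_predictors()
  dat <- exposure_profiles %>%
    left_join(users %>% select("user_id", "home_area_id"), by = "user_id") %>%
    left_join(areas %>% select("area_id", all_of(preds)),
              by = c(home_area_id = "area_id")) %>%
    select(all_of(c(response, preds))) %>%
    filter(complete.cases(.))
  if (nrow(dat) < 2 * (length(preds) + 1))
    abort("need at least twice as many observations as predictors.")

  for (p in preds) {
    s <- sd(dat[[p]])
    if (s < 1e-12) abort(sprintf("predictor `%s` is constant.", p))
    dat[[p]] <- (dat[[p]] - mean(dat[[p]])) / s
  }
  cm <- cor(as.matrix(dat[preds]))
  diag(cm) <- 0
  if (any(abs(cm) > 0.999)) {
    bad <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    abort(sprintf("collinear predictors: `%s` and `%s`.",
                  preds[bad[1]], preds[bad[2]]))
  }

  X <- cbind(1, as.matrix(dat[preds]))
  if (qr(X)$rank < ncol(X))
    abort("predictor matrix is rank deficient (too few distinct home areas).")

  fml <- stats::as.formula(paste(response, "~", paste(preds, collapse = " + ")))
  fit <- lm(fml, data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  out <- list(
    response_name = response,
    coefficients = tibble(
      term = rownames(co),
      estimate = co[, 1], std.error = co[, 2],
      conf.low = co[, 1] - 1.96 * co[, 2],
      conf.high = co[, 1] + 1.96 * co[, 2]
    ),
    r_squared = sm$r.squared,
    n = nrow(dat),
    lm_fit = fit
  )
  class(out) <- "exposure_ols"
  out
}

#' @export
print.exposure_ols <- function(x, ...) {
  cat(sprintf("<exposure_ols> response: %s, n = %d, R^2 = %.3f\n",
              x$response_name, x$n, x$r_squared))
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.exposure_ols <- function(x, ...) x$coefficients

#' @export
glance.exposure_ols <- function(x, ...) {
  tibble(response = x$response_name, r.squared = x$r_squared, n = x$n)
}

#' Coefficient plot for demographic association models
#'
#' @param object An \code{exposure_ols} fit.
#' @param ... Unused.
#' @return A ggplot object (point estimates with 95\% CI bars, intercept
#'   omitted).
#' @export
autoplot.exposure_ols <- function(object, ...) {
  dat <- object$coefficients %>% filter(.data$term != "(Intercept)")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate,
                                    y = stats::reorder(.data$term,
                                                       .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "standardised OLS coefficient (95% CI)", y = NULL,
      title = sprintf("Demographic associations of %s", object$response_name)
    ) +
    ggplot2::theme_minimal()
}
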