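# Food-environment ratio phi(x): share of fast-food outlets (FFO) among all
# food outlets (FO) around a location, either within a fixed radius or among
# the k nearest FO. Planar Euclidean geometry throughout.

# Vectorised engine. locations: data frame / matrix with x, y columns.
# Returns tibble(phi, n_fo, n_ffo). For method = "knn", n_fo is k.
env_stats <- function(locations, pois, method = c("radius", "knn"),
                      radius_m = 1000, k = 25L, chunk = 1024L) {
  method <- match.arg(method)
  loc <- as.data.frame(locations)[, c("x", "y"), drop = FALSE]
  fo <- pois[pois$is_food_outlet, , drop = FALSE]
  n <- nrow(loc)
  if (nrow(fo) == 0L) {
    if (method == "knn") abort("no food outlets: k-NN environment undefined.")
    return(tibble(phi = rep(NA_real_, n), n_fo = 0L, n_ffo = 0L))
  }
  if (method == "knn" && nrow(fo) < k)
    abort(sprintf("only %d food outlets but k = %d: k-NN environment undefined.",
                  nrow(fo), k))
  # deterministic tie-break for knn: pre-sort FO by poi_id so that equal
  # distances resolve to the smallest poi_id
  fo <- fo[order(fo$poi_id), , drop = FALSE]
  fx <- fo$x; fy <- fo$y; fffo <- fo$is_ffo
  out_phi <- numeric(n); out_nfo <- integer(n); out_nffo <- integer(n)
  r2 <- radius_m^2
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    cx <- loc$x[i0:i1]; cy <- loc$y[i0:i1]
    d2 <- outer(cx, fx, function(a, b) (a - b)^2) +
      outer(cy, fy, function(a, b) (a - b)^2)
    if (method == "radius") {
      inside <- d2 <= r2
      nfo <- rowSums(inside)
      nffo <- as.integer(inside %*% fffo)
      out_nfo[i0:i1] <- nfo
      out_nffo[i0:i1] <- nffo
      out_phi[i0:i1] <- ifelse(nfo > 0, nffo / nfo, NA_real_)
    } else {
      for (j in seq_len(i1 - i0 + 1L)) {
        # order() is stable, so equal distances keep ascending poi_id order
        nn <- order(d2[j, ])[seq_len(k)]
        nffo <- sum(fffo[nn])
        out_nfo[i0 + j - 1L] <- k
        out_nffo[i0 + j - 1L] <- nffo
        out_phi[i0 + j - 1L] <- nffo / k
      }
    }
  }
  tibble(phi = out_phi, n_fo = out_nfo, n_ffo = out_nffo)
}

# Environment stats with de-duplication of repeated query locations.
env_stats_dedup <- function(locations, pois, method, radius_m, k) {
  loc <- as.data.frame(locations)[, c("x", "y")]
  key <- paste(loc$x, loc$y, sep = "\r")
  uk <- !duplicated(key)
  st <- env_stats(loc[uk, , drop = FALSE], pois, method = method,
                  radius_m = radius_m, k = k)
  st[match(key, key[uk]), , drop = FALSE]
}

#' Food-environment ratio within a radius
#'
#' Computes \eqn{\phi(x)}, the ratio of fast-food outlets to all food outlets
#' with Euclidean distance at most \code{radius_m} from each query location.
#' Outlets at exactly the radius count as inside. Locations with no food
#' outlet in range get \code{NA} (undefined environment).
#'
#' @param locations Data frame (or matrix) with columns \code{x}, \code{y}
#'   in meters; one row per query point.
#' @param pois POI table with columns \code{poi_id}, \code{x}, \code{y},
#'   \code{is_food_outlet}, \code{is_ffo}.
#' @param radius_m Environment radius in meters (default 1000).
#' @return Numeric vector of ratios in \eqn{[0,1]}, \code{NA} where no food
#'   outlet lies within the radius.
#' @examples
#' pois <- tibble::tibble(poi_id = 1:4, x = c(0, 100, 200, 5000), y = 0,
#'                        is_food_outlet = TRUE,
#'                        is_ffo = c(TRUE, FALSE, FALSE, FALSE))
#' environment_ratio_radius(data.frame(x = 0, y = 0), pois, 1000)
#' @export
environment_ratio_radius <- function(locations, pois, radius_m = 1000) {
  if (radius_m <= 0) abort("`radius_m` must be positive.")
  env_stats(locations, pois, method = "radius", radius_m = radius_m)$phi
}

#' Food-environment ratio among the k nearest food outlets
#'
#' Density-adjusted variant of \eqn{\phi(x)}: the share of fast-food outlets
#' among the \code{k} food outlets closest to each query location. Distance
#' ties are broken by ascending \code{poi_id} so results are deterministic.
#'
#' @inheritParams environment_ratio_radius
#' @param k Number of nearest food outlets (default 25). An error is raised
#'   if fewer than \code{k} food outlets exist.
#' @return Numeric vector of ratios in \eqn{[0,1]}.
#' @export
environment_ratio_knn <- function(locations, pois, k = 25L) {
  env_stats(locations, pois, method = "knn", k = as.integer(k))$phi
}

# phi under the config's chosen environment definition, deduplicated.
config_env <- function(locations, pois, cfg) {
  env_stats_dedup(locations, pois, method = cfg$env_method,
                  radius_m = cfg$env_radius_m, k = cfg$env_knn)
}
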