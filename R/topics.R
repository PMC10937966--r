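# Topic profiling of areas. Latent Dirichlet allocation on the per-area
# POI-category count matrix describes each area as a mixture of venue
# "topics" (mall-like, office-like, ...), used to characterise the kinds
# of places an intervention strategy targets.

#' Fit an LDA topic model on area POI composition
#'
#' Runs collapsed-Gibbs latent Dirichlet allocation on the area-by-category
#' POI count matrix with symmetric Dirichlet priors \code{1/n_topics} and a
#' fixed seed. Per-area topic proportions sum to one.
#'
#' @param pois POI table with \code{area_id} and \code{category}.
#' @param n_topics Number of topics (default 20).
#' @param n_iter Gibbs sweeps (default 500).
#' @param seed Sampler seed (default 1).
#' @return An object of class \code{"poi_lda"} with \code{theta}
#'   (area x topic proportions), \code{terms} (topic x category
#'   proportions), and the area/category labels.
#' @export
fit_poi_topics <- function(pois, n_topics = 20L, n_iter = 500L, seed = 1L) {
  tab <- table(pois$area_id, pois$category)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab))
  rownames(counts) <- rownames(tab); colnames(counts) <- colnames(tab)
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (n_topics > ncol(counts))
    abort(sprintf("n_topics (%d) exceeds the number of POI categories (%d).",
                  n_topics, ncol(counts)))
  if (nrow(counts) < n_topics)
    abort(sprintf("only %d non-empty areas for %d topics.",
                  nrow(counts), n_topics))
  res <- lda_gibbs(counts, as.integer(n_topics),
                   alpha = 1 / n_topics, eta = 1 / n_topics,
                   n_iter = as.integer(n_iter), seed = as.integer(seed))
  theta <- res$theta
  rownames(theta) <- rownames(counts)
  colnames(theta) <- paste0("topic_", seq_len(n_topics))
  terms <- res$phi
  rownames(terms) <- colnames(theta)
  colnames(terms) <- colnames(counts)
  out <- list(theta = theta, terms = terms,
              area_ids = as.integer(rownames(counts)),
              categories = colnames(counts), n_topics = n_topics)
  class(out) <- "poi_lda"
  out
}

#' @export
print.poi_lda <- function(x, ...) {
  cat(sprintf("<poi_lda> %d topics over %d areas x %d categories\n",
              x$n_topics, nrow(x$theta), length(x$categories)))
  top <- apply(x$terms, 1, function(r) {
    paste(head(x$categories[order(-r)], 3), collapse = ", ")
  })
  for (t in seq_len(min(x$n_topics, 8)))
    cat(sprintf("  %s: %s\n", rownames(x$terms)[t], top[t]))
  invisible(x)
}

#' @export
tidy.poi_lda <- function(x, matrix = c("theta", "terms"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "theta") {
    as_tibble(x$theta) %>%
      mutate(area_id = x$area_ids) %>%
      tidyr::pivot_longer(-"area_id", names_to = "topic",
                          values_to = "proportion")
  } else {
    as_tibble(x$terms) %>%
      mutate(topic = rownames(x$terms)) %>%
      tidyr::pivot_longer(-"topic", names_to = "category",
                          values_to = "proportion")
  }
}

#' Topic enrichment of a set of selected areas
#'
#' For every topic, the mean topic weight in the selected areas divided by
#' the mean weight over all areas: values above one mark venue types
#' over-represented where the intervention would act.
#'
#' @param lda A [fit_poi_topics()] object, or a plain area-by-topic weight
#'   matrix with area ids as row names.
#' @param selected_area_ids Areas chosen by a strategy.
#' @return A tibble: \code{topic}, \code{selected_mean}, \code{overall_mean},
#'   \code{relative_frequency}.
#' @export
topic_enrichment <- function(lda, selected_area_ids) {
  if (is.matrix(lda)) {
    lda <- list(theta = lda, area_ids = as.integer(rownames(lda)))
    if (is.null(colnames(lda$theta)))
      colnames(lda$theta) <- paste0("topic_", seq_len(ncol(lda$theta)))
    class(lda) <- "poi_lda"
  }
  stopifnot(inherits(lda, "poi_lda"))
  sel <- lda$area_ids %in% selected_area_ids
  if (!any(sel)) abort("selection contains no areas with POIs.")
  sel_mean <- colMeans(lda$theta[sel, , drop = FALSE])
  all_mean <- colMeans(lda$theta)
  tibble(
    topic = colnames(lda$theta),
    selected_mean = unname(sel_mean),
    overall_mean = unname(all_mean),
    relative_frequency = unname(sel_mean / all_mean)
  )
}
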