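#' Tidy a PCA summary
#'
#' @param x A `graft_pca` object.
#' @param matrix Which table to return: `"scores"`, `"loadings"` (long, one
#'   row per feature x component) or `"top"` (the top positive/negative
#'   loadings per component).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy graft_pca
#' @export
tidy.graft_pca <- function(x, matrix = c("scores", "loadings", "top"), ...) {
  switch(match.arg(matrix),
    scores = tidyr::pivot_longer(x$scores, -"sample",
                                 names_to = "component",
                                 values_to = "score"),
    loadings = tidyr::pivot_longer(x$loadings, -"feature",
                                   names_to = "component",
                                   values_to = "loading"),
    top = x$top_loadings
  )
}

#' One-row summary of a PCA
#'
#' @param x A `graft_pca` object.
#' @param ... Unused.
#' @return A tibble with the sample/feature counts and the explained-variance
#'   fraction of each kept component.
#' @method glance graft_pca
#' @export
glance.graft_pca <- function(x, ...) {
  out <- tibble(n_samples = nrow(x$scores), n_features = nrow(x$loadings))
  for (j in seq_along(x$var_explained)) {
    out[[sprintf("var_pc%d", j)]] <- x$var_explained[[j]]
  }
  out
}

#' Tidy a metabolite clustering
#'
#' @param x A `graft_clusters` object.
#' @param ... Unused.
#' @return The assignment tibble (`metabolite`, `cluster`).
#' @method tidy graft_clusters
#' @export
tidy.graft_clusters <- function(x, ...) {
  x$assignments
}

#' One-row summary of a metabolite clustering
#'
#' @param x A `graft_clusters` object.
#' @param ... Unused.
#' @return A tibble with `k`, metabolite count, linkage and the size of the
#'   largest and smallest cluster.
#' @method glance graft_clusters
#' @export
glance.graft_clusters <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  tibble(k = x$k, n_metabolites = nrow(x$assignments),
         linkage = x$tree$method,
         largest_cluster = as.integer(max(sizes)),
         smallest_cluster = as.integer(min(sizes)))
}
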