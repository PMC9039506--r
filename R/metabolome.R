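#' Select the metabolite set for cluster analysis with the R/Z rule
#'
#' For every metabolite and every (graft combination, tissue) the
#' chilling/control intensity ratio of replicate-aggregated abundance is
#' recorded as `R` and its log2 as `Z`. A metabolite is retained for
#' clustering when its Z values across contrasts satisfy the selection rule:
#' the `"literal"` rule retains `Zmin > 2 or Zmax < -2` (every contrast at
#' least 4-fold in the same direction — unusually strict, but stated as
#' such); the `"lenient"` alternative retains `Zmax > 2 or Zmin < -2` (any
#' contrast at least 4-fold). Metabolites whose control intensity aggregates
#' to zero with `pseudocount = 0` have an undefined ratio and are excluded
#' with a message.
#'
#' @param intensity Long intensity tibble (`metabolite`, design columns,
#'   `intensity`).
#' @param rule `"literal"` (default) or `"lenient"`.
#' @param pseudocount Added to both condition aggregates before the ratio
#'   (default 0: ratios on raw intensity).
#' @param aggregate Replicate aggregation, `"mean"` or `"median"`.
#' @param exclude Character vector of `scion/rootstock.tissue` group keys to
#'   drop before computing ratios (explicit exclusion list for contaminated
#'   sample groups, e.g. `"Cmo_Cmo.root"`).
#' @return A list with `retained` (character vector of metabolite ids),
#'   `fold_changes` (tibble `metabolite`, `scion`, `rootstock`, `tissue`,
#'   `R`, `Z`) and `excluded` (tibble of metabolites dropped for undefined
#'   ratios).
#' @export
select_cluster_set <- function(intensity, rule = c("literal", "lenient"),
                               pseudocount = 0,
                               aggregate = c("mean", "median"),
                               exclude = character()) {
  rule <- match.arg(rule)
  assert_columns(intensity, c("metabolite", "scion", "rootstock", "tissue",
                              "condition", "intensity"), "intensity")
  agg <- switch(match.arg(aggregate), mean = mean, median = median)
  if (any(intensity$intensity < 0)) abort("ion intensities must be >= 0")
  means <- intensity |>
    dplyr::mutate(group = sprintf("%s_%s.%s", .data$scion, .data$rootstock,
                                  .data$tissue)) |>
    dplyr::filter(!.data$group %in% exclude) |>
    dplyr::group_by(.data$metabolite, .data$scion, .data$rootstock,
                    .data$tissue, .data$condition) |>
    dplyr::summarise(value = agg(.data$intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value")
  assert_columns(means, c("control", "chilling"), "intensity contrasts")
  undefined <- means$control + pseudocount == 0
  excluded <- means |>
    dplyr::filter(.data$metabolite %in% unique(means$metabolite[undefined])) |>
    dplyr::distinct(.data$metabolite) |>
    dplyr::mutate(reason = "zero control intensity with pseudocount 0")
  if (nrow(excluded) > 0) {
    inform(sprintf("%d metabolite(s) excluded: undefined chilling/control ratio",
                   nrow(excluded)))
  }
  fc <- means |>
    dplyr::filter(!.data$metabolite %in% excluded$metabolite) |>
    dplyr::mutate(R = (.data$chilling + pseudocount) /
                    (.data$control + pseudocount),
                  Z = log2(.data$R)) |>
    dplyr::select("metabolite", "scion", "rootstock", "tissue", "R", "Z") |>
    dplyr::arrange(.data$metabolite, .data$scion, .data$rootstock,
                   .data$tissue)
  verdict <- fc |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(z_min = min(.data$Z), z_max = max(.data$Z),
                     .groups = "drop") |>
    dplyr::mutate(retained = if (rule == "literal") {
      .data$z_min > 2 | .data$z_max < -2
    } else {
      .data$z_max > 2 | .data$z_min < -2
    })
  list(retained = verdict$metabolite[verdict$retained],
       fold_changes = fc, excluded = excluded)
}

#' Min-max normalization
#'
#' Rescales a vector of intensities onto \[0, 1\] as
#' `x_star = (x - min) / (max - min)`, so the extremes map exactly to 0 and
#' 1 and order is preserved.
#'
#' @param x Numeric vector with `max(x) > min(x)`.
#' @return A tibble `x`, `x_star`, `min`, `max` (one row per input value, in
#'   input order).
#' @examples
#' minmax_normalize(c(1, 3, 5))$x_star
#' @export
minmax_normalize <- function(x) {
  if (length(x) < 2 || any(!is.finite(x))) {
    abort("min-max normalization needs >= 2 finite values")
  }
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) {
    abort("constant vector: min-max denominator (max - min) is zero")
  }
  tibble(x = x, x_star = (x - lo) / (hi - lo), min = lo, max = hi)
}

#' Hierarchically cluster metabolite fold-change profiles
#'
#' Agglomerative clustering of per-metabolite log2 fold-change profiles with
#' Euclidean distance and average linkage (fixed here for reproducibility),
#' cutting the tree into `k` clusters. Duplicate profiles always share a
#' label, and relabelling under row permutation is the only non-identity
#' freedom.
#'
#' @param profiles A tibble whose first column is the metabolite id and
#'   whose remaining numeric columns are the fold-change coordinates, or a
#'   numeric matrix with rownames.
#' @param k Number of clusters (default 8); must not exceed the number of
#'   metabolites.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `graft_clusters`: list with `assignments`
#'   (tibble `metabolite`, `cluster`), `tree` (the hclust object), `k` and
#'   `data`.
#' @export
cluster_metabolites <- function(profiles, k = 8, linkage = "average") {
  m <- as_profile_matrix(profiles)
  if (any(!is.finite(m))) abort("fold-change matrix must be finite")
  if (k > nrow(m)) {
    abort(sprintf("k = %d exceeds the %d metabolites available", k, nrow(m)))
  }
  tree <- hclust(dist(m, method = "euclidean"), method = linkage)
  assignment <- cutree(tree, k = k)
  structure(
    list(
      assignments = tibble(metabolite = rownames(m),
                           cluster = unname(assignment)),
      tree = tree, k = as.integer(k), data = m
    ),
    class = "graft_clusters"
  )
}

as_profile_matrix <- function(profiles) {
  if (is.matrix(profiles)) {
    if (is.null(rownames(profiles))) {
      rownames(profiles) <- sprintf("row%04d", seq_len(nrow(profiles)))
    }
    return(profiles)
  }
  stopifnot(is.data.frame(profiles), ncol(profiles) >= 2)
  m <- as.matrix(profiles[-1])
  if (!is.numeric(m)) abort("profile columns after the id must be numeric")
  rownames(m) <- as.character(profiles[[1]])
  m
}

#' @export
print.graft_clusters <- function(x, ...) {
  cat(sprintf("<graft_clusters> %d metabolites in %d clusters (%s linkage)\n",
              nrow(x$assignments), x$k, x$tree$method))
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Principal component summary of a sample-by-feature matrix
#'
#' Column-centred (unscaled) PCA with a fixed sign convention — each
#' component is oriented so its largest-magnitude loading is positive — plus
#' the explained-variance fractions and the `top_k` most positive and most
#' negative loadings per component, the summary used to read which features
#' drive the separation of samples.
#'
#' @param x Samples-by-features input: a numeric matrix with rownames, or a
#'   data frame whose first column is the sample id.
#' @param n_components Number of components to keep.
#' @param top_k Loadings to report per direction per component (truncated
#'   with a warning when the feature count is smaller).
#' @return An object of class `graft_pca`: list with `scores` (tibble),
#'   `loadings` (tibble), `var_explained` (fractions, non-increasing),
#'   `top_loadings` (tibble `component`, `direction`, `feature`, `loading`).
#' @export
pca_summary <- function(x, n_components = 2, top_k = 10) {
  m <- as_profile_matrix(x)
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("PCA needs at least 2 samples and 2 features")
  }
  if (all(apply(m, 2, function(col) length(unique(col)) == 1))) {
    abort("matrix has rank 0 after centring: no variance to decompose")
  }
  n_components <- min(n_components, nrow(m) - 1L, ncol(m))
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  keep <- seq_len(n_components)
  scores <- fit$x[, keep, drop = FALSE]
  loadings <- fit$rotation[, keep, drop = FALSE]
  for (j in keep) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  var_explained <- fit$sdev^2 / sum(fit$sdev^2)
  if (top_k > ncol(m)) {
    warn(sprintf("top_k = %d exceeds the %d features; truncating", top_k,
                 ncol(m)))
    top_k <- ncol(m)
  }
  top <- purrr::map_dfr(keep, function(j) {
    ord <- order(loadings[, j])
    dplyr::bind_rows(
      tibble(component = colnames(loadings)[j], direction = "positive",
             feature = rownames(loadings)[rev(utils::tail(ord, top_k))],
             loading = loadings[rev(utils::tail(ord, top_k)), j]),
      tibble(component = colnames(loadings)[j], direction = "negative",
             feature = rownames(loadings)[utils::head(ord, top_k)],
             loading = loadings[utils::head(ord, top_k), j])
    )
  })
  structure(
    list(
      scores = dplyr::bind_cols(tibble(sample = rownames(m)),
                                as_tibble(scores)),
      loadings = dplyr::bind_cols(tibble(feature = colnames(m)),
                                  as_tibble(loadings)),
      var_explained = var_explained[keep],
      top_loadings = top
    ),
    class = "graft_pca"
  )
}

#' @export
print.graft_pca <- function(x, ...) {
  cat(sprintf("<graft_pca> %d samples, %d components\n", nrow(x$scores),
              length(x$var_explained)))
  cat("variance explained:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
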