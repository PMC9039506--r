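#' Compute FPKM from fragment counts
#'
#' Fragments per kilobase of transcript per million mapped reads:
#' `fpkm = count * 1e9 / (total * length)`, with `total` the per-sample
#' mapped-fragment total (computed from the table itself when not supplied).
#'
#' @param counts Long tibble with `feature`, `sample_id` and `count`.
#' @param lengths Tibble with `feature` and `length` (bases, > 0).
#' @param totals Optional tibble with `sample_id` and `total` (> 0); defaults
#'   to the column sums of `counts`.
#' @return The input with an `fpkm` column appended.
#' @examples
#' compute_fpkm(
#'   tibble::tibble(feature = "g1", sample_id = "s1", count = 10),
#'   lengths = tibble::tibble(feature = "g1", length = 1000),
#'   totals = tibble::tibble(sample_id = "s1", total = 1e6)
#' )
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  assert_columns(counts, c("feature", "sample_id", "count"), "counts")
  assert_columns(lengths, c("feature", "length"), "lengths")
  if (any(lengths$length <= 0)) abort("feature lengths must be > 0")
  if (is.null(totals)) {
    totals <- counts |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::summarise(total = sum(.data$count), .groups = "drop")
  }
  assert_columns(totals, c("sample_id", "total"), "totals")
  if (any(totals$total <= 0)) {
    abort(sprintf("per-sample totals must be > 0 (offending sample: %s)",
                  totals$sample_id[which(totals$total <= 0)[1]]))
  }
  counts |>
    dplyr::left_join(lengths, by = "feature") |>
    dplyr::left_join(totals, by = "sample_id") |>
    dplyr::mutate(fpkm = .data$count * 1e9 / (.data$total * .data$length)) |>
    dplyr::select(-"length", -"total")
}

# replicate aggregation then log2 with pseudocount; the single Delta engine
delta_contrast <- function(het, homo, pseudocount = 1,
                           aggregate = c("mean", "median"),
                           log_space = TRUE) {
  agg <- switch(match.arg(aggregate), mean = mean, median = median)
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  if (pseudocount == 0 && (agg(het) == 0 || agg(homo) == 0) && log_space) {
    abort("all-zero group with pseudocount 0: log2 contrast undefined")
  }
  if (log_space) {
    log2(agg(het) + pseudocount) - log2(agg(homo) + pseudocount)
  } else {
    agg(het) - agg(homo)
  }
}

#' The delta2 - delta1 difference-of-differences statistic
#'
#' The differential rule of the heterografting design: delta1 is the
#' heterograft-minus-homograft log2 contrast of replicate-aggregated
#' abundance under the control condition, delta2 the same contrast under
#' chilling, and the statistic delta2 - delta1 measures how much the
#' heterograft-specific difference changes with chilling. Features with
#' statistic > `threshold` are called `up`, below `-threshold` `down`,
#' otherwise `none`; at the default threshold of 2 the calls correspond to a
#' 4-fold change in the ratio of ratios.
#'
#' @param het_control,homo_control,het_chilling,homo_chilling Replicate
#'   abundance vectors (FPKM or ion intensity) of the four sample groups.
#' @param pseudocount Added before taking logs (default 1); guards zeros.
#' @param aggregate Replicate aggregation, `"mean"` (default) or `"median"`.
#' @param log_space Compute contrasts as log2 differences of aggregated
#'   abundances (default). `FALSE` subtracts raw aggregates instead, in which
#'   case the threshold applies to raw abundance differences; provided for
#'   sensitivity checks only.
#' @param threshold Call cutoff on the statistic (log2 units).
#' @return A one-row tibble `delta1`, `delta2`, `statistic`, `call`.
#' @examples
#' delta_statistic(c(8, 8), c(1, 1), c(16, 16), c(1, 1), pseudocount = 0)
#' @export
delta_statistic <- function(het_control, homo_control, het_chilling,
                            homo_chilling, pseudocount = 1,
                            aggregate = c("mean", "median"),
                            log_space = TRUE, threshold = 2) {
  d1 <- delta_contrast(het_control, homo_control, pseudocount, aggregate,
                       log_space)
  d2 <- delta_contrast(het_chilling, homo_chilling, pseudocount, aggregate,
                       log_space)
  s <- d2 - d1
  tibble(delta1 = d1, delta2 = d2, statistic = s,
         call = delta_call(s, threshold))
}

delta_call <- function(statistic, threshold) {
  dplyr::case_when(statistic > threshold ~ "up",
                   statistic < -threshold ~ "down",
                   TRUE ~ "none")
}

# shared per-feature delta table for one heterograft-vs-homograft contrast
delta_feature_table <- function(df, id_col, value_col, scion, rootstock,
                                tissue, threshold, pseudocount, aggregate,
                                log_space) {
  assert_columns(df, c(id_col, "scion", "rootstock", "tissue", "condition",
                       "replicate", value_col), "df")
  if (scion == rootstock) {
    abort("the contrast graft must be a heterograft (scion != rootstock)")
  }
  res <- resident_species(scion, rootstock, tissue)
  groups <- tidyr::expand_grid(condition = CONDITIONS,
                               graft = c("het", "homo")) |>
    dplyr::mutate(scion = ifelse(.data$graft == "het", scion, res),
                  rootstock = ifelse(.data$graft == "het", rootstock, res))
  sub <- df |>
    dplyr::filter(.data$tissue == !!tissue) |>
    dplyr::inner_join(groups, by = c("scion", "rootstock", "condition"))
  present <- dplyr::distinct(sub, .data$condition, .data$graft)
  missing <- dplyr::anti_join(groups, present, by = c("condition", "graft"))
  if (nrow(missing) > 0) {
    m <- missing[1, ]
    abort(sprintf("missing sample group: %s %s/%s %s",
                  m$condition, m$scion, m$rootstock, tissue))
  }
  sub |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::summarise(
      delta1 = delta_contrast(.data[[value_col]][.data$graft == "het" &
                                                   .data$condition == "control"],
                              .data[[value_col]][.data$graft == "homo" &
                                                   .data$condition == "control"],
                              pseudocount, aggregate, log_space),
      delta2 = delta_contrast(.data[[value_col]][.data$graft == "het" &
                                                   .data$condition == "chilling"],
                              .data[[value_col]][.data$graft == "homo" &
                                                   .data$condition == "chilling"],
                              pseudocount, aggregate, log_space),
      .groups = "drop"
    ) |>
    dplyr::mutate(statistic = .data$delta2 - .data$delta1,
                  call = delta_call(.data$statistic, threshold),
                  scion = scion, rootstock = rootstock, tissue = tissue)
}

#' Call differentially expressed genes for one species and tissue
#'
#' Applies [delta_statistic()] to every gene of `species` in `tissue`,
#' contrasting the heterograft in which that species occupies the tissue
#' (e.g. Csa leaf: Csa/Cmo vs Csa/Csa; Csa root: Cmo/Csa vs Csa/Csa) against
#' its homograft, under both conditions. The DEG rule is the pure
#' ±`threshold` cutoff on delta2 - delta1; no p-value layer is added because
#' none is part of the rule.
#'
#' @param expr Long expression tibble with `gene`, `scion`, `rootstock`,
#'   `tissue`, `condition`, `replicate` and `fpkm` columns (the `expression`
#'   element of [make_expression_tables()]).
#' @param species,tissue The gene set and tissue to contrast.
#' @param threshold,pseudocount,aggregate,log_space See [delta_statistic()].
#' @return A tibble `gene`, `species`, `tissue`, `delta1`, `delta2`,
#'   `statistic`, `call`.
#' @export
call_degs <- function(expr, species, tissue, threshold = 2, pseudocount = 1,
                      aggregate = c("mean", "median"), log_space = TRUE) {
  stopifnot(species %in% SPECIES, tissue %in% TISSUES)
  other <- other_species(species)
  scion <- if (tissue == "leaf") species else other
  rootstock <- if (tissue == "leaf") other else species
  delta_feature_table(expr, "gene", "fpkm", scion, rootstock, tissue,
                      threshold, pseudocount, aggregate, log_space) |>
    dplyr::mutate(species = species) |>
    dplyr::select("gene", "species", "tissue", "delta1", "delta2",
                  "statistic", "call")
}

#' Call differentially intense metabolites for one heterograft and tissue
#'
#' The metabolite twin of [call_degs()]: the identical delta2 - delta1 code
#' path applied to replicate ion intensities, contrasting the named
#' heterograft combination against the homograft of the tissue's resident
#' species.
#'
#' @param intensity Long intensity tibble with `metabolite`, design columns
#'   and `intensity` (the `intensity` element of
#'   [make_metabolite_tables()]).
#' @param scion,rootstock The heterograft combination to contrast.
#' @param tissue Tissue of the contrast.
#' @param threshold,pseudocount,aggregate,log_space See [delta_statistic()].
#' @return A tibble `metabolite`, `scion`, `rootstock`, `tissue`, `delta1`,
#'   `delta2`, `statistic`, `call`.
#' @export
call_dims <- function(intensity, scion, rootstock, tissue, threshold = 2,
                      pseudocount = 1, aggregate = c("mean", "median"),
                      log_space = TRUE) {
  stopifnot(scion %in% SPECIES, rootstock %in% SPECIES, tissue %in% TISSUES)
  delta_feature_table(intensity, "metabolite", "intensity", scion, rootstock,
                      tissue, threshold, pseudocount, aggregate, log_space) |>
    dplyr::select("metabolite", "scion", "rootstock", "tissue", "delta1",
                  "delta2", "statistic", "call")
}

#' Per-contrast heterograft log2 fold-change profiles
#'
#' Computes, for every feature, the heterograft-vs-homograft log2 fold
#' change (replicate-aggregated, pseudocount-guarded) for each available
#' (heterograft combination, tissue, condition) contrast. These profile
#' vectors are the coordinates on which transcript-metabolite correlations
#' are computed: a species' genes contribute the four contrasts of the
#' tissues that species occupies, metabolites all eight.
#'
#' @param df Long feature table (`expression` or `intensity` layout).
#' @param id_col,value_col Feature id and abundance column names.
#' @param pseudocount,aggregate See [delta_statistic()].
#' @return A tibble `feature` (named as `id_col`), `scion`, `rootstock`,
#'   `tissue`, `condition`, `log2fc`.
#' @export
log2fc_profiles <- function(df, id_col = "gene", value_col = "fpkm",
                            pseudocount = 1, aggregate = c("mean", "median")) {
  assert_columns(df, c(id_col, "scion", "rootstock", "tissue", "condition",
                       "replicate", value_col), "df")
  agg <- switch(match.arg(aggregate), mean = mean, median = median)
  means <- df |>
    dplyr::group_by(.data[[id_col]], .data$scion, .data$rootstock,
                    .data$tissue, .data$condition) |>
    dplyr::summarise(value = agg(.data[[value_col]]), .groups = "drop")
  het <- means |>
    dplyr::filter(.data$scion != .data$rootstock) |>
    dplyr::mutate(resident = resident_species(.data$scion, .data$rootstock,
                                              .data$tissue))
  homo <- means |>
    dplyr::filter(.data$scion == .data$rootstock) |>
    dplyr::select(dplyr::all_of(id_col), resident = "scion", "tissue",
                  "condition", homo_value = "value")
  het |>
    dplyr::inner_join(homo, by = c(id_col, "resident", "tissue",
                                   "condition")) |>
    dplyr::mutate(log2fc = log2(.data$value + pseudocount) -
                    log2(.data$homo_value + pseudocount)) |>
    dplyr::select(dplyr::all_of(id_col), "scion", "rootstock", "tissue",
                  "condition", "log2fc") |>
    dplyr::arrange(.data[[id_col]], .data$scion, .data$rootstock,
                   .data$tissue, .data$condition)
}
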