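#' Best-hit orthology between two transcript sets
#'
#' Scores every cross-species sequence pair by global (Needleman-Wunsch)
#' alignment with match +1, mismatch -1 and gap -2, keeps the best-scoring
#' species-B hit per species-A sequence, and then resolves duplicates by
#' retaining only the highest-scoring pair per B id (ties broken by the
#' lexicographically smallest A id), so the final map is one-to-one.
#'
#' @param seqs_a,seqs_b Tibbles with `transcript` and `sequence` columns (or
#'   the `id_a/seq_a`, `id_b/seq_b` halves of a reference table; see
#'   [reference_seqs()]). Empty sequences are skipped with a message.
#' @return A tibble `id_a`, `id_b`, `score`, sorted by `id_a`.
#' @export
best_hit_orthology <- function(seqs_a, seqs_b) {
  assert_columns(seqs_a, c("transcript", "sequence"), "seqs_a")
  assert_columns(seqs_b, c("transcript", "sequence"), "seqs_b")
  drop_a <- nchar(seqs_a$sequence) == 0
  drop_b <- nchar(seqs_b$sequence) == 0
  if (any(drop_a) || any(drop_b)) {
    inform(sprintf("skipping %d empty sequence(s)", sum(drop_a) + sum(drop_b)))
    seqs_a <- seqs_a[!drop_a, ]
    seqs_b <- seqs_b[!drop_b, ]
  }
  if (nrow(seqs_a) == 0 || nrow(seqs_b) == 0) {
    abort("both sequence sets must be non-empty")
  }
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  b_set <- Biostrings::DNAStringSet(setNames(seqs_b$sequence,
                                             seqs_b$transcript))
  best <- purrr::map_dfr(seq_len(nrow(seqs_a)), function(i) {
    scores <- Biostrings::pairwiseAlignment(
      pattern = b_set, subject = Biostrings::DNAString(seqs_a$sequence[[i]]),
      type = "global", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2, scoreOnly = TRUE
    )
    ord <- order(-scores, seqs_b$transcript)
    tibble(id_a = seqs_a$transcript[[i]],
           id_b = seqs_b$transcript[[ord[1]]],
           score = scores[[ord[1]]])
  })
  best |>
    dplyr::arrange(.data$id_b, dplyr::desc(.data$score), .data$id_a) |>
    dplyr::distinct(.data$id_b, .keep_all = TRUE) |>
    dplyr::select("id_a", "id_b", "score") |>
    dplyr::arrange(.data$id_a)
}

#' Extract one species' transcript sequences from a reference table
#'
#' @param refs Homolog reference table from [make_homolog_references()].
#' @param species Which species' transcripts to extract.
#' @return A tibble `transcript`, `sequence`.
#' @export
reference_seqs <- function(refs, species) {
  tx <- reference_transcripts(refs)
  dplyr::select(dplyr::filter(tx, .data$species == !!species),
                "transcript", "sequence")
}

#' Correlate gene and metabolite fold-change profiles
#'
#' Pearson correlation between every gene's and every metabolite's
#' heterograft log2 fold-change profile (from [log2fc_profiles()]), computed
#' over the contrast keys the two share. Pairs sharing fewer than
#' `min_points` contrasts are not evaluated; pairs where either profile has
#' zero variance over the shared contrasts are skipped with a message; edges
#' are emitted where `|cor| >= threshold`.
#'
#' @param gene_fc,metabolite_fc Fold-change profile tibbles with id column
#'   (`gene` / `metabolite`), contrast keys (`scion`, `rootstock`, `tissue`,
#'   `condition`) and `log2fc`.
#' @param min_points Minimum shared contrasts per pair (default 4).
#' @param threshold Absolute-correlation cutoff for an edge (default 0.95).
#' @return A tibble `gene`, `metabolite`, `n` (shared contrasts), `cor`,
#'   `sign` (+1/-1), sorted by ids.
#' @export
correlate_deg_dim <- function(gene_fc, metabolite_fc, min_points = 4,
                              threshold = 0.95) {
  keys <- c("scion", "rootstock", "tissue", "condition")
  assert_columns(gene_fc, c("gene", keys, "log2fc"), "gene_fc")
  assert_columns(metabolite_fc, c("metabolite", keys, "log2fc"),
                 "metabolite_fc")
  key_of <- function(df) do.call(paste, c(df[keys], sep = "|"))
  g <- gene_fc |>
    dplyr::mutate(key = key_of(gene_fc)) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "gene",
                       values_from = "log2fc")
  m <- metabolite_fc |>
    dplyr::mutate(key = key_of(metabolite_fc)) |>
    tidyr::pivot_wider(id_cols = "key", names_from = "metabolite",
                       values_from = "log2fc")
  all_keys <- union(g$key, m$key)
  gm <- as.matrix(g[match(all_keys, g$key), -1, drop = FALSE])
  mm <- as.matrix(m[match(all_keys, m$key), -1, drop = FALSE])
  n_shared <- crossprod(!is.na(gm), !is.na(mm))
  cors <- suppressWarnings(cor(gm, mm, use = "pairwise.complete.obs"))
  # zero-variance profiles yield NA / NaN from cor(); count and skip them
  evaluable <- n_shared >= min_points
  skipped <- sum(evaluable & !is.finite(cors))
  if (skipped > 0) {
    inform(sprintf("%d pair(s) skipped: zero-variance profile over shared contrasts",
                   skipped))
  }
  hit <- which(evaluable & is.finite(cors) & abs(cors) >= threshold,
               arr.ind = TRUE)
  tibble(
    gene = rownames(cors)[hit[, 1]],
    metabolite = colnames(cors)[hit[, 2]],
    n = as.integer(n_shared[hit]),
    cor = cors[hit],
    sign = sign(cors[hit])
  ) |>
    dplyr::arrange(.data$gene, .data$metabolite)
}

#' Pathway over-representation by the hypergeometric test
#'
#' For each pathway, tests whether the feature set hits it more often than
#' expected from the background using the upper-tail hypergeometric
#' probability, with Benjamini-Hochberg adjustment across pathways. The
#' result is sorted by ascending p-value, so a genuinely enriched pathway
#' ranks first.
#'
#' @param features Character vector, the feature set of interest (must be a
#'   non-empty subset of `background`).
#' @param annotation Tibble `feature`, `pathway` (many-to-many).
#' @param background Character vector, the universe; defaults to all
#'   annotated features.
#' @return A tibble `pathway`, `set_hits`, `set_size`, `background_hits`,
#'   `background_size`, `p_value`, `p_adjust`, ascending by p-value.
#' @export
pathway_enrichment <- function(features, annotation,
                               background = unique(annotation$feature)) {
  assert_columns(annotation, c("feature", "pathway"), "annotation")
  features <- unique(features)
  background <- unique(background)
  if (length(features) == 0) abort("empty feature set: nothing to test")
  outside <- setdiff(features, background)
  if (length(outside) > 0) {
    abort(sprintf("feature(s) outside the background universe: %s",
                  paste(head(outside, 5), collapse = ", ")))
  }
  ann <- annotation |>
    dplyr::filter(.data$feature %in% background) |>
    dplyr::distinct(.data$feature, .data$pathway)
  n_bg <- length(background)
  n_set <- length(features)
  ann |>
    dplyr::group_by(.data$pathway) |>
    dplyr::summarise(
      background_hits = dplyr::n_distinct(.data$feature),
      set_hits = sum(unique(.data$feature) %in% features),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      set_size = n_set,
      background_size = n_bg,
      p_value = phyper(.data$set_hits - 1, .data$background_hits,
                       n_bg - .data$background_hits, n_set,
                       lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) |>
    dplyr::select("pathway", "set_hits", "set_size", "background_hits",
                  "background_size", "p_value", "p_adjust") |>
    dplyr::arrange(.data$p_value, .data$pathway)
}

#' Exact Venn region counts for up to four id sets
#'
#' Partitions the union of the sets into its exclusive membership regions
#' and counts each region, the tabulation behind the overlap analyses of
#' mobile-mRNA and DEG lists.
#'
#' @param sets A named list of at most 4 character vectors.
#' @return A tibble with one logical membership column per set plus `n`, one
#'   row per region (including empty regions), ordered by membership
#'   pattern.
#' @examples
#' venn_overlap(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
venn_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, length(sets) <= 4)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  if (anyDuplicated(names(sets)) > 0) abort("set names must be unique")
  sets <- purrr::map(sets, unique)
  universe <- unique(unlist(sets))
  membership <- purrr::map(sets, function(s) universe %in% s)
  regions <- rlang::exec(tidyr::expand_grid,
                         !!!purrr::map(sets, function(s) c(FALSE, TRUE)))
  regions <- regions[rowSums(as.matrix(regions)) > 0, ]
  pattern_of <- function(flags) paste(as.integer(flags), collapse = "")
  observed <- if (length(universe) == 0) character() else {
    apply(do.call(cbind, membership), 1, pattern_of)
  }
  regions$n <- vapply(seq_len(nrow(regions)), function(i) {
    sum(observed == pattern_of(unlist(regions[i, names(sets)])))
  }, integer(1L))
  as_tibble(regions)
}

#' Build the typed mobile-mRNA / DEG / DIM network
#'
#' Joins the three evidence layers into one edge list: a `mobile-deg` edge
#' links a mobile transcript to a differential gene when the gene is the
#' transcript's ortholog (or the transcript itself) and the two share at
#' least one pathway annotation; a `deg-dim` edge links a differential gene
#' to a differential metabolite through a correlation edge, carrying the
#' correlation sign. Correlation or orthology rows pointing at features
#' absent from the DEG/DIM/mobile tables are dropped, with the dropped count
#' reported.
#'
#' @param mobile Mobility calls (rows with `is_mobile = FALSE` are ignored)
#'   or any tibble with a `transcript` column of mobile ids.
#' @param degs DEG table from [call_degs()] (rows with `call != "none"` are
#'   the DEGs).
#' @param dims DIM table from [call_dims()] (same convention).
#' @param orthology Best-hit map from [best_hit_orthology()].
#' @param correlations Correlation edges from [correlate_deg_dim()].
#' @param annotation Pathway annotation tibble (`feature`, `pathway`).
#' @return A tibble `source`, `target`, `type`, `sign` (`NA` for
#'   `mobile-deg` edges), stably sorted.
#' @export
build_network <- function(mobile, degs, dims, orthology, correlations,
                          annotation) {
  assert_columns(mobile, "transcript", "mobile")
  assert_columns(degs, c("gene", "call"), "degs")
  assert_columns(dims, c("metabolite", "call"), "dims")
  assert_columns(orthology, c("id_a", "id_b"), "orthology")
  assert_columns(annotation, c("feature", "pathway"), "annotation")
  if ("is_mobile" %in% names(mobile)) {
    mobile <- dplyr::filter(mobile, .data$is_mobile)
  }
  mobile_ids <- unique(mobile$transcript)
  deg_ids <- unique(degs$gene[degs$call != "none"])
  dim_ids <- unique(dims$metabolite[dims$call != "none"])

  # orientation-agnostic ortholog lookup, plus identity (a DEG can be the
  # mobile transcript's own id when both tables live in one species)
  ortho <- dplyr::bind_rows(
    dplyr::select(orthology, transcript = "id_a", partner = "id_b"),
    dplyr::select(orthology, transcript = "id_b", partner = "id_a"),
    tibble(transcript = mobile_ids, partner = mobile_ids)
  ) |>
    dplyr::distinct()

  mobile_deg <- tibble(transcript = mobile_ids) |>
    dplyr::inner_join(ortho, by = "transcript",
                      relationship = "many-to-many") |>
    dplyr::filter(.data$partner %in% deg_ids) |>
    dplyr::inner_join(dplyr::rename(annotation, transcript = "feature"),
                      by = "transcript", relationship = "many-to-many") |>
    dplyr::inner_join(dplyr::rename(annotation, partner = "feature"),
                      by = c("partner", "pathway"),
                      relationship = "many-to-many") |>
    dplyr::distinct(source = .data$transcript, target = .data$partner) |>
    dplyr::mutate(type = "mobile-deg", sign = NA_real_)

  cor_edges <- correlations %||%
    tibble(gene = character(), metabolite = character(), sign = numeric())
  assert_columns(cor_edges, c("gene", "metabolite", "sign"), "correlations")
  keep <- cor_edges$gene %in% deg_ids & cor_edges$metabolite %in% dim_ids
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("%d correlation edge(s) dropped: endpoint not a DEG/DIM",
                   dropped))
  }
  deg_dim <- cor_edges[keep, ] |>
    dplyr::distinct(source = .data$gene, target = .data$metabolite,
                    .data$sign) |>
    dplyr::mutate(type = "deg-dim")

  dplyr::bind_rows(mobile_deg, deg_dim) |>
    dplyr::select("source", "target", "type", "sign") |>
    dplyr::arrange(.data$type, .data$source, .data$target)
}
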