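#' Generate homologous reference transcripts for two species
#'
#' Creates `n_pairs` random transcripts for species A (`Csa`) and derives the
#' species-B (`Cmo`) homolog of each by substituting bases at a per-base rate
#' of `divergence_rate` at uniformly chosen positions. No indels are
#' introduced, so position i of one homolog always faces position i of the
#' other and every differing position is a usable diagnostic site. Real
#' cucurbit homolog pairs are never sequence-identical; `min_substitutions`
#' (default 1) enforces the same property on the synthetic pairs.
#'
#' @param config A [sim_config()].
#' @param min_substitutions Minimum substitutions forced into each pair.
#' @param allow_zero_divergence Permit `divergence_rate = 0` (useful only for
#'   degenerate-input tests); otherwise a zero rate is an error because no
#'   diagnostic sites could exist.
#' @return A tibble with one row per homolog pair: `pair`, `species_a`,
#'   `id_a`, `seq_a`, `species_b`, `id_b`, `seq_b`.
#' @examples
#' refs <- make_homolog_references(sim_config(n_pairs = 3, seed = 1))
#' refs$id_a
#' @export
make_homolog_references <- function(config,
                                    min_substitutions = 1L,
                                    allow_zero_divergence = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$divergence_rate == 0 && !allow_zero_divergence) {
    abort(paste("divergence_rate is 0: homolog pairs would carry no",
                "diagnostic sites. Set allow_zero_divergence = TRUE only for",
                "degenerate-input checks."))
  }
  if (config$divergence_rate > 0 &&
      config$divergence_rate * config$transcript_length < 1) {
    abort("expected substitutions per pair (divergence_rate * transcript_length) must be >= 1")
  }
  L <- config$transcript_length
  withr::with_seed(config$seed, {
    purrr::map_dfr(seq_len(config$n_pairs), function(i) {
      seq_a <- paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
      n_sub <- max(min_substitutions, rbinom(1L, L, config$divergence_rate))
      chars <- strsplit(seq_a, "", fixed = TRUE)[[1]]
      if (n_sub > 0) {
        pos <- sample.int(L, n_sub)
        chars[pos] <- vapply(chars[pos], function(b) {
          sample(setdiff(DNA_BASES, b), 1L)
        }, character(1L))
      }
      tibble(
        pair = i,
        species_a = SPECIES[[1]], id_a = sprintf("%s_%04d", SPECIES[[1]], i),
        seq_a = seq_a,
        species_b = SPECIES[[2]], id_b = sprintf("%s_%04d", SPECIES[[2]], i),
        seq_b = paste(chars, collapse = "")
      )
    })
  })
}

# long view of the references: one row per transcript
reference_transcripts <- function(refs) {
  assert_columns(refs, c("pair", "species_a", "id_a", "seq_a",
                         "species_b", "id_b", "seq_b"), "refs")
  dplyr::bind_rows(
    tibble(pair = refs$pair, species = refs$species_a,
           transcript = refs$id_a, sequence = refs$seq_a),
    tibble(pair = refs$pair, species = refs$species_b,
           transcript = refs$id_b, sequence = refs$seq_b)
  )
}

#' Simulate per-sample sequencing reads for the whole grafting design
#'
#' Draws reads for every sample of the grafting design from the resident
#' species' transcripts (the scion's in the leaf, the rootstock's in the
#' root), then adds planted graft-mobile foreign reads in the heterograft
#' tissues named by `mobility_plan`. Per-transcript read counts are Poisson
#' with mean `config$depth`; start positions are uniform on the forward
#' strand; sequencing errors are independent per-base substitutions at
#' `config$error_rate`.
#'
#' `mobility_plan` rows plant mobile transcripts: columns `transcript` (an id
#' from `refs`, of the species foreign to the destination tissue), `scion`,
#' `rootstock`, `tissue`, `condition` and `reads` (foreign reads planted in
#' each replicate of that sample group). Naming a homograft destination, or a
#' transcript that is resident in the destination tissue, is an error: only
#' cross-species movement is biologically possible in this design.
#'
#' @param refs Homolog references from [make_homolog_references()].
#' @param config A [sim_config()].
#' @param mobility_plan Optional tibble of planted mobile transcripts.
#' @param design Sample sheet, by default [graft_design()] with
#'   `config$n_replicates` replicates.
#' @return A list with `reads` (tibble: sample metadata, `read_id`,
#'   `sequence`) and `truth` (list with `mobile`, the planted mobility table,
#'   and `read_counts`, per-sample resident/foreign read totals). The truth
#'   tables are never consumed by the pipeline; they exist for validation.
#' @export
simulate_graft_reads <- function(refs, config, mobility_plan = NULL,
                                 design = graft_design(config$n_replicates)) {
  stopifnot(inherits(config, "sim_config"))
  tx <- reference_transcripts(refs)
  plan <- validate_mobility_plan(mobility_plan, tx)
  rl <- config$read_length
  L <- config$transcript_length
  seq_of <- setNames(tx$sequence, tx$transcript)

  withr::with_seed(config$seed + 1L, {
    per_sample <- purrr::pmap(design, function(scion, rootstock, tissue,
                                               condition, replicate, resident,
                                               sample_id, ...) {
      res_tx <- tx[tx$species == resident, ]
      n_per_tx <- rpois(nrow(res_tx), config$depth)
      src <- rep(res_tx$transcript, n_per_tx)
      planted <- plan[plan$scion == scion & plan$rootstock == rootstock &
                        plan$tissue == tissue & plan$condition == condition, ]
      if (nrow(planted) > 0) {
        src <- c(src, rep(planted$transcript, planted$reads))
      }
      n <- length(src)
      if (n == 0) {
        return(tibble(sample_id = character(), read_id = character(),
                      sequence = character(),
                      .resident = integer(), .foreign = integer()))
      }
      starts <- sample.int(L - rl + 1L, n, replace = TRUE)
      seqs <- substr(seq_of[src], starts, starts + rl - 1L)
      seqs <- apply_sequencing_errors(seqs, config$error_rate)
      tibble(
        sample_id = sample_id,
        read_id = sprintf("%s:r%05d", sample_id, seq_len(n)),
        sequence = unname(seqs),
        .resident = sum(n_per_tx),
        .foreign = n - sum(n_per_tx)
      )
    })
  })
  reads <- dplyr::bind_rows(per_sample)
  read_counts <- reads |>
    dplyr::distinct(.data$sample_id, resident_reads = .data$.resident,
                    foreign_reads = .data$.foreign)
  reads <- reads |>
    dplyr::select(-".resident", -".foreign") |>
    dplyr::left_join(
      dplyr::select(design, "sample_id", "scion", "rootstock", "tissue",
                    "condition", "replicate"),
      by = "sample_id"
    ) |>
    dplyr::relocate("sample_id", "scion", "rootstock", "tissue", "condition",
                    "replicate")
  mobile_truth <- plan |>
    dplyr::distinct(.data$transcript, .data$origin, .data$scion,
                    .data$rootstock, .data$tissue, .data$condition)
  list(reads = reads,
       truth = list(mobile = mobile_truth, read_counts = read_counts))
}

validate_mobility_plan <- function(plan, tx) {
  if (is.null(plan) || nrow(plan) == 0) {
    return(tibble(transcript = character(), origin = character(),
                  scion = character(), rootstock = character(),
                  tissue = character(), condition = character(),
                  reads = integer()))
  }
  assert_columns(plan, c("transcript", "scion", "rootstock", "tissue",
                         "condition", "reads"), "mobility_plan")
  unknown <- setdiff(plan$transcript, tx$transcript)
  if (length(unknown) > 0) {
    abort(sprintf("mobility_plan names unknown transcript(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(plan$reads < 1)) abort("planted abundance must be >= 1 read")
  homo <- plan$scion == plan$rootstock
  if (any(homo)) {
    abort(sprintf(
      "mobility_plan plants foreign reads into homograft(s) %s: impossible in this design",
      paste(unique(sprintf("%s/%s", plan$scion[homo], plan$rootstock[homo])),
            collapse = ", ")))
  }
  plan <- dplyr::left_join(plan,
                           dplyr::select(tx, "transcript", origin = "species"),
                           by = "transcript")
  res <- resident_species(plan$scion, plan$rootstock, plan$tissue)
  native <- plan$origin == res
  if (any(native)) {
    abort(sprintf(
      "mobility_plan transcript(s) %s are resident in their destination tissue, not foreign",
      paste(unique(plan$transcript[native]), collapse = ", ")))
  }
  plan
}

apply_sequencing_errors <- function(seqs, error_rate) {
  if (error_rate == 0 || length(seqs) == 0) return(seqs)
  rl <- nchar(seqs[[1]])
  n_err <- rbinom(length(seqs), rl, error_rate)
  for (i in which(n_err > 0)) {
    pos <- sample.int(rl, n_err[[i]])
    for (p in pos) {
      old <- substr(seqs[[i]], p, p)
      substr(seqs[[i]], p, p) <- sample(setdiff(DNA_BASES, old), 1L)
    }
  }
  seqs
}

#' Generate FPKM expression tables with planted delta2 - delta1 effects
#'
#' Builds replicate-level FPKM values for one species' genes across every
#' sample of the design in which that species is present (its homograft plus
#' the heterograft tissues it occupies). Baseline abundances are lognormal;
#' replicate noise is multiplicative lognormal with standard deviation
#' `noise_sd` on the log2 scale. Planted heterograft effects are inserted in
#' pseudocount-adjusted log2 space, so a noiseless table round-trips exactly
#' through [delta_statistic()]: background genes have expected
#' delta2 - delta1 of 0 and a planted gene recovers its target effect.
#'
#' @param n_genes Number of background genes.
#' @param species Species whose transcriptome is tabulated (`"Csa"` or
#'   `"Cmo"`).
#' @param planted_effects Optional tibble `gene`, `tissue`, `effect`: target
#'   delta2 - delta1 in log2 units (chilling-contrast planting; the control
#'   contrast stays at 0).
#' @param planted_profiles Optional tibble `gene`, `tissue`, `condition`,
#'   `delta`: explicit per-condition heterograft-vs-homograft log2 contrasts,
#'   used to plant full fold-change profiles (e.g. for transcript-metabolite
#'   correlations).
#' @param n_replicates,noise_sd,pseudocount,seed Generator parameters;
#'   `pseudocount` must match the one later used in [delta_statistic()] for
#'   exact round-trips.
#' @param baseline_log_mean,baseline_log_sd Natural-log mean and sd of the
#'   lognormal baseline FPKM distribution.
#' @return A list with `expression` (long tibble: `gene`, design columns,
#'   `fpkm`) and `truth` (list with `deg`, the planted effect table with
#'   direction signs, and `profiles`, all planted contrasts).
#' @export
make_expression_tables <- function(n_genes = 200,
                                   species = "Csa",
                                   planted_effects = NULL,
                                   planted_profiles = NULL,
                                   n_replicates = 3,
                                   noise_sd = 0,
                                   pseudocount = 1,
                                   seed = 1,
                                   baseline_log_mean = log(30),
                                   baseline_log_sd = 0.8) {
  stopifnot(species %in% SPECIES)
  genes <- sprintf("%sG%04d", species, seq_len(n_genes))
  deltas <- collect_planted_deltas(planted_effects, planted_profiles, genes,
                                   id_col = "gene")
  design <- graft_design(n_replicates) |>
    dplyr::filter(.data$resident == species)
  tab <- simulate_feature_table(
    ids = genes, id_col = "gene", design = design, deltas = deltas,
    noise_sd = noise_sd, pseudocount = pseudocount, seed = seed,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    value_col = "fpkm"
  )
  deg_truth <- if (is.null(planted_effects)) {
    tibble(gene = character(), species = character(), tissue = character(),
           effect = numeric(), direction = character())
  } else {
    planted_effects |>
      dplyr::mutate(species = species,
                    direction = ifelse(.data$effect > 0, "up", "down")) |>
      dplyr::select("gene", "species", "tissue", "effect", "direction")
  }
  list(expression = tab, truth = list(deg = deg_truth, profiles = deltas))
}

#' Generate metabolite ion-intensity tables with planted DIMs and correlations
#'
#' Same generative model as [make_expression_tables()] but on the positive
#' ion-intensity scale and measured in every sample of the design (metabolites
#' are not species-specific). Two kinds of truth can be planted:
#' differentially intense metabolites (`planted_dims`: a target
#' delta2 - delta1 for one heterograft combination x tissue) and
#' transcript-metabolite correlations (`planted_correlations`: the
#' metabolite's heterograft log2 fold-change profile is forced to equal
#' plus/minus the named gene's planted profile across the contrasts the two
#' share, so their Pearson correlation is exactly +/-1 in the noiseless
#' table).
#'
#' @param n_metabolites Number of background metabolites.
#' @param planted_dims Optional tibble `metabolite`, `scion`, `rootstock`,
#'   `tissue`, `effect` (log2 delta2 - delta1 target for that heterograft).
#' @param planted_correlations Optional tibble `gene`, `metabolite`, `sign`
#'   (+1 or -1). Requires `gene_truth`.
#' @param gene_truth The `truth` element returned by
#'   [make_expression_tables()] for the correlated genes (its `profiles`
#'   table supplies the gene fold-change profiles to mirror).
#' @param gene_species Species of the correlated genes, used to map each gene
#'   contrast (tissue x condition) to its heterograft combination.
#' @param n_replicates,noise_sd,pseudocount,seed,baseline_log_mean,baseline_log_sd
#'   As in [make_expression_tables()]; intensities default to a lognormal
#'   around 1e5.
#' @return A list with `intensity` (long tibble: `metabolite`, design
#'   columns, `intensity`) and `truth` (list `dim`, `correlation`,
#'   `profiles`).
#' @export
make_metabolite_tables <- function(n_metabolites = 300,
                                   planted_dims = NULL,
                                   planted_correlations = NULL,
                                   gene_truth = NULL,
                                   gene_species = "Csa",
                                   n_replicates = 3,
                                   noise_sd = 0,
                                   pseudocount = 1,
                                   seed = 2,
                                   baseline_log_mean = log(1e5),
                                   baseline_log_sd = 1) {
  mets <- sprintf("M%04d", seq_len(n_metabolites))
  deltas <- tibble(metabolite = character(), scion = character(),
                   rootstock = character(), tissue = character(),
                   condition = character(), delta = numeric())
  if (!is.null(planted_dims) && nrow(planted_dims) > 0) {
    assert_columns(planted_dims,
                   c("metabolite", "scion", "rootstock", "tissue", "effect"),
                   "planted_dims")
    deltas <- dplyr::bind_rows(deltas, planted_dims |>
      dplyr::mutate(condition = "chilling", delta = .data$effect) |>
      dplyr::select("metabolite", "scion", "rootstock", "tissue",
                    "condition", "delta"))
  }
  cor_truth <- tibble(gene = character(), metabolite = character(),
                      sign = numeric())
  if (!is.null(planted_correlations) && nrow(planted_correlations) > 0) {
    assert_columns(planted_correlations, c("gene", "metabolite", "sign"),
                   "planted_correlations")
    if (is.null(gene_truth)) {
      abort("planted_correlations requires `gene_truth` from make_expression_tables()")
    }
    gp <- gene_truth$profiles
    mirrored <- planted_correlations |>
      dplyr::inner_join(gp, by = "gene", relationship = "many-to-many") |>
      dplyr::mutate(
        scion = ifelse(.data$tissue == "leaf", gene_species,
                       other_species(gene_species)),
        rootstock = ifelse(.data$tissue == "leaf",
                           other_species(gene_species), gene_species),
        delta = .data$sign * .data$delta
      ) |>
      dplyr::select("metabolite", "scion", "rootstock", "tissue",
                    "condition", "delta")
    deltas <- dplyr::bind_rows(deltas, mirrored)
    cor_truth <- planted_correlations
  }
  if (anyDuplicated(deltas[c("metabolite", "scion", "rootstock", "tissue",
                             "condition")]) > 0) {
    abort("conflicting planted contrasts for the same metabolite x heterograft x tissue x condition")
  }
  unknown <- setdiff(deltas$metabolite, mets)
  if (length(unknown) > 0) {
    abort(sprintf("planted metabolite(s) not generated: %s",
                  paste(unknown, collapse = ", ")))
  }
  tab <- simulate_feature_table(
    ids = mets, id_col = "metabolite", design = graft_design(n_replicates),
    deltas = deltas, noise_sd = noise_sd, pseudocount = pseudocount,
    seed = seed, baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd, value_col = "intensity"
  )
  dim_truth <- if (is.null(planted_dims)) {
    tibble(metabolite = character(), scion = character(),
           rootstock = character(), tissue = character(), effect = numeric(),
           direction = character())
  } else {
    planted_dims |>
      dplyr::mutate(direction = ifelse(.data$effect > 0, "up", "down"))
  }
  list(intensity = tab,
       truth = list(dim = dim_truth, correlation = cor_truth,
                    profiles = deltas))
}

# normalize planted_effects/planted_profiles into one delta table keyed by
# (id, tissue, condition); effects plant the chilling contrast only
collect_planted_deltas <- function(planted_effects, planted_profiles, ids,
                                   id_col) {
  out <- tibble(!!id_col := character(), tissue = character(),
                condition = character(), delta = numeric())
  if (!is.null(planted_effects) && nrow(planted_effects) > 0) {
    assert_columns(planted_effects, c(id_col, "tissue", "effect"),
                   "planted_effects")
    if (any(!is.finite(planted_effects$effect))) {
      abort("planted effects must be finite")
    }
    out <- dplyr::bind_rows(out, planted_effects |>
      dplyr::mutate(condition = "chilling", delta = .data$effect) |>
      dplyr::select(dplyr::all_of(id_col), "tissue", "condition", "delta"))
  }
  if (!is.null(planted_profiles) && nrow(planted_profiles) > 0) {
    assert_columns(planted_profiles, c(id_col, "tissue", "condition", "delta"),
                   "planted_profiles")
    if (any(!is.finite(planted_profiles$delta))) {
      abort("planted profile contrasts must be finite")
    }
    out <- dplyr::bind_rows(out, planted_profiles[c(id_col, "tissue",
                                                    "condition", "delta")])
  }
  if (anyDuplicated(out[c(id_col, "tissue", "condition")]) > 0) {
    abort("the same feature x tissue x condition contrast is planted twice")
  }
  unknown <- setdiff(out[[id_col]], ids)
  if (length(unknown) > 0) {
    abort(sprintf("planted feature(s) not generated: %s",
                  paste(unknown, collapse = ", ")))
  }
  out
}

# shared engine behind the expression and metabolite generators; `deltas`
# carries planted log2 heterograft-vs-homograft contrasts, either keyed by
# (id, tissue, condition) or additionally by (scion, rootstock)
simulate_feature_table <- function(ids, id_col, design, deltas, noise_sd,
                                   pseudocount, seed, baseline_log_mean,
                                   baseline_log_sd, value_col) {
  has_combo <- all(c("scion", "rootstock") %in% names(deltas))
  withr::with_seed(seed, {
    baseline <- exp(rnorm(length(ids), baseline_log_mean, baseline_log_sd))
    names(baseline) <- ids
    # floor baselines so down-planted group means stay strictly positive
    if (nrow(deltas) > 0) {
      floors <- deltas |>
        dplyr::group_by(.data[[id_col]]) |>
        dplyr::summarise(min_delta = min(c(.data$delta, 0)),
                         .groups = "drop")
      fl <- 2 * pseudocount * (2^(-floors$min_delta) - 1)
      baseline[floors[[id_col]]] <-
        pmax(baseline[floors[[id_col]]], fl + pseudocount)
    }
    grid <- tidyr::expand_grid(
      !!id_col := ids,
      dplyr::distinct(design, .data$scion, .data$rootstock, .data$tissue,
                      .data$condition, .data$heterograft)
    )
    join_keys <- c(id_col, "tissue", "condition",
                   if (has_combo) c("scion", "rootstock"))
    grid <- dplyr::left_join(grid, deltas, by = join_keys) |>
      dplyr::mutate(
        delta = dplyr::if_else(is.na(.data$delta) | !.data$heterograft,
                               0, .data$delta),
        base = baseline[.data[[id_col]]],
        group_mean = (.data$base + pseudocount) * 2^.data$delta - pseudocount
      )
    if (nrow(deltas) > 0) {
      stray <- dplyr::anti_join(deltas, dplyr::filter(grid, .data$heterograft),
                                by = join_keys)
      if (nrow(stray) > 0) {
        abort("planted contrasts name groups absent from the design (homografts or unknown tissues)")
      }
    }
    out <- dplyr::inner_join(
      grid, design,
      by = c("scion", "rootstock", "tissue", "condition", "heterograft"),
      relationship = "many-to-many"
    )
    noise <- if (noise_sd > 0) 2^rnorm(nrow(out), 0, noise_sd) else 1
    out |>
      dplyr::mutate(!!value_col := .data$group_mean * noise) |>
      dplyr::select(dplyr::all_of(id_col), "scion", "rootstock", "tissue",
                    "condition", "replicate", "sample_id",
                    dplyr::all_of(value_col)) |>
      dplyr::arrange(.data[[id_col]], .data$sample_id)
  })
}

#' Generate a feature-to-pathway annotation table
#'
#' Assigns each gene and metabolite to a Poisson-distributed number of random
#' pathways (many-to-many), optionally over-representing one or more pathways
#' in a designated feature set via `enriched_plan`, so that downstream
#' enrichment analysis has a planted positive. Duplicate (feature, pathway)
#' rows are collapsed with a warning.
#'
#' @param genes,metabolites Character vectors of feature ids to annotate.
#' @param n_pathways Number of pathway ids (`map00001` ...) to draw from.
#' @param enriched_plan Optional tibble `feature`, `pathway` of guaranteed
#'   annotations (the enrichment truth).
#' @param mean_pathways Poisson mean of background pathways per feature.
#' @param seed Integer seed.
#' @return A list with `annotation` (tibble `feature`, `pathway`) and `truth`
#'   (the enriched plan, possibly empty).
#' @export
make_pathway_annotation <- function(genes, metabolites = character(),
                                    n_pathways = 20, enriched_plan = NULL,
                                    mean_pathways = 1.5, seed = 3) {
  features <- c(genes, metabolites)
  pathways <- sprintf("map%05d", seq_len(n_pathways))
  withr::with_seed(seed, {
    n_each <- rpois(length(features), mean_pathways)
    ann <- tibble(
      feature = rep(features, n_each),
      pathway = unlist(purrr::map(n_each, function(k) {
        sample(pathways, min(k, n_pathways))
      }))
    )
  })
  truth <- tibble(feature = character(), pathway = character())
  if (!is.null(enriched_plan) && nrow(enriched_plan) > 0) {
    assert_columns(enriched_plan, c("feature", "pathway"), "enriched_plan")
    unknown <- setdiff(enriched_plan$feature, features)
    if (length(unknown) > 0) {
      abort(sprintf("enriched_plan names unknown feature(s): %s",
                    paste(unknown, collapse = ", ")))
    }
    ann <- dplyr::bind_rows(ann, enriched_plan[c("feature", "pathway")])
    truth <- as_tibble(enriched_plan[c("feature", "pathway")])
  }
  if (anyDuplicated(ann) > 0) {
    warn("duplicate (feature, pathway) annotation rows collapsed")
    ann <- dplyr::distinct(ann)
  }
  list(annotation = dplyr::arrange(ann, .data$feature, .data$pathway),
       truth = truth)
}
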