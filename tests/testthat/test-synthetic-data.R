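test_that("homolog references diverge at the configured rate and are reproducible", {
  cfg <- sim_config(n_pairs = 6, transcript_length = 300,
                    divergence_rate = 0.01, seed = 42)
  refs <- make_homolog_references(cfg)
  expect_equal(nrow(refs), 6)
  expect_true(all(nchar(refs$seq_a) == 300 & nchar(refs$seq_b) == 300))

  # differing positions equal the brute-force position-wise diff, and every
  # pair carries at least one diagnostic site
  n_diff <- vapply(seq_len(nrow(refs)), function(i) {
    nrow(oracle_diff_sites(refs$seq_a[i], refs$seq_b[i]))
  }, numeric(1))
  expect_true(all(n_diff >= 1))
  expect_equal(n_diff, vapply(seq_len(nrow(refs)), function(i) {
    oracle_hamming(refs$seq_a[i], refs$seq_b[i])
  }, numeric(1)))

  # determinism: same config, same seed, byte-identical output
  expect_identical(refs, make_homolog_references(cfg))
  # and a different seed gives different sequences
  cfg2 <- sim_config(n_pairs = 6, transcript_length = 300,
                     divergence_rate = 0.01, seed = 43)
  expect_false(identical(refs$seq_a, make_homolog_references(cfg2)$seq_a))
})

test_that("minimal divergence case plants exactly one substitution", {
  cfg <- sim_config(n_pairs = 1, transcript_length = 4,
                    divergence_rate = 0.25, read_length = 4, seed = 1)
  refs <- make_homolog_references(cfg)
  # binomial draw can exceed 1, but the forced minimum guarantees >= 1
  expect_gte(oracle_hamming(refs$seq_a, refs$seq_b), 1)
  cfg0 <- sim_config(n_pairs = 1, transcript_length = 4,
                     divergence_rate = 0, read_length = 4, seed = 1)
  expect_error(make_homolog_references(cfg0), "diagnostic sites")
  refs0 <- make_homolog_references(cfg0, min_substitutions = 1,
                                   allow_zero_divergence = TRUE)
  expect_equal(oracle_hamming(refs0$seq_a, refs0$seq_b), 1)
})

test_that("simulated reads conserve counts and respect the mobility plan", {
  fx <- tiny_refs(n_pairs = 4, depth = 5, seed = 3)
  # empty plan: every sample's reads all derive from the resident species
  sim <- simulate_graft_reads(fx$refs, fx$config)
  expect_equal(nrow(sim$truth$mobile), 0)
  expect_true(all(sim$truth$read_counts$foreign_reads == 0))
  expect_equal(nrow(sim$reads), sum(sim$truth$read_counts$resident_reads))
  expect_true(all(nchar(sim$reads$sequence) == fx$config$read_length))

  # planted foreign reads appear in exactly the planned sample group, 30
  # per replicate, drawn verbatim from the planted transcript (error_rate 0)
  plan <- tibble::tibble(transcript = "Csa_0002", scion = "Cmo",
                         rootstock = "Csa", tissue = "leaf",
                         condition = "chilling", reads = 30)
  sim2 <- simulate_graft_reads(fx$refs, fx$config, plan)
  counts <- dplyr::filter(sim2$truth$read_counts, foreign_reads > 0)
  expect_equal(nrow(counts), fx$config$n_replicates)
  expect_true(all(counts$foreign_reads == 30))
  expect_true(all(grepl("Cmo_Csa\\.leaf\\.chilling", counts$sample_id)))
  # conservation: per-sample read totals equal resident + foreign
  per_sample <- dplyr::count(sim2$reads, sample_id)
  joined <- dplyr::inner_join(per_sample, sim2$truth$read_counts,
                              by = "sample_id")
  expect_equal(joined$n, joined$resident_reads + joined$foreign_reads)
  # every read in the planned group that is a verbatim substring of the
  # planted Csa transcript but not of its Cmo homolog is a planted read
  target <- dplyr::filter(sim2$reads, scion == "Cmo", rootstock == "Csa",
                          tissue == "leaf", condition == "chilling",
                          replicate == 1)
  src <- fx$refs$seq_a[fx$refs$id_a == "Csa_0002"]
  hom <- fx$refs$seq_b[fx$refs$id_a == "Csa_0002"]
  from_planted <- vapply(target$sequence, grepl, logical(1), x = src,
                         fixed = TRUE) &
    !vapply(target$sequence, grepl, logical(1), x = hom, fixed = TRUE)
  expect_lte(sum(from_planted), 30)
  expect_gte(sum(from_planted), 1)

  # determinism of the full read set
  expect_identical(sim2$reads, simulate_graft_reads(fx$refs, fx$config, plan)$reads)
})

test_that("mobility plans naming impossible destinations error", {
  fx <- tiny_refs(seed = 4)
  homograft_plan <- tibble::tibble(transcript = "Csa_0001", scion = "Cmo",
                                   rootstock = "Cmo", tissue = "leaf",
                                   condition = "control", reads = 5)
  expect_error(simulate_graft_reads(fx$refs, fx$config, homograft_plan),
               "homograft")
  native_plan <- tibble::tibble(transcript = "Csa_0001", scion = "Csa",
                                rootstock = "Cmo", tissue = "leaf",
                                condition = "control", reads = 5)
  expect_error(simulate_graft_reads(fx$refs, fx$config, native_plan),
               "resident")
})

test_that("sequencing errors hit bases at the configured rate", {
  # identical seeds draw identical reads for the first sample; the only
  # difference is the per-base error process, so the mismatch fraction
  # between the two runs estimates the error rate
  clean <- tiny_refs(n_pairs = 20, transcript_length = 500, depth = 40,
                     error_rate = 0, seed = 9)
  noisy <- tiny_refs(n_pairs = 20, transcript_length = 500, depth = 40,
                     error_rate = 0.001, seed = 9)
  r0 <- simulate_graft_reads(clean$refs, clean$config)$reads
  r1 <- simulate_graft_reads(noisy$refs, noisy$config)$reads
  first <- r0$sample_id[[1]]
  a <- r0$sequence[r0$sample_id == first]
  b <- r1$sequence[r1$sample_id == first]
  expect_identical(length(a), length(b))
  mm <- vapply(seq_along(a), function(i) oracle_hamming(a[i], b[i]),
               numeric(1))
  n_bases <- length(a) * 150
  p_hat <- sum(mm) / n_bases
  se <- sqrt(0.001 * 0.999 / n_bases)
  expect_lt(abs(p_hat - 0.001), 3 * se)
})

test_that("expression generator round-trips planted effects and keeps background at zero", {
  effects <- tibble::tibble(gene = c("CsaG0001", "CsaG0002"),
                            tissue = c("leaf", "root"), effect = c(3, -3))
  ex <- make_expression_tables(n_genes = 50, planted_effects = effects,
                               noise_sd = 0, seed = 5)
  leaf <- call_degs(ex$expression, "Csa", "leaf")
  root <- call_degs(ex$expression, "Csa", "root")
  expect_equal(leaf$statistic[leaf$gene == "CsaG0001"], 3, tolerance = 1e-12)
  expect_equal(root$statistic[root$gene == "CsaG0002"], -3, tolerance = 1e-12)
  background <- dplyr::bind_rows(leaf, root) |>
    dplyr::anti_join(effects, by = c("gene", "tissue"))
  expect_equal(max(abs(background$statistic)), 0)
  expect_error(make_expression_tables(
    n_genes = 5, planted_effects = tibble::tibble(
      gene = "CsaG0001", tissue = "leaf", effect = Inf)), "finite")
})

test_that("background delta statistics under noise are centred on zero", {
  ex <- make_expression_tables(n_genes = 200, noise_sd = 0.2, seed = 8)
  degs <- call_degs(ex$expression, "Csa", "leaf")
  se <- stats::sd(degs$statistic) / sqrt(nrow(degs))
  expect_lt(abs(mean(degs$statistic)), 3 * se + 1e-9)
})

test_that("metabolite generator plants DIMs and perfect correlations", {
  profiles <- tidyr::expand_grid(gene = "CsaG0003",
                                 tissue = c("leaf", "root"),
                                 condition = c("control", "chilling")) |>
    dplyr::mutate(delta = c(1.5, 3, -1, 0.5))
  ex <- make_expression_tables(n_genes = 10, planted_profiles = profiles,
                               noise_sd = 0, seed = 6)
  met <- make_metabolite_tables(
    n_metabolites = 40,
    planted_dims = tibble::tibble(metabolite = "M0001", scion = "Csa",
                                  rootstock = "Cmo", tissue = "leaf",
                                  effect = -3),
    planted_correlations = tibble::tibble(gene = "CsaG0003",
                                          metabolite = c("M0002", "M0003"),
                                          sign = c(1, -1)),
    gene_truth = ex$truth, noise_sd = 0, seed = 7)
  dims <- call_dims(met$intensity, "Csa", "Cmo", "leaf")
  expect_equal(dims$statistic[dims$metabolite == "M0001"], -3,
               tolerance = 1e-12)
  expect_equal(dims$call[dims$metabolite == "M0001"], "down")

  gfc <- log2fc_profiles(ex$expression, "gene", "fpkm")
  mfc <- log2fc_profiles(met$intensity, "metabolite", "intensity")
  g <- dplyr::filter(gfc, gene == "CsaG0003")
  for (m_id in c("M0002", "M0003")) {
    m <- dplyr::filter(mfc, metabolite == m_id) |>
      dplyr::semi_join(g, by = c("scion", "rootstock", "tissue", "condition"))
    joined <- dplyr::inner_join(
      g, m, by = c("scion", "rootstock", "tissue", "condition"))
    expect_equal(abs(oracle_pearson(joined$log2fc.x, joined$log2fc.y)), 1,
                 tolerance = 1e-9)
  }
})

test_that("unplanted pairs rarely reach the correlation threshold under noise", {
  # two independent noisy tables sharing all 8 heterograft contrasts: with
  # >= 6 shared contrasts the null rate of |cor| >= 0.95 is well under 5%
  met_a <- make_metabolite_tables(n_metabolites = 40, noise_sd = 0.3,
                                  seed = 21)
  met_b <- make_metabolite_tables(n_metabolites = 40, noise_sd = 0.3,
                                  seed = 22)
  fc_a <- log2fc_profiles(met_a$intensity, "metabolite", "intensity") |>
    dplyr::rename(gene = metabolite)
  fc_b <- log2fc_profiles(met_b$intensity, "metabolite", "intensity")
  edges <- correlate_deg_dim(fc_a, fc_b, min_points = 6, threshold = 0.95)
  expect_true(all(edges$n == 8))
  expect_lt(nrow(edges) / (40 * 40), 0.05)
})

test_that("pathway annotation is deterministic, collapses duplicates and records the plan", {
  genes <- sprintf("G%02d", 1:20)
  plan <- tibble::tibble(feature = genes[1:5], pathway = "map00001")
  # planned rows can coincide with random background rows, which is the
  # documented collapse-with-warning path
  ann1 <- suppressWarnings(make_pathway_annotation(genes, n_pathways = 5,
                                                   enriched_plan = plan,
                                                   seed = 12))
  ann2 <- suppressWarnings(make_pathway_annotation(genes, n_pathways = 5,
                                                   enriched_plan = plan,
                                                   seed = 12))
  expect_identical(ann1$annotation, ann2$annotation)
  expect_identical(ann1$truth, plan)
  expect_equal(anyDuplicated(ann1$annotation), 0)
  dup_plan <- tibble::tibble(feature = c("G01", "G01"),
                             pathway = c("map00009", "map00009"))
  expect_warning(make_pathway_annotation(genes, n_pathways = 5,
                                         enriched_plan = dup_plan, seed = 12),
                 "collapsed")
})
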