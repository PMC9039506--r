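test_that("best-hit orthology recovers the generator's pair map", {
  fx <- tiny_refs(n_pairs = 8, transcript_length = 150,
                  divergence_rate = 0.03, read_length = 50, seed = 43)
  map <- best_hit_orthology(reference_seqs(fx$refs, "Csa"),
                            reference_seqs(fx$refs, "Cmo"))
  expect_equal(map$id_a, fx$refs$id_a)
  expect_equal(map$id_b, fx$refs$id_b)

  # an identical pair among unrelated sequences is matched
  withr::with_seed(44, {
    noise <- vapply(1:3, function(i) {
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    }, character(1))
  })
  a <- tibble::tibble(transcript = c("a1", "a2"),
                      sequence = c(noise[1], noise[2]))
  b <- tibble::tibble(transcript = c("b1", "b2"),
                      sequence = c(noise[1], noise[3]))
  map2 <- best_hit_orthology(a, b)
  expect_equal(map2$id_b[map2$id_a == "a1"], "b1")

  # two A ids best-hitting one B id: only the higher-scoring pair survives
  a3 <- tibble::tibble(
    transcript = c("a1", "a2"),
    sequence = c(noise[1], paste0(substring(noise[1], 1, 50),
                                  substring(noise[2], 51, 60))))
  b3 <- tibble::tibble(transcript = "b1", sequence = noise[1])
  map3 <- best_hit_orthology(a3, b3)
  expect_equal(nrow(map3), 1)
  expect_equal(map3$id_a, "a1")
})

test_that("correlation edges equal the brute-force all-pairs oracle", {
  withr::with_seed(45, {
    keys <- tidyr::expand_grid(scion = "Csa", rootstock = "Cmo",
                               tissue = c("leaf", "root"),
                               condition = c("control", "chilling"))
    gene_fc <- tidyr::expand_grid(gene = sprintf("g%02d", 1:50),
                                  keys) |>
      dplyr::mutate(log2fc = rnorm(dplyr::n()))
    met_fc <- tidyr::expand_grid(metabolite = sprintf("m%02d", 1:30),
                                 keys) |>
      dplyr::mutate(log2fc = rnorm(dplyr::n()))
  })
  # plant one perfect pair and one anti-correlated pair
  g1 <- dplyr::filter(gene_fc, gene == "g01")
  met_fc$log2fc[met_fc$metabolite == "m01"] <- g1$log2fc
  met_fc$log2fc[met_fc$metabolite == "m02"] <- -g1$log2fc

  got <- correlate_deg_dim(gene_fc, met_fc, min_points = 4, threshold = 0.95)
  planted <- dplyr::filter(got, gene == "g01",
                           metabolite %in% c("m01", "m02"))
  expect_equal(nrow(planted), 2)
  expect_equal(planted$cor[planted$metabolite == "m01"], 1, tolerance = 1e-9)
  expect_equal(planted$sign[planted$metabolite == "m02"], -1)

  # brute force every pair with a first-principles Pearson formula
  brute <- list()
  for (g in unique(gene_fc$gene)) {
    gv <- dplyr::arrange(dplyr::filter(gene_fc, gene == g),
                         tissue, condition)
    for (m in unique(met_fc$metabolite)) {
      mv <- dplyr::arrange(dplyr::filter(met_fc, metabolite == m),
                           tissue, condition)
      r <- oracle_pearson(gv$log2fc, mv$log2fc)
      if (is.finite(r) && abs(r) >= 0.95) {
        brute[[length(brute) + 1]] <- tibble::tibble(gene = g,
                                                     metabolite = m,
                                                     cor = r)
      }
    }
  }
  brute <- dplyr::bind_rows(brute) |> dplyr::arrange(gene, metabolite)
  expect_equal(got$gene, brute$gene)
  expect_equal(got$metabolite, brute$metabolite)
  expect_equal(got$cor, brute$cor, tolerance = 1e-12)

  # a moderate correlation stays below the threshold
  mid <- met_fc
  mid$log2fc[mid$metabolite == "m03"] <-
    0.5 * g1$log2fc + withr::with_seed(46, rnorm(4, sd = 2))
  got_mid <- correlate_deg_dim(gene_fc, mid, threshold = 0.95)
  expect_false(any(got_mid$gene == "g01" & got_mid$metabolite == "m03"))

  # shared contrasts below min_points are not evaluated
  short <- dplyr::filter(met_fc, tissue == "leaf")
  expect_equal(nrow(correlate_deg_dim(gene_fc, short, min_points = 4)), 0)
})

test_that("pathway enrichment matches the closed-form hypergeometric tail", {
  # 10 of 12 set genes in pathway P, background 10 of 500 extra
  genes <- sprintf("G%03d", 1:512)
  set <- genes[1:12]
  ann <- dplyr::bind_rows(
    tibble::tibble(feature = genes[1:10], pathway = "P"),
    tibble::tibble(feature = genes[501:510], pathway = "P"),
    tibble::tibble(feature = genes, pathway = "Q"),
    tibble::tibble(feature = genes[5:104], pathway = "R"))
  res <- pathway_enrichment(set, ann, background = genes)
  expect_equal(res$pathway[1], "P")
  want_p <- oracle_hyper_tail(10, 20, 512, 12)
  expect_equal(res$p_value[res$pathway == "P"], want_p, tolerance = 1e-12)
  expect_equal(res$p_adjust,
               p.adjust(res$p_value, method = "BH"))
  # a pathway covering the whole background is never enriched
  expect_equal(res$p_value[res$pathway == "Q"], 1)
  expect_true(all(res$p_value > 0 & res$p_value <= 1))

  # set = background: all p-values 1
  flat <- pathway_enrichment(genes, ann, background = genes)
  expect_true(all(flat$p_value == 1))
  expect_error(pathway_enrichment(character(), ann), "empty")
  expect_error(pathway_enrichment("ZZZ", ann, background = genes), "outside")
})

test_that("Venn regions equal inclusion-exclusion on random sets", {
  expect_equal(
    dplyr::filter(venn_overlap(list(A = c("a", "b", "c"),
                                    B = c("b", "c", "d"))), A & B)$n, 2)
  disjoint <- venn_overlap(list(A = c("a", "b"), B = c("x", "y")))
  expect_equal(dplyr::filter(disjoint, A & B)$n, 0)
  expect_equal(dplyr::filter(disjoint, A & !B)$n, 2)

  withr::with_seed(47, {
    for (k in 2:4) {
      sets <- setNames(lapply(1:k, function(i) {
        sample(sprintf("e%02d", 1:30), sample(5:20, 1))
      }), LETTERS[1:k])
      got <- venn_overlap(sets)
      want <- oracle_venn_regions(sets)
      for (r in seq_len(nrow(got))) {
        mask <- sum(2^(which(unlist(got[r, LETTERS[1:k]])) - 1))
        expect_equal(got$n[r], unname(want[as.character(mask)]))
      }
      # regions partition the union
      expect_equal(sum(got$n), length(unique(unlist(sets))))
    }
  })
  expect_error(venn_overlap(rep(list(letters), 5)), "length")
})

test_that("a planted mobile -> DEG -> DIM chain is recovered as two typed edges", {
  mobile <- tibble::tibble(transcript = "Cmo_0001", is_mobile = TRUE)
  ortho <- tibble::tibble(id_a = "CsaG0001", id_b = "Cmo_0001", score = 100)
  degs <- tibble::tibble(gene = c("CsaG0001", "CsaG0002"),
                         call = c("up", "none"))
  dims <- tibble::tibble(metabolite = c("M0001", "M0002"),
                         call = c("down", "none"))
  cors <- tibble::tibble(gene = c("CsaG0001", "CsaG0002"),
                         metabolite = c("M0001", "M0002"),
                         cor = c(0.99, 0.99), sign = c(1, 1))
  ann <- tibble::tibble(feature = c("Cmo_0001", "CsaG0001", "M0001"),
                        pathway = "map00260")
  net <- suppressMessages(
    build_network(mobile, degs, dims, ortho, cors, ann))
  expect_equal(nrow(net), 2)
  expect_equal(net$type, c("deg-dim", "mobile-deg"))
  expect_equal(net$source, c("CsaG0001", "Cmo_0001"))
  expect_equal(net$target, c("M0001", "CsaG0001"))
  expect_equal(net$sign, c(1, NA))

  # without a shared pathway there is no mobile-deg edge
  ann2 <- tibble::tibble(feature = c("Cmo_0001", "CsaG0001"),
                         pathway = c("map00260", "map00071"))
  net2 <- suppressMessages(
    build_network(mobile, degs, dims, ortho, cors, ann2))
  expect_false(any(net2$type == "mobile-deg"))

  # empty correlation table leaves only mobile-deg edges
  net3 <- build_network(mobile, degs, dims, ortho,
                        tibble::tibble(gene = character(),
                                       metabolite = character(),
                                       sign = numeric()),
                        ann)
  expect_true(all(net3$type == "mobile-deg"))
  expect_equal(nrow(net3), 1)

  # determinism: identical inputs, identical edge list
  expect_identical(net, suppressMessages(
    build_network(mobile, degs, dims, ortho, cors, ann)))
})
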