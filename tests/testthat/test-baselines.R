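test_that("the GSEA baseline and ECEA share one enrichment engine", {
  set.seed(61)
  stat <- runif(80, -1, 1)
  genes <- sprintf("g%03d", 1:80)
  # a DE table whose weighted statistic equals a given weighted ECI vector
  de <- tibble::tibble(gene = genes, effect = stat, pvalue = 0)
  eci_tab <- tibble::tibble(gene = genes, weighted_eci = stat)
  sets <- list(a = genes[1:15], b = genes[30:60], c = sample(genes, 20))
  res_gsea <- gsea_single(de, sets, n_perm = 200, seed = 4, quiet = TRUE)
  res_ecea <- ecea(eci_tab, sets, n_perm = 200, seed = 4, quiet = TRUE)
  expect_equal(tidy(res_gsea)[c("pathway", "es", "nes", "pval", "fdr")],
               tidy(res_ecea)[c("pathway", "es", "nes", "pval", "fdr")])
  expect_setequal(unique(res_gsea$direction), c("up", "down"))
})

test_that("a top-ranked pathway is called up-enriched deterministically", {
  set.seed(62)
  de <- tibble::tibble(gene = sprintf("g%03d", 1:100),
                       effect = sort(rnorm(100), decreasing = TRUE),
                       pvalue = runif(100, 0, 0.05))
  sets <- list(top = de$gene[1:15], mid = de$gene[40:70])
  r1 <- gsea_single(de, sets, n_perm = 300, seed = 5, quiet = TRUE)
  expect_gt(r1$nes[r1$pathway == "top"], 0)
  expect_equal(r1$direction[r1$pathway == "top"], "up")
  r2 <- gsea_single(de, sets, n_perm = 300, seed = 5, quiet = TRUE)
  expect_identical(tidy(r1), tidy(r2))
})

test_that("ECI-ranked and fold-change-ranked enrichment differ in general", {
  fx <- planted_pairs_fixture(n_genes = 150, n_planted = 25, seed = 63)
  # inverse coupling: strong opposite effects rank low by ECI, high by lfc
  pairs <- fx$pairs
  pairs$beta2[1:25] <- -pairs$beta1[1:25]
  tab <- build_eci_table(pairs)
  de1 <- tibble::tibble(gene = pairs$gene, effect = pairs$beta1,
                        pvalue = pairs$p1)
  sets <- list(planted = fx$planted, other = pairs$gene[50:90])
  res_eci <- ecea(tab, sets, n_perm = 300, seed = 6, quiet = TRUE)
  res_lfc <- gsea_single(de1, sets, n_perm = 300, seed = 6, quiet = TRUE)
  expect_false(isTRUE(all.equal(res_eci$es[order(res_eci$pathway)],
                                res_lfc$es[order(res_lfc$pathway)])))
  expect_lt(res_eci$es[res_eci$pathway == "planted"], 0)
})

test_that("GSEA intersection applies the joint-significance sign rule", {
  r1 <- tibble::tibble(pathway = c("p1", "p2", "p3", "p4"),
                       nes = c(2.0, 1.5, -1.2, 2.2),
                       fdr = c(0.01, 0.02, 0.10, 0.50))
  r2 <- tibble::tibble(pathway = c("p1", "p2", "p3", "p4"),
                       nes = c(-1.8, 1.1, -2.0, 2.5),
                       fdr = c(0.02, 0.20, 0.01, 0.01))
  calls <- gsea_intersection(r1, r2, fdr_threshold = 0.25)
  expect_setequal(calls$pathway, c("p1", "p2", "p3"))
  expect_equal(calls$relationship[calls$pathway == "p1"], "inverse")
  expect_equal(calls$relationship[calls$pathway == "p2"], "equivalent")
  expect_equal(calls$relationship[calls$pathway == "p3"], "equivalent")
  # p4 significant in experiment 2 only: excluded
  expect_false("p4" %in% calls$pathway)
  # empty intersection is a zero-row tibble, not an error
  none <- gsea_intersection(
    dplyr::mutate(r1, fdr = 0.9), r2, fdr_threshold = 0.25)
  expect_equal(nrow(none), 0)
  expect_error(gsea_intersection(r1, r2[1:3, ]), "different")
})

test_that("ORA hypergeometric p-values match exact enumeration", {
  # small universe: every tail probability checked against direct counting
  set.seed(64)
  universe <- sprintf("g%02d", 1:30)
  de <- tibble::tibble(gene = universe,
                       effect = 1,
                       pvalue = c(rep(1e-6, 12), runif(18, 0.5, 1)))
  sets <- list(pathA = universe[c(1:7, 20:22)], pathB = universe[13:27])
  tests <- eqenrich:::ora_tests(de, sets, gene_fdr = 0.05,
                                min_size = 5, max_size = 50, quiet = TRUE)
  up <- tests[tests$direction == "up", ]
  for (i in seq_len(nrow(up))) {
    expect_equal(up$pval[i],
                 hyper_tail_oracle(up$overlap[i], up$n_sig[i], 30,
                                   up$size[i]),
                 tolerance = 1e-12)
  }
  expect_equal(up$overlap[up$pathway == "pathA"], 7)
})

test_that("ORA intersection labels directions and handles empty lists", {
  universe <- sprintf("g%03d", 1:200)
  pathway <- universe[1:20]
  strong <- function(up) tibble::tibble(
    gene = universe,
    effect = ifelse(universe %in% pathway, if (up) 2 else -2, 0.01),
    pvalue = ifelse(universe %in% pathway, 1e-8, runif(200, 0.5, 1))
  )
  sets <- list(path = pathway, other = universe[100:140])
  # all pathway genes significant-up in both experiments: equivalent
  calls <- ora_intersection(strong(TRUE), strong(TRUE), sets, quiet = TRUE)
  expect_equal(calls$relationship[calls$pathway == "path"], "equivalent")
  # up in one, down in the other: inverse
  calls2 <- ora_intersection(strong(TRUE), strong(FALSE), sets, quiet = TRUE)
  expect_equal(calls2$relationship[calls2$pathway == "path"], "inverse")
  # no significant genes in experiment 2: empty intersection
  flat <- tibble::tibble(gene = universe, effect = 0.01,
                         pvalue = runif(200, 0.5, 1))
  expect_equal(nrow(ora_intersection(strong(TRUE), flat, sets, quiet = TRUE)),
               0)
})
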