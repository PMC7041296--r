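test_that("running fractions match hand-enumerated sums", {
  ranked <- ranked_fixture(c(0.9, 0.7, 0.4, 0.1))
  fr <- running_fractions(ranked, c("g01", "g02"), omega = 0)
  expect_equal(fr$f_s, c(0.5, 1, 1, 1))
  expect_equal(fr$f_r, c(0, 0, 0.5, 1))

  # omega = 1 weights in-pathway genes by |weighted ECI|
  fr1 <- running_fractions(ranked, c("g01", "g03"), omega = 1)
  expect_equal(fr1$f_s, c(0.9, 0.9, 1.3, 1.3) / 1.3)
  expect_equal(fr1$f_r, c(0, 0.5, 0.5, 1))
})

test_that("both running fractions are nondecreasing and end at 1", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    ranked <- ranked_fixture(runif(n, -1, 1))
    pathway <- sample(ranked$gene, sample(2:(n - 1), 1))
    fr <- running_fractions(ranked, pathway, omega = sample(c(0, 1), 1))
    expect_true(all(diff(fr$f_s) >= -1e-12))
    expect_true(all(diff(fr$f_r) >= -1e-12))
    expect_equal(fr$f_s[n], 1)
    expect_equal(fr$f_r[n], 1)
  }
})

test_that("degenerate pathways and weights are rejected with clear errors", {
  ranked <- ranked_fixture(c(0.9, 0.5, 0.2, -0.4))
  expect_error(running_fractions(ranked, ranked$gene), "whole universe")
  expect_error(running_fractions(ranked, c("x1", "x2")), "no genes")
  zero <- tibble::tibble(gene = c("a", "b", "c", "d"),
                         weighted_eci = c(0.5, 0.3, 0, 0), rank = 1:4)
  expect_error(running_fractions(zero, c("c", "d"), omega = 1),
               "p-value weighting")
  # at omega = 0 zero weights are fine (plain proportions)
  expect_silent(fr <- running_fractions(zero, c("c", "d"), omega = 0))
  expect_equal(fr$f_s, c(0, 0, 0.5, 1))
})

test_that("unweighted |ES| equals the brute-force KS statistic", {
  set.seed(21)
  for (n in 4:9) {
    ranked <- ranked_fixture(runif(n, -1, 1))
    for (mask in 1:(2^n - 2)) {
      in_set <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
      es <- enrichment_score(ranked, ranked$gene[in_set], omega = 0)
      expect_equal(abs(es$es),
                   ks_oracle(which(in_set), which(!in_set)),
                   tolerance = 1e-12)
    }
  }
})

test_that("ES sign tracks where pathway genes concentrate", {
  ranked <- ranked_fixture(seq(1, -1, length.out = 20))
  expect_gt(enrichment_score(ranked, ranked$gene[1:10])$es, 0)
  expect_lt(enrichment_score(ranked, ranked$gene[11:20])$es, 0)
})

test_that("weighted ES matches exhaustive evaluation at every rank", {
  stat <- c(0.9, 0.6, 0.3, -0.2, -0.5, -0.8)
  ranked <- ranked_fixture(stat)
  pathway <- c("g02", "g05")
  # direct evaluation of the definitions at all 6 ranks
  in_set <- ranked$gene %in% pathway
  w <- abs(stat) * in_set
  f_s <- cumsum(w) / sum(w)
  f_r <- cumsum(!in_set) / 4
  d <- f_s - f_r
  i <- which.max(abs(d))
  es <- enrichment_score(ranked, pathway, omega = 1)
  expect_equal(es$es, d[i])
  expect_equal(es$argmax_rank, i)
})

test_that("ES agrees with the fgsea running-statistic on random inputs", {
  set.seed(31)
  for (i in 1:10) {
    n <- 50
    stat <- sort(rnorm(n), decreasing = TRUE)
    ranked <- ranked_fixture(stat)
    pos <- sort(sample(n, 8))
    es <- enrichment_score(ranked, ranked$gene[pos], omega = 1)$es
    expect_equal(es, fgsea::calcGseaStat(stat, pos, gseaParam = 1),
                 tolerance = 1e-10)
  }
})

test_that("fast position-based ES equals the step-function ES", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(10:80, 1)
    stat <- sort(runif(n, -1, 1), decreasing = TRUE)
    ranked <- ranked_fixture(stat)
    pos <- sort(sample(n, sample(2:(n - 1), 1)))
    omega <- sample(c(0, 1, 2), 1)
    expect_equal(
      eqenrich:::es_from_positions(stat, pos, omega, on_zero = "uniform"),
      enrichment_score(ranked, ranked$gene[pos], omega)$es,
      tolerance = 1e-12
    )
  }
})

test_that("permutation null is reproducible and validates its inputs", {
  ranked <- ranked_fixture(runif(30, -1, 1))
  n1 <- permutation_null(ranked, 5, n_perm = 100, seed = 9)
  n2 <- permutation_null(ranked, 5, n_perm = 100, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 100)
  # boundary: pathway of G - 1 genes leaves one out-of-set gene
  nb <- permutation_null(ranked, 29, n_perm = 100, seed = 1)
  expect_true(all(is.finite(nb)))
  expect_error(permutation_null(ranked, 30, n_perm = 100), "pathway_size")
  expect_error(permutation_null(ranked, 0, n_perm = 100), "pathway_size")
  expect_error(permutation_null(ranked, 5, n_perm = 50), "at least 100")
})

test_that("NES and permutation p-values follow the sign-stratified rules", {
  null <- c(0.2, 0.4, 0.6, -0.1, -0.3)
  # es equal to the mean same-sign null score gives NES 1
  out <- normalize_and_test(0.4, null)
  expect_equal(out$nes, 1)
  expect_equal(out$pval, (1 + 2) / (1 + 3))
  # zero score
  expect_equal(normalize_and_test(0, null),
               list(nes = 0, pval = 1, flagged = FALSE))
  # more extreme than all k same-sign nulls: pval = 1/(k+1)
  ext <- normalize_and_test(0.9, null)
  expect_equal(ext$pval, 1 / 4)
  # no same-sign nulls: flagged, pooled fallback
  flg <- normalize_and_test(-0.5, c(0.1, 0.2, 0.9))
  expect_true(flg$flagged)
  expect_true(is.na(flg$nes))
  expect_equal(flg$pval, (1 + 1) / (1 + 3))
  expect_error(normalize_and_test(0.5, numeric()), "non-empty")
})

test_that("ecea recovers a planted equivalently changed gene set", {
  fx <- planted_pairs_fixture(n_genes = 150, n_planted = 25, seed = 5)
  tab <- build_eci_table(fx$pairs)
  sets <- list(planted = fx$planted,
               random1 = sample(fx$pairs$gene, 30),
               random2 = sample(fx$pairs$gene, 15))
  res <- ecea(tab, sets, n_perm = 500, seed = 11, quiet = TRUE)
  planted <- res[res$pathway == "planted", ]
  expect_gt(planted$nes, 0)
  expect_lte(planted$fdr, 0.25)
  expect_equal(planted$direction, "equivalent")
  expect_true(planted$enriched)
  expect_equal(planted$size, 25)
  # top genes are planted members with the largest weighted ECI
  top <- strsplit(planted$top_genes, ",")[[1]]
  expect_length(top, 5)
  expect_true(all(top %in% fx$planted))
  in_stat <- tab$weighted_eci[match(fx$planted, tab$gene)]
  expect_setequal(top, fx$planted[order(-in_stat)][1:5])
})

test_that("ecea is deterministic under a fixed seed and drops degenerate sets", {
  fx <- planted_pairs_fixture(seed = 6)
  tab <- build_eci_table(fx$pairs)
  sets <- list(planted = fx$planted, whole = fx$pairs$gene,
               random = fx$pairs$gene[30:70])
  expect_warning(res1 <- ecea(tab, sets, n_perm = 200, seed = 3),
                 "whole universe")
  res2 <- suppressWarnings(ecea(tab, sets, n_perm = 200, seed = 3))
  expect_identical(tidy(res1), tidy(res2))
  expect_setequal(res1$pathway, c("planted", "random"))
  expect_error(
    suppressWarnings(ecea(tab, list(tiny = fx$planted[1:3]), n_perm = 200)),
    "sizes in"
  )
})

test_that("negating every weighted ECI flips scores and labels", {
  fx <- planted_pairs_fixture(n_genes = 100, n_planted = 20, seed = 8)
  tab <- build_eci_table(fx$pairs)
  neg <- tab
  neg$weighted_eci <- -neg$weighted_eci
  neg$rank <- NULL
  sets <- list(planted = fx$planted, other = fx$pairs$gene[41:75])
  res <- ecea(tab, sets, n_perm = 300, seed = 13, quiet = TRUE)
  res_neg <- ecea(neg, sets, n_perm = 300, seed = 13, quiet = TRUE)
  res_neg <- res_neg[match(res$pathway, res_neg$pathway), ]
  expect_equal(res_neg$es, -res$es, tolerance = 1e-12)
  expect_equal(sign(res_neg$nes), -sign(res$nes))
  expect_equal(res_neg$direction,
               ifelse(res$direction == "equivalent", "inverse", "equivalent"))
})

test_that("out-of-pathway weights never influence F_S", {
  ranked <- ranked_fixture(c(0.8, 0.6, 0.5, 0.3, 0.2, -0.7))
  other <- ranked
  other$weighted_eci[!other$gene %in% c("g02", "g04")] <-
    c(5, 4, 3, 2) * 0.1 # different out-of-set magnitudes, same order
  f1 <- running_fractions(ranked, c("g02", "g04"), omega = 1)
  f2 <- running_fractions(other, c("g02", "g04"), omega = 1)
  expect_equal(f1$f_s, f2$f_s)
})

test_that("p-values of random gene sets are roughly uniform under the null", {
  set.seed(55)
  n_genes <- 400
  ranked <- ranked_fixture(runif(n_genes, -1, 1))
  pvals <- vapply(1:40, function(i) {
    pathway <- sample(ranked$gene, 20)
    es <- enrichment_score(ranked, pathway)$es
    null <- permutation_null(ranked, 20, n_perm = 400, seed = 100 + i)
    normalize_and_test(es, null)$pval
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})
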