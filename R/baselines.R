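#' Single-experiment enrichment on the log2 fold change
#'
#' Runs the same weighted-KS enrichment engine as [ecea()], but ranks genes
#' by the p-value-weighted log2 fold change of ONE experiment
#' (`effect * (1 - pvalue)`), i.e. conventional per-experiment GSEA-style
#' enrichment. Direction labels are `up`/`down`. Two such runs intersected
#' with [gsea_intersection()] form the GSEA-intersection baseline.
#'
#' @param de A per-gene DE table with columns `gene`, `effect`, `pvalue`.
#' @inheritParams ecea
#' @return An `ecea_result` tibble (see [ecea()]) with `up`/`down`
#'   direction labels.
#' @export
gsea_single <- function(de, gene_sets, omega = 1, n_perm = 1000,
                        min_size = 10, max_size = 500, fdr_threshold = 0.25,
                        seed = NULL, n_top = 5, quiet = FALSE) {
  de <- check_de_table(de, "de")
  stat_tbl <- tibble::tibble(gene = de$gene,
                             stat = de$effect * (1 - de$pvalue))
  enrich_ranked(ranked_stats(stat_tbl), gene_sets,
                omega = omega, n_perm = n_perm,
                min_size = min_size, max_size = max_size,
                fdr_threshold = fdr_threshold, seed = seed, n_top = n_top,
                quiet = quiet, statistic = "weighted_log2fc",
                labels = c(pos = "up", neg = "down"))
}

#' Intersect two single-experiment enrichment results
#'
#' The GSEA-intersection strategy: a pathway is called only when it is
#' significant in BOTH experiments at the FDR threshold; it is labeled
#' `equivalent` when the two normalized enrichment scores share a sign and
#' `inverse` when they differ.
#'
#' @param results1,results2 `ecea_result` tables from [gsea_single()] run
#'   over the same gene-set collection.
#' @param fdr_threshold Per-experiment significance threshold.
#' @return A tibble of calls with columns `pathway`, `direction1`,
#'   `direction2`, `relationship`, `nes1`, `nes2`, `fdr1`, `fdr2`. Empty
#'   (zero rows) when no pathway survives in both.
#' @export
gsea_intersection <- function(results1, results2, fdr_threshold = 0.25) {
  r1 <- tibble::as_tibble(results1)
  r2 <- tibble::as_tibble(results2)
  if (!setequal(r1$pathway, r2$pathway)) {
    abort("The two result sets cover different gene-set collections.")
  }
  joined <- dplyr::inner_join(
    dplyr::select(r1, "pathway", nes1 = "nes", fdr1 = "fdr"),
    dplyr::select(r2, "pathway", nes2 = "nes", fdr2 = "fdr"),
    by = "pathway"
  )
  joined <- dplyr::filter(joined,
                          !is.na(.data$fdr1), !is.na(.data$fdr2),
                          .data$fdr1 <= fdr_threshold,
                          .data$fdr2 <= fdr_threshold,
                          !is.na(.data$nes1), !is.na(.data$nes2),
                          .data$nes1 != 0, .data$nes2 != 0)
  joined <- dplyr::mutate(
    joined,
    direction1 = ifelse(.data$nes1 > 0, "up", "down"),
    direction2 = ifelse(.data$nes2 > 0, "up", "down"),
    relationship = ifelse(.data$direction1 == .data$direction2,
                          "equivalent", "inverse")
  )
  dplyr::select(joined, "pathway", "direction1", "direction2",
                "relationship", "nes1", "nes2", "fdr1", "fdr2")
}

#' Over-representation (hypergeometric) intersection baseline
#'
#' For each experiment, genes significant at the BH-adjusted `gene_fdr` are
#' split into up- and down-regulated lists; each list is tested against each
#' pathway with the hypergeometric over-representation test (universe = all
#' genes in the DE table), and pathway p-values are BH-adjusted across all
#' pathway-direction tests of that experiment. Pathways significant in both
#' experiments are intersected and labeled `equivalent`/`inverse` by
#' direction concordance.
#'
#' @param de1,de2 Per-gene DE tables (`gene`, `effect`, `pvalue`) over a
#'   shared universe.
#' @param gene_sets Named list of pathways.
#' @param gene_fdr BH-FDR threshold for calling individual genes significant.
#' @param pathway_fdr BH-FDR threshold for the pathway-level tests.
#' @param min_size,max_size Pathway size bounds after intersection with the
#'   universe.
#' @param quiet Suppress informational messages.
#' @return A tibble of calls in the same layout as [gsea_intersection()]
#'   (with per-experiment hypergeometric FDRs in `fdr1`, `fdr2` and no
#'   `nes` columns).
#' @export
ora_intersection <- function(de1, de2, gene_sets, gene_fdr = 0.05,
                             pathway_fdr = 0.25, min_size = 10,
                             max_size = 500, quiet = FALSE) {
  de1 <- check_de_table(de1, "de1")
  de2 <- check_de_table(de2, "de2")
  calls1 <- ora_single(de1, gene_sets, gene_fdr, pathway_fdr,
                       min_size, max_size, quiet)
  calls2 <- ora_single(de2, gene_sets, gene_fdr, pathway_fdr,
                       min_size, max_size, quiet)
  joined <- dplyr::inner_join(
    dplyr::select(calls1, "pathway", direction1 = "direction", fdr1 = "fdr"),
    dplyr::select(calls2, "pathway", direction2 = "direction", fdr2 = "fdr"),
    by = "pathway"
  )
  dplyr::mutate(joined,
                relationship = ifelse(.data$direction1 == .data$direction2,
                                      "equivalent", "inverse"),
                .after = "direction2")
}

# One experiment's full ORA test table: one hypergeometric upper-tail test
# per retained pathway and direction list, BH-adjusted across all tests.
ora_tests <- function(de, gene_sets, gene_fdr, min_size, max_size, quiet) {
  universe <- de$gene
  n_univ <- length(universe)
  padj <- p.adjust(de$pvalue, method = "BH")
  sig_up <- de$gene[padj <= gene_fdr & de$effect > 0]
  sig_down <- de$gene[padj <= gene_fdr & de$effect < 0]
  if (!quiet && length(sig_up) + length(sig_down) == 0) {
    inform("No significant genes at the gene-level FDR; all pathway p-values are 1.")
  }

  members <- lapply(gene_sets, function(g) intersect(unique(g), universe))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size & sizes < n_univ
  members <- members[keep]

  test_list <- function(sig, dir) {
    purrr::imap(members, function(m, nm) {
      overlap <- sum(m %in% sig)
      p <- if (length(sig) == 0) 1 else {
        phyper(overlap - 1, length(sig), n_univ - length(sig), length(m),
               lower.tail = FALSE)
      }
      tibble::tibble(pathway = nm, direction = dir, size = length(m),
                     n_sig = length(sig), overlap = overlap, pval = p)
    })
  }
  tests <- dplyr::bind_rows(c(test_list(sig_up, "up"),
                              test_list(sig_down, "down")))
  if (nrow(tests) > 0) tests$fdr <- p.adjust(tests$pval, method = "BH")
  tests
}

# One experiment's ORA calls: significant pathways with their direction.
ora_single <- function(de, gene_sets, gene_fdr, pathway_fdr,
                       min_size, max_size, quiet) {
  tests <- ora_tests(de, gene_sets, gene_fdr, min_size, max_size, quiet)
  if (nrow(tests) == 0) {
    return(tibble::tibble(pathway = character(), direction = character(),
                          fdr = numeric()))
  }
  sig <- dplyr::filter(tests, .data$fdr <= pathway_fdr)
  # one call per pathway: keep the more significant direction
  sig <- dplyr::arrange(sig, .data$pval)
  sig <- dplyr::distinct(sig, .data$pathway, .keep_all = TRUE)
  dplyr::select(sig, "pathway", "direction", "fdr")
}
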