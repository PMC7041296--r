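#' @title Weighted Kolmogorov-Smirnov enrichment over an ECI-ranked list
#' @name enrichment
#' @description
#' ECEA asks whether a pathway's genes concentrate at the equivalently
#' changed top or the inversely changed bottom of the gene list ranked by
#' weighted ECI. The statistic is the supremum deviation between two running
#' cumulative fractions: a weighted fraction of in-pathway genes
#' (weights `|weighted ECI|^omega`) and the plain fraction of out-of-pathway
#' genes. With `omega = 0` and uniform weights this is the classical
#' two-sample KS statistic on ranks; `omega = 1` (the default) gives the
#' GSEA-style weighted variant, which is less sensitive to within-pathway
#' correlation. Significance comes from a gene-sampling permutation null:
#' random gene sets of matched size drawn from the universe.
NULL

# Normalise a ranked input into parallel vectors of genes and statistics.
# Accepts an ECI table (gene, weighted_eci, rank) or any tibble with
# columns `gene` and `stat`; without a `rank` column rows are ordered by
# decreasing statistic with gene-id tie-breaks.
ranked_stats <- function(x) {
  if (is.list(x) && !is.data.frame(x) &&
      all(c("genes", "stat") %in% names(x))) {
    return(x) # already normalised
  }
  x <- tibble::as_tibble(x)
  stat_col <- if ("weighted_eci" %in% names(x)) "weighted_eci" else "stat"
  if (!all(c("gene", stat_col) %in% names(x))) {
    abort("Ranked input needs columns `gene` and `weighted_eci` (or `stat`).")
  }
  if (anyDuplicated(x$gene)) abort("Ranked input has duplicate genes.")
  if (nrow(x) < 2) abort("Ranked input needs at least 2 genes.")
  ord <- if ("rank" %in% names(x)) {
    order(x$rank)
  } else {
    order(-x[[stat_col]], x$gene, method = "radix")
  }
  list(genes = x$gene[ord], stat = as.numeric(x[[stat_col]][ord]))
}

#' Running cumulative fractions for one pathway
#'
#' Evaluates, at every rank `x` of the gene list, the weighted cumulative
#' fraction of in-pathway genes `F_S(x)` and the plain cumulative fraction of
#' out-of-pathway genes `F_R(x)`. Both are nondecreasing step functions
#' ending at 1.
#'
#' @param ranked A ranked ECI table from [build_eci_table()] (or any tibble
#'   with columns `gene` and `stat`, ordered by `rank` if present).
#' @param pathway Character vector of gene identifiers.
#' @param omega Nonnegative weighting exponent; 0 gives plain rank
#'   proportions, 1 the weighted statistic used throughout.
#'
#' @return A tibble with columns `rank`, `gene`, `in_pathway`, `f_s`, `f_r`.
#' @export
running_fractions <- function(ranked, pathway, omega = 1) {
  rs <- ranked_stats(ranked)
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0) {
    abort("`omega` must be a single nonnegative number.")
  }
  in_set <- rs$genes %in% pathway
  n_in <- sum(in_set)
  n_genes <- length(rs$genes)
  if (n_in == 0) abort("The pathway shares no genes with the ranked universe.")
  if (n_in == n_genes) {
    abort("Degenerate gene set: the pathway covers the whole universe.")
  }
  w <- abs(rs$stat)^omega
  totw <- sum(w[in_set])
  if (omega > 0 && totw == 0) {
    abort(paste0("Degenerate weights: every in-pathway weighted statistic is ",
                 "0 at omega > 0. Check the p-value weighting of the input."))
  }
  tibble::tibble(
    rank = seq_len(n_genes),
    gene = rs$genes,
    in_pathway = in_set,
    f_s = cumsum(ifelse(in_set, w, 0)) / totw,
    f_r = cumsum(!in_set) / (n_genes - n_in)
  )
}

#' Signed enrichment score for one pathway
#'
#' Returns the value of `F_S - F_R` at the rank where its absolute value is
#' maximal (earliest such rank on ties). The magnitude is the weighted KS
#' statistic D; the sign carries direction: positive when pathway genes
#' concentrate at the equivalent-change top of the list, negative at the
#' inverse-change bottom.
#'
#' @inheritParams running_fractions
#' @return A list with `es` (signed score) and `argmax_rank`.
#' @export
enrichment_score <- function(ranked, pathway, omega = 1) {
  fr <- running_fractions(ranked, pathway, omega)
  d <- fr$f_s - fr$f_r
  i <- which.max(abs(d))
  list(es = d[i], argmax_rank = i)
}

# O(k) enrichment score from in-pathway positions only: F_S is constant
# between member ranks while F_R rises, so the supremum of |F_S - F_R| is
# attained at a member rank, just before one, or at the end of the list.
es_from_positions <- function(stat, pos, omega, on_zero = c("error", "uniform")) {
  on_zero <- match.arg(on_zero)
  n_genes <- length(stat)
  pos <- sort(pos)
  k <- length(pos)
  w <- abs(stat[pos])^omega
  totw <- sum(w)
  if (totw == 0) {
    if (on_zero == "error" && omega > 0) {
      abort(paste0("Degenerate weights: every in-pathway weighted statistic ",
                   "is 0 at omega > 0. Check the p-value weighting of the ",
                   "input."))
    }
    w <- rep(1, k)
    totw <- k
  }
  csw <- cumsum(w) / totw
  f_r <- (pos - seq_len(k)) / (n_genes - k)
  cand <- c(csw - f_r, c(0, csw[-k]) - f_r, 0)
  cand[which.max(abs(cand))]
}

#' Gene-sampling permutation null for the enrichment score
#'
#' Draws random gene sets of the given size without replacement from the
#' ranked universe and records their signed enrichment scores. This is the
#' appropriate null when only per-gene statistics are available (sample-label
#' permutation is impossible for a statistic that already compares two
#' experiments).
#'
#' @inheritParams running_fractions
#' @param pathway_size Number of genes per random set; must satisfy
#'   `1 <= pathway_size < G`.
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed for reproducibility.
#'
#' @return Numeric vector of `n_perm` signed enrichment scores.
#' @export
permutation_null <- function(ranked, pathway_size, omega = 1, n_perm = 1000,
                             seed = NULL) {
  rs <- ranked_stats(ranked)
  n_genes <- length(rs$genes)
  if (!is.numeric(pathway_size) || length(pathway_size) != 1 ||
      pathway_size < 1 || pathway_size >= n_genes) {
    abort("`pathway_size` must satisfy 1 <= pathway_size < universe size.")
  }
  if (!is.numeric(n_perm) || n_perm < 100) {
    abort("`n_perm` must be at least 100.")
  }
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    es_from_positions(rs$stat, sample.int(n_genes, pathway_size), omega,
                      on_zero = "uniform")
  }, numeric(1))
}

#' Normalize an enrichment score and compute its permutation p-value
#'
#' Follows the GSEA sign-stratified convention: the normalized enrichment
#' score (NES) divides the observed score by the mean magnitude of the
#' same-sign null scores, and the p-value is the one-sided empirical tail
#' probability within the same-sign null, with a +1 pseudo-count so no
#' p-value is exactly 0.
#'
#' @param es Signed enrichment score.
#' @param null_scores Numeric vector of null scores from
#'   [permutation_null()].
#'
#' @return A list with `nes`, `pval` and `flagged` (`TRUE` when no same-sign
#'   null score existed, in which case `nes` is `NA` and the p-value falls
#'   back to the pooled two-sided null).
#' @export
normalize_and_test <- function(es, null_scores) {
  if (length(null_scores) == 0) abort("`null_scores` must be non-empty.")
  if (es == 0) {
    return(list(nes = 0, pval = 1, flagged = FALSE))
  }
  same <- if (es > 0) null_scores[null_scores > 0] else null_scores[null_scores < 0]
  if (length(same) == 0) {
    return(list(
      nes = NA_real_,
      pval = (1 + sum(abs(null_scores) >= abs(es))) / (1 + length(null_scores)),
      flagged = TRUE
    ))
  }
  list(
    nes = es / mean(abs(same)),
    pval = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)),
    flagged = FALSE
  )
}

#' Equivalent change enrichment analysis
#'
#' Runs the weighted-KS enrichment test over a ranked ECI table for every
#' pathway in a gene-set collection, with gene-sampling permutation
#' significance, sign-stratified NES and Benjamini-Hochberg FDR across all
#' tested pathways. Pathways are labeled `equivalent` (positive score:
#' genes concentrated at the equivalent-change top) or `inverse` (negative
#' score) and flagged enriched at `fdr <= fdr_threshold`.
#'
#' @param eci_table Ranked ECI table from [build_eci_table()].
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]). Each set is intersected with the ranked universe; sets
#'   smaller than `min_size` or larger than `max_size` afterwards are
#'   dropped, and a set equal to the whole universe is rejected.
#' @param omega Weighting exponent (default 1, the weighted KS statistic).
#' @param n_perm Permutations per null (default 1000). Nulls are shared
#'   between pathways of identical post-intersection size.
#' @param min_size,max_size Pathway size bounds after intersection.
#' @param fdr_threshold Enrichment call threshold on the BH FDR
#'   (default 0.25, the conventional GSEA cut-off).
#' @param seed Optional integer seed.
#' @param n_top Number of top genes to report per pathway (default 5): the
#'   members with the largest weighted-ECI magnitude in the direction of
#'   enrichment.
#' @param quiet Suppress informational messages.
#'
#' @return An `ecea_result` tibble with columns `pathway`, `size`, `es`,
#'   `nes`, `pval`, `fdr`, `direction`, `enriched`, `top_genes`, arranged by
#'   p-value.
#'
#' @examples
#' set.seed(1)
#' pairs <- tibble::tibble(
#'   gene = sprintf("g%03d", 1:120),
#'   beta1 = rnorm(120), beta2 = rnorm(120),
#'   p1 = runif(120), p2 = runif(120)
#' )
#' # plant an equivalently changed block
#' pairs$beta2[1:20] <- pairs$beta1[1:20]
#' pairs$p1[1:20] <- pairs$p2[1:20] <- 0.001
#' tab <- build_eci_table(pairs)
#' sets <- list(planted = sprintf("g%03d", 1:20),
#'              random = sprintf("g%03d", 51:80))
#' ecea(tab, sets, n_perm = 200, seed = 7)
#' @export
ecea <- function(eci_table, gene_sets, omega = 1, n_perm = 1000,
                 min_size = 10, max_size = 500, fdr_threshold = 0.25,
                 seed = NULL, n_top = 5, quiet = FALSE) {
  enrich_ranked(ranked_stats(eci_table), gene_sets,
                omega = omega, n_perm = n_perm,
                min_size = min_size, max_size = max_size,
                fdr_threshold = fdr_threshold, seed = seed, n_top = n_top,
                quiet = quiet, statistic = "weighted_eci",
                labels = c(pos = "equivalent", neg = "inverse"))
}

# Shared enrichment engine: ECEA and the per-experiment GSEA baseline differ
# only in the local statistic fed in through `ranked`.
enrich_ranked <- function(rs, gene_sets, omega, n_perm, min_size, max_size,
                          fdr_threshold, seed, n_top, quiet, statistic,
                          labels) {
  if (!is.list(gene_sets) || length(gene_sets) == 0 ||
      is.null(names(gene_sets)) || any(names(gene_sets) == "")) {
    abort("`gene_sets` must be a non-empty named list of gene-id vectors.")
  }
  if (anyDuplicated(names(gene_sets))) abort("Gene-set names must be unique.")
  universe <- rs$genes
  n_genes <- length(universe)

  members <- lapply(gene_sets, function(g) intersect(unique(g), universe))
  n_dropped <- sum(lengths(gene_sets) - lengths(lapply(gene_sets, unique))) +
    sum(vapply(gene_sets, function(g) sum(!unique(g) %in% universe), 0L))
  if (!quiet && n_dropped > 0) {
    inform(paste0(n_dropped, " gene-set member(s) absent from the universe ",
                  "(or duplicated) were dropped."))
  }
  sizes <- lengths(members)
  whole <- sizes == n_genes
  if (any(whole) && !quiet) {
    warn(paste0("Dropping degenerate set(s) covering the whole universe: ",
                paste(names(gene_sets)[whole], collapse = ", "), "."))
  }
  keep <- !whole & sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    abort(paste0("No gene set left after filtering to sizes in [",
                 min_size, ", ", max_size, "] within the universe."))
  }
  members <- members[keep]
  sizes <- sizes[keep]

  if (!is.null(seed)) set.seed(seed)
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(size) {
    key <- as.character(size)
    if (is.null(null_cache[[key]])) {
      null_cache[[key]] <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(rs$stat, sample.int(n_genes, size), omega,
                          on_zero = "uniform")
      }, numeric(1))
    }
    null_cache[[key]]
  }

  stat_by_gene <- setNames(rs$stat, rs$genes)
  rows <- purrr::imap(members, function(m, nm) {
    es <- es_from_positions(rs$stat, match(m, universe), omega,
                            on_zero = "error")
    nt <- normalize_and_test(es, get_null(length(m)))
    s <- stat_by_gene[m]
    ord <- if (es >= 0) order(-s, m, method = "radix") else order(s, m, method = "radix")
    tibble::tibble(
      pathway = nm, size = length(m), es = es, nes = nt$nes,
      pval = nt$pval, flagged = nt$flagged,
      top_genes = paste(m[ord][seq_len(min(n_top, length(m)))], collapse = ",")
    )
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- p.adjust(out$pval, method = "BH")
  out$direction <- dplyr::case_when(
    out$es > 0 ~ labels[["pos"]],
    out$es < 0 ~ labels[["neg"]],
    TRUE ~ NA_character_
  )
  out$enriched <- !is.na(out$fdr) & out$fdr <= fdr_threshold &
    !is.na(out$direction)
  out <- dplyr::arrange(out, .data$pval, .data$pathway)
  out <- dplyr::select(out, "pathway", "size", "es", "nes", "pval", "fdr",
                       "direction", "enriched", "top_genes", "flagged")
  structure(out,
            class = c("ecea_result", class(out)),
            statistic = statistic, omega = omega, n_perm = n_perm,
            seed = seed, fdr_threshold = fdr_threshold,
            universe_size = n_genes, labels = labels)
}
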