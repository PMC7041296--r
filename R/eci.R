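#' Equivalent change index (ECI)
#'
#' The ECI measures how similarly a gene responds to two different treatments,
#' each assessed against its own control. For effect sizes `beta1` and `beta2`
#' (log2 fold changes, standardized mean differences, or plain mean
#' differences) it is the ratio of the smaller to the larger absolute effect,
#' signed by whether the two effects point in the same direction:
#'
#' \deqn{ECI = sign(\beta_1 \beta_2) \, \frac{\min(|\beta_1|, |\beta_2|)}
#'   {\max(|\beta_1|, |\beta_2|)}}
#'
#' An ECI of 1 means the gene changed to exactly the same degree in both
#' experiments; -1 means it changed to the same degree in opposite
#' directions; values near 0 mean the responses were unrelated in magnitude
#' or absent. When either effect is exactly zero the ECI is defined as 0:
#' there is no evidence of shared (or opposed) change.
#'
#' @param beta1,beta2 Numeric vectors of finite effect sizes, recycled to a
#'   common length.
#'
#' @return A numeric vector of ECI values in \[-1, 1\].
#'
#' @examples
#' compute_eci(1, 1)    #  1: identical response
#' compute_eci(1, -1)   # -1: exactly opposite response
#' compute_eci(1, 2)    #  0.5
#' compute_eci(0, 5)    #  0
#' @seealso [weight_eci()], [build_eci_table()]
#' @export
compute_eci <- function(beta1, beta2) {
  if (is.logical(beta1) && all(is.na(beta1))) beta1 <- as.numeric(beta1)
  if (is.logical(beta2) && all(is.na(beta2))) beta2 <- as.numeric(beta2)
  if (!is.numeric(beta1) || !is.numeric(beta2)) {
    abort("`beta1` and `beta2` must be numeric.")
  }
  n <- max(length(beta1), length(beta2))
  beta1 <- rep_len(beta1, n)
  beta2 <- rep_len(beta2, n)
  if (!all(is.finite(beta1)) || !all(is.finite(beta2))) {
    abort("Effect sizes must be finite (no NA, NaN or Inf).")
  }
  a1 <- abs(beta1)
  a2 <- abs(beta2)
  hi <- pmax(a1, a2)
  out <- numeric(n)
  nz <- hi > 0
  out[nz] <- sign(beta1[nz] * beta2[nz]) * pmin(a1[nz], a2[nz]) / hi[nz]
  out
}

#' Confidence-weight an ECI by differential-expression p-values
#'
#' Multiplies the ECI by `1 - max(p1, p2)`, so a gene only retains its ECI
#' when both underlying effect-size estimates are confident. A gene with an
#' uninformative test in either experiment (p near 1) is shrunk towards 0.
#'
#' @param eci Numeric vector of ECI values in \[-1, 1\].
#' @param p1,p2 p-values in \[0, 1\] from the differential-expression tests
#'   of experiments 1 and 2.
#'
#' @return The weighted ECI; its magnitude never exceeds `abs(eci)`.
#'
#' @examples
#' weight_eci(1, 0, 0)         # 1: fully confident
#' weight_eci(1, 1, 0.5)       # 0: one test uninformative
#' weight_eci(-0.8, 0.05, 0.1) # -0.72
#' @export
weight_eci <- function(eci, p1, p2) {
  n <- max(length(eci), length(p1), length(p2))
  eci <- rep_len(eci, n)
  p1 <- rep_len(p1, n)
  p2 <- rep_len(p2, n)
  bad <- (!is.na(p1) & (p1 < 0 | p1 > 1)) | (!is.na(p2) & (p2 < 0 | p2 > 1))
  if (any(bad)) {
    abort("p-values must lie in [0, 1].")
  }
  eci * (1 - pmax(p1, p2))
}

#' Build a ranked ECI table from paired effect sizes
#'
#' Computes the ECI and weighted ECI for every gene and assigns ranks in
#' decreasing order of the weighted ECI, so rank 1 is the most equivalently
#' changed gene and rank G the most inversely changed. Ranking uses the
#' weighted ECI so that the ordering fed to enrichment and the weights used
#' inside the enrichment statistic agree; ties are broken by gene identifier
#' for determinism.
#'
#' @param pairs A data frame with columns `gene`, `beta1`, `beta2` and,
#'   optionally, `p1` and `p2`. Missing p-values give the gene full weight
#'   (weighted ECI = ECI) with a warning.
#'
#' @return A tibble with columns `gene`, `beta1`, `beta2`, `p1`, `p2`,
#'   `eci`, `weighted_eci` and `rank`, arranged by rank.
#'
#' @examples
#' pairs <- tibble::tibble(
#'   gene = c("A", "B", "C"),
#'   beta1 = c(1, -2, 0.5), beta2 = c(1.2, 2, 0.1),
#'   p1 = c(0.01, 0.2, 0.9), p2 = c(0.03, 0.01, 0.5)
#' )
#' build_eci_table(pairs)
#' @export
build_eci_table <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("gene", "beta1", "beta2")
  missing_cols <- setdiff(need, names(pairs))
  if (length(missing_cols) > 0) {
    abort(paste0("`pairs` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (nrow(pairs) < 2) {
    abort("At least 2 genes are required to build an ECI table.")
  }
  dup <- unique(pairs$gene[duplicated(pairs$gene)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene identifier(s): ",
                 paste(head(dup, 10), collapse = ", "),
                 if (length(dup) > 10) ", ..." else "", "."))
  }
  if (!"p1" %in% names(pairs)) pairs$p1 <- NA_real_
  if (!"p2" %in% names(pairs)) pairs$p2 <- NA_real_

  eci <- compute_eci(pairs$beta1, pairs$beta2)
  pmax_p <- pmax(pairs$p1, pairs$p2)
  n_miss <- sum(is.na(pmax_p))
  if (n_miss > 0) {
    warn(paste0(n_miss, " gene(s) have missing p-values; their weighted ECI ",
                "uses weight 1 (raw ECI)."))
    pmax_p[is.na(pmax_p)] <- 0
  }
  weighted <- weight_eci(eci, pmax_p, pmax_p)

  ord <- order(-weighted, pairs$gene, method = "radix")
  rnk <- integer(nrow(pairs))
  rnk[ord] <- seq_len(nrow(pairs))

  out <- dplyr::mutate(pairs, eci = eci, weighted_eci = weighted, rank = rnk)
  dplyr::arrange(out, .data$rank)
}

#' Join two differential-expression tables on their shared gene universe
#'
#' Inner-joins two per-gene DE tables (columns `gene`, `effect`, `pvalue`)
#' and reports how many genes were dropped from each side for lacking a
#' partner. The result feeds [build_eci_table()].
#'
#' @param de1,de2 Data frames with columns `gene`, `effect`, `pvalue`.
#' @param quiet Suppress the dropped-genes report.
#'
#' @return A tibble with columns `gene`, `beta1`, `beta2`, `p1`, `p2`.
#' @export
pair_de_tables <- function(de1, de2, quiet = FALSE) {
  de1 <- check_de_table(de1, "de1")
  de2 <- check_de_table(de2, "de2")
  shared <- intersect(de1$gene, de2$gene)
  if (length(shared) < 2) {
    abort("Fewer than 2 genes are shared between the two tables.")
  }
  if (!quiet) {
    d1 <- sum(!de1$gene %in% shared)
    d2 <- sum(!de2$gene %in% shared)
    if (d1 + d2 > 0) {
      inform(paste0("Dropped ", d1, " gene(s) from experiment 1 and ", d2,
                    " from experiment 2 not present in both tables."))
    }
  }
  out <- dplyr::inner_join(
    dplyr::select(de1, gene = "gene", beta1 = "effect", p1 = "pvalue"),
    dplyr::select(de2, gene = "gene", beta2 = "effect", p2 = "pvalue"),
    by = "gene"
  )
  dplyr::select(out, "gene", "beta1", "beta2", "p1", "p2")
}

check_de_table <- function(de, arg) {
  de <- tibble::as_tibble(de)
  need <- c("gene", "effect", "pvalue")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols) > 0) {
    abort(paste0("`", arg, "` is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  dup <- unique(de$gene[duplicated(de$gene)])
  if (length(dup) > 0) {
    abort(paste0("`", arg, "` has duplicate gene identifier(s): ",
                 paste(head(dup, 10), collapse = ", "), "."))
  }
  de
}
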