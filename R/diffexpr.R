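#' Per-gene differential expression for a two-group expression matrix
#'
#' Computes, for every gene, the mean difference between treatment and
#' control samples on the log2 scale (a log2 fold change when the matrix
#' holds log2 intensities) and a Welch two-sample t-test p-value. This is
#' the in-package route from simulated expression matrices to the per-gene
#' effect/p-value tables the ECI consumes; real studies should supply their
#' own tables from limma, DESeq2 or similar.
#'
#' @param values Numeric matrix, genes x samples, with gene ids as row
#'   names; no missing values.
#' @param group Character vector aligned with the columns, containing the
#'   labels `"treatment"` and `"control"`, each at least twice. A list with
#'   elements `values` and `group` (as returned by [read_expression()] or
#'   found in a simulated experiment) may be passed as the first argument
#'   instead.
#'
#' @return A tibble with columns `gene`, `effect`, `pvalue`.
#'
#' @details Degenerate genes with zero variance in both groups get a
#'   p-value of 1 when the group means agree and 0 when they differ (the
#'   limit of the t-test as the pooled variance vanishes).
#' @export
de_table <- function(values, group = NULL) {
  if (is.list(values) && !is.matrix(values) &&
      all(c("values", "group") %in% names(values))) {
    group <- values$group
    values <- values$values
  }
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (genes x samples).")
  }
  if (anyNA(values)) abort("`values` must not contain missing values.")
  if (is.null(rownames(values))) abort("`values` must have gene row names.")
  if (length(group) != ncol(values)) {
    abort("`group` must have one label per sample column.")
  }
  if (!all(group %in% c("treatment", "control"))) {
    abort('`group` labels must be "treatment" or "control".')
  }
  t_idx <- group == "treatment"
  c_idx <- group == "control"
  n1 <- sum(t_idx)
  n2 <- sum(c_idx)
  if (n1 < 2 || n2 < 2) {
    abort("Each group needs at least 2 samples (variance undefined below).")
  }

  x1 <- values[, t_idx, drop = FALSE]
  x2 <- values[, c_idx, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  effect <- m1 - m2

  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  tstat <- effect / sqrt(se2)
  pvalue <- 2 * pt(-abs(tstat), df)
  zero_var <- se2 == 0
  pvalue[zero_var] <- ifelse(effect[zero_var] == 0, 1, 0)

  tibble::tibble(gene = rownames(values), effect = unname(effect),
                 pvalue = unname(pvalue))
}
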