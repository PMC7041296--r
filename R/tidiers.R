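#' Tidy an enrichment result
#'
#' @param x An `ecea_result`.
#' @param ... Unused.
#' @return A plain tibble of the per-pathway results.
#' @method tidy ecea_result
#' @export
tidy.ecea_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "ecea_result")
  for (a in c("statistic", "omega", "n_perm", "seed", "fdr_threshold",
              "universe_size", "labels")) {
    attr(out, a) <- NULL
  }
  out
}

#' One-row summary of an enrichment result
#'
#' @param x An `ecea_result`.
#' @param ... Unused.
#' @return A one-row tibble: pathways tested, enriched calls per direction,
#'   and the engine settings (statistic, omega, permutations, universe size,
#'   FDR threshold).
#' @method glance ecea_result
#' @export
glance.ecea_result <- function(x, ...) {
  labels <- attr(x, "labels")
  tibble::tibble(
    n_pathways = nrow(x),
    n_enriched = sum(x$enriched),
    n_positive = sum(x$enriched & x$direction == labels[["pos"]]),
    n_negative = sum(x$enriched & x$direction == labels[["neg"]]),
    statistic = attr(x, "statistic"),
    omega = attr(x, "omega"),
    n_perm = attr(x, "n_perm"),
    universe_size = attr(x, "universe_size"),
    fdr_threshold = attr(x, "fdr_threshold")
  )
}

#' @export
print.ecea_result <- function(x, ...) {
  cat("Enrichment over ", attr(x, "universe_size"), " genes (statistic: ",
      attr(x, "statistic"), ", omega = ", attr(x, "omega"), ", ",
      attr(x, "n_perm"), " permutations)\n", sep = "")
  cat(sum(x$enriched), " of ", nrow(x), " pathways enriched at FDR <= ",
      attr(x, "fdr_threshold"), "\n", sep = "")
  NextMethod()
  invisible(x)
}
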