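#' Plot an enrichment result as an NES dot chart
#'
#' Pathways ordered by normalized enrichment score, colored by direction,
#' with enriched calls (FDR at or below the threshold) drawn solid.
#'
#' @param object An `ecea_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ecea_result
#' @export
autoplot.ecea_result <- function(object, ...) {
  labels <- attr(object, "labels")
  dat <- tidy(object)
  dat <- dplyr::filter(dat, !is.na(.data$nes))
  dat$pathway <- stats::reorder(dat$pathway, dat$nes)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$nes, y = .data$pathway,
                                    color = .data$direction,
                                    alpha = .data$enriched)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$nes,
                                       yend = .data$pathway)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35),
                                guide = "none") +
    ggplot2::labs(x = "normalized enrichment score", y = NULL,
                  color = "direction",
                  title = paste0("Enrichment (", attr(object, "statistic"),
                                 ", FDR ≤ ",
                                 attr(object, "fdr_threshold"), ")"))
}

#' Running enrichment curve for one pathway
#'
#' Plots `F_S - F_R` along the ranked gene list with a rug of pathway-member
#' positions; the peak of the curve is the signed enrichment score.
#'
#' @inheritParams running_fractions
#' @return A ggplot.
#' @export
plot_running_score <- function(ranked, pathway, omega = 1) {
  fr <- running_fractions(ranked, pathway, omega)
  fr$diff <- fr$f_s - fr$f_r
  peak <- fr[which.max(abs(fr$diff)), ]
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$rank, y = .data$diff)) +
    ggplot2::geom_hline(yintercept = 0, color = "grey60") +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_point(data = peak, color = "firebrick", size = 2) +
    ggplot2::geom_rug(data = dplyr::filter(fr, .data$in_pathway),
                      sides = "b", alpha = 0.5) +
    ggplot2::labs(x = "rank (1 = most equivalently changed)",
                  y = expression(F[S] - F[R]),
                  title = sprintf("Running enrichment (ES = %.3f at rank %d)",
                                  peak$diff, peak$rank))
}

#' Plot benchmark sensitivity or false-positive-rate curves
#'
#' Renders a [run_benchmark()] table as sensitivity (for the planted
#' equivalent/inverse pathways) or FPR (DE-only pathway) against symmetry,
#' one line per `pde` level, faceted by method.
#'
#' @param bench Output of [run_benchmark()].
#' @param metric `"sensitivity"` or `"fpr"`.
#' @param class Truth class to display: `"equivalent"` or `"inverse"` for
#'   sensitivity, `"de_only"` or `"null"` for FPR.
#' @return A ggplot.
#' @export
plot_benchmark <- function(bench, metric = c("sensitivity", "fpr"),
                           class = NULL) {
  metric <- match.arg(metric)
  if (is.null(class)) {
    class <- if (metric == "sensitivity") "equivalent" else "de_only"
  }
  dat <- dplyr::filter(tibble::as_tibble(bench), .data$class == !!class)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$symmetry, y = .data[[metric]],
                                    color = factor(.data$pde),
                                    group = factor(.data$pde))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~method) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "symmetry (P(up-regulated))", y = metric,
                  color = "PDE",
                  title = paste0(metric, " for the ", class, " pathway"))
}
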