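#' Score an enrichment run against simulated ground truth
#'
#' Converts one method's output on one simulated dataset into per-class
#' confusion counts. Detection requires the correct direction: the planted
#' equivalent pathway counts as a true positive only when called enriched in
#' the equivalent (positive) direction, the inverse pathway only in the
#' inverse (negative) direction. The DE-only pathway called in either
#' direction is a false positive, as is any called null pathway.
#'
#' @param results Either an `ecea_result` from [ecea()] (columns `nes`,
#'   `fdr`) or an intersection-call tibble from [gsea_intersection()] /
#'   [ora_intersection()] (column `relationship`).
#' @param truth The pathway-label tibble (`pathway`, `label`) from a
#'   simulated dataset, or the `ec_simulation` object itself.
#' @param fdr_threshold Call threshold applied to `ecea_result` FDRs (calls
#'   tibbles are already thresholded).
#'
#' @return A tibble with one row per truth class (`equivalent`, `inverse`,
#'   `de_only`, `null`) and integer columns `tp`, `fp`, `tn`, `fn`.
#' @export
score_run <- function(results, truth, fdr_threshold = 0.25) {
  if (inherits(truth, "ec_simulation")) truth <- truth$truth$pathways
  truth <- tibble::as_tibble(truth)
  if (!all(c("pathway", "label") %in% names(truth))) {
    abort("`truth` needs columns `pathway` and `label`.")
  }
  res <- tibble::as_tibble(results)

  if ("relationship" %in% names(res)) {
    if (!all(res$pathway %in% truth$pathway)) {
      abort("Calls mention pathways absent from the truth labels.")
    }
    called_eq <- res$pathway[res$relationship == "equivalent"]
    called_inv <- res$pathway[res$relationship == "inverse"]
  } else if (all(c("nes", "fdr") %in% names(res))) {
    if (!all(truth$pathway %in% res$pathway)) {
      abort("Results do not cover every truth pathway.")
    }
    hit <- !is.na(res$fdr) & res$fdr <= fdr_threshold & !is.na(res$es)
    called_eq <- res$pathway[hit & res$es > 0]
    called_inv <- res$pathway[hit & res$es < 0]
  } else {
    abort("`results` is neither an enrichment result nor a calls table.")
  }
  called_any <- union(called_eq, called_inv)

  eq_path <- truth$pathway[truth$label == "equivalent"]
  inv_path <- truth$pathway[truth$label == "inverse"]
  de_path <- truth$pathway[truth$label == "de_only"]
  null_paths <- truth$pathway[truth$label == "null"]

  count <- function(class) {
    switch(class,
      equivalent = {
        tp <- sum(eq_path %in% called_eq)
        c(tp = tp, fp = 0L, tn = 0L, fn = length(eq_path) - tp)
      },
      inverse = {
        tp <- sum(inv_path %in% called_inv)
        c(tp = tp, fp = 0L, tn = 0L, fn = length(inv_path) - tp)
      },
      de_only = {
        fp <- sum(de_path %in% called_any)
        c(tp = 0L, fp = fp, tn = length(de_path) - fp, fn = 0L)
      },
      null = {
        fp <- sum(null_paths %in% called_any)
        c(tp = 0L, fp = fp, tn = length(null_paths) - fp, fn = 0L)
      })
  }
  classes <- c("equivalent", "inverse", "de_only", "null")
  counts <- t(vapply(classes, count, integer(4)))
  tibble::tibble(class = classes,
                 tp = unname(counts[, "tp"]), fp = unname(counts[, "fp"]),
                 tn = unname(counts[, "tn"]), fn = unname(counts[, "fn"]))
}

#' Benchmark ECEA and its baselines over a simulation grid
#'
#' Sweeps the full factorial grid of differential-expression probability
#' (`pde`), up/down `symmetry` and cross-experiment coupling (`p_match`),
#' simulating `reps` datasets per cell, running each requested method, and
#' aggregating confusion counts per cell, method and truth class.
#' Sensitivity is reported for the planted equivalent and inverse pathways
#' and the false-positive rate for the DE-only and null pathways.
#'
#' @param pde_grid,symmetry_grid,p_match_grid Grid coordinates
#'   (probabilities in (0, 1)).
#' @param reps Simulated datasets per grid cell.
#' @param methods Any of `"ecea"`, `"gsea"` (GSEA-intersection), `"ora"`
#'   (ORA-intersection).
#' @param seed Base seed; every dataset and permutation stream derives from
#'   it deterministically.
#' @param base_config A [sim_config()] for the non-grid simulation
#'   parameters.
#' @param n_perm Permutations per enrichment run.
#' @param fdr_threshold Enrichment call threshold.
#' @param verbose Print per-cell progress.
#'
#' @return A long tibble with columns `pde`, `symmetry`, `p_match`,
#'   `method`, `class`, `tp`, `fp`, `tn`, `fn`, `sensitivity` (equivalent /
#'   inverse rows) and `fpr` (de_only / null rows), summed over reps.
#' @export
run_benchmark <- function(pde_grid = 0.5, symmetry_grid = 0.5,
                          p_match_grid = 0.5, reps = 20,
                          methods = c("ecea", "gsea", "ora"), seed = 1,
                          base_config = sim_config(), n_perm = 1000,
                          fdr_threshold = 0.25, verbose = FALSE) {
  methods <- match.arg(methods, c("ecea", "gsea", "ora"), several.ok = TRUE)
  base_config$seed <- seed
  grid <- grid_configs(base_config, pde_grid, symmetry_grid, p_match_grid,
                       reps = reps)

  rows <- purrr::pmap(grid, function(pde, symmetry, p_match, rep, seed) {
    cfg <- base_config
    cfg$pde <- pde
    cfg$symmetry <- symmetry
    cfg$p_match <- p_match
    cfg$seed <- seed
    sim <- simulate_dataset(cfg)
    de1 <- de_table(sim$expr1)
    de2 <- de_table(sim$expr2)
    truth <- sim$truth$pathways

    purrr::map(setNames(methods, methods), function(m) {
      scores <- switch(m,
        ecea = {
          tab <- build_eci_table(pair_de_tables(de1, de2, quiet = TRUE))
          res <- ecea(tab, sim$gene_sets, n_perm = n_perm,
                      fdr_threshold = fdr_threshold, seed = seed + 1L,
                      quiet = TRUE)
          score_run(res, truth, fdr_threshold)
        },
        gsea = {
          r1 <- gsea_single(de1, sim$gene_sets, n_perm = n_perm,
                            fdr_threshold = fdr_threshold, seed = seed + 2L,
                            quiet = TRUE)
          r2 <- gsea_single(de2, sim$gene_sets, n_perm = n_perm,
                            fdr_threshold = fdr_threshold, seed = seed + 3L,
                            quiet = TRUE)
          score_run(gsea_intersection(r1, r2, fdr_threshold), truth)
        },
        ora = {
          score_run(ora_intersection(de1, de2, sim$gene_sets,
                                     pathway_fdr = fdr_threshold,
                                     quiet = TRUE), truth)
        })
      dplyr::mutate(scores, method = m, pde = pde, symmetry = symmetry,
                    p_match = p_match, .before = 1)
    }) |> dplyr::bind_rows()
  })
  if (verbose) inform(paste0("Scored ", nrow(grid), " simulated datasets."))

  out <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$pde, .data$symmetry, .data$p_match,
                    .data$method, .data$class),
    dplyr::across(c("tp", "fp", "tn", "fn"), sum),
    .groups = "drop"
  )
  dplyr::mutate(
    out,
    sensitivity = ifelse(.data$class %in% c("equivalent", "inverse"),
                         .data$tp / (.data$tp + .data$fn), NA_real_),
    fpr = ifelse(.data$class %in% c("de_only", "null"),
                 .data$fp / (.data$fp + .data$tn), NA_real_)
  )
}
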