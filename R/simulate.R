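#' Simulation configuration
#'
#' Collects and validates the parameters of the paired-experiment expression
#' simulator. The default design follows the benchmark layout: ten disjoint
#' pathways (one equivalently changed, one inversely changed, one enriched
#' for differential expression with no cross-experiment coupling, and seven
#' unaffected), five treated and five control samples per experiment.
#'
#' @param pde Probability that a gene of an affected pathway is
#'   differentially expressed in experiment 1 (and, for the DE-only pathway,
#'   independently in experiment 2).
#' @param symmetry Probability that an affected gene is up- rather than
#'   down-regulated; 0.5 is balanced, extremes produce co-expressed blocks.
#' @param p_match Probability that a gene differentially expressed in
#'   experiment 1 receives the same (equivalent pathway) or negated (inverse
#'   pathway) planted effect in experiment 2; uncoupled genes receive no
#'   experiment-2 effect.
#' @param n_null_pathways Number of unaffected background pathways.
#' @param genes_per_pathway Genes per pathway.
#' @param n_treat,n_control Samples per arm and experiment (each >= 2).
#' @param effect_low,effect_high Bounds of the uniform distribution of
#'   planted absolute log2 fold changes.
#' @param rho Within-pathway equicorrelation of the baseline expression
#'   (one-factor Gaussian construction), `0 <= rho < 1`.
#' @param sigma Residual noise scale (log2 units).
#' @param baseline_mean,baseline_sd Per-gene baseline means are drawn from
#'   `N(baseline_mean, baseline_sd)`, shared across experiments.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(pde = 0.5, symmetry = 0.5, p_match = 0.5,
                       n_null_pathways = 7, genes_per_pathway = 50,
                       n_treat = 5, n_control = 5,
                       effect_low = 0.5, effect_high = 2,
                       rho = 0.3, sigma = 1,
                       baseline_mean = 7, baseline_sd = 1,
                       seed = 1) {
  cfg <- list(pde = pde, symmetry = symmetry, p_match = p_match,
              n_null_pathways = n_null_pathways,
              genes_per_pathway = genes_per_pathway,
              n_treat = n_treat, n_control = n_control,
              effect_low = effect_low, effect_high = effect_high,
              rho = rho, sigma = sigma,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              seed = seed)
  for (p in c("pde", "symmetry", "p_match")) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      abort(paste0("`", p, "` must be a probability in [0, 1]."))
    }
  }
  if (cfg$n_null_pathways < 1) abort("`n_null_pathways` must be >= 1.")
  if (cfg$genes_per_pathway < 2) abort("`genes_per_pathway` must be >= 2.")
  if (cfg$n_treat < 2 || cfg$n_control < 2) {
    abort("Each arm needs at least 2 samples.")
  }
  if (cfg$effect_low <= 0 || cfg$effect_high < cfg$effect_low) {
    abort("Need 0 < effect_low <= effect_high.")
  }
  if (cfg$rho < 0 || cfg$rho >= 1) abort("`rho` must be in [0, 1).")
  if (cfg$sigma <= 0) abort("`sigma` must be positive.")
  structure(cfg, class = "sim_config")
}

#' Simulate a paired two-experiment expression dataset with planted pathways
#'
#' Generates log2-scale expression matrices for two treatment-vs-control
#' experiments over a shared gene universe partitioned into disjoint
#' pathways. Baseline expression within each pathway is equicorrelated
#' (correlation `rho`) via a one-factor Gaussian construction; treatment
#' effects are planted per the pathway label:
#'
#' * `equivalent`: a gene is DE in experiment 1 with probability `pde`
#'   (sign up with probability `symmetry`, magnitude uniform on
#'   `[effect_low, effect_high]`); with probability `p_match` the identical
#'   effect is planted in experiment 2, otherwise experiment 2 is untouched.
#' * `inverse`: as above with the experiment-2 effect negated.
#' * `de_only`: genes are DE independently in each experiment with
#'   probability `pde` (no cross-experiment coupling) — the false-positive
#'   probe.
#' * `null1..nullK`: no planted effects.
#'
#' @param config A [sim_config()].
#'
#' @return A list of class `ec_simulation` with elements `expr1`, `expr2`
#'   (each a list with `values` matrix and `group` labels), `gene_sets`
#'   (named list partitioning the universe), `truth` (list with the
#'   pathway-label tibble `pathways` and the per-gene planted-effect tibble
#'   `genes`), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  labels <- c("equivalent", "inverse", "de_only",
              paste0("null", seq_len(config$n_null_pathways)))
  n_path <- length(labels)
  gpp <- config$genes_per_pathway
  n_genes <- n_path * gpp
  genes <- sprintf("g%04d", seq_len(n_genes))
  pathway_of <- rep(labels, each = gpp)
  gene_sets <- split(genes, factor(pathway_of, levels = labels))
  label_of <- ifelse(grepl("^null", labels), "null", labels)

  # planted effects per gene and experiment
  eff1 <- eff2 <- numeric(n_genes)
  draw_effects <- function(n) {
    de <- rbinom(n, 1, config$pde) == 1
    sgn <- ifelse(runif(n) < config$symmetry, 1, -1)
    mag <- runif(n, config$effect_low, config$effect_high)
    ifelse(de, sgn * mag, 0)
  }
  for (i in seq_along(labels)) {
    idx <- which(pathway_of == labels[i])
    lab <- label_of[i]
    if (lab %in% c("equivalent", "inverse")) {
      e1 <- draw_effects(gpp)
      coupled <- runif(gpp) < config$p_match
      e2 <- ifelse(e1 != 0 & coupled, if (lab == "equivalent") e1 else -e1, 0)
      eff1[idx] <- e1
      eff2[idx] <- e2
    } else if (lab == "de_only") {
      eff1[idx] <- draw_effects(gpp)
      eff2[idx] <- draw_effects(gpp)
    }
  }

  mu <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)

  make_experiment <- function(effects, tag) {
    n_s <- config$n_treat + config$n_control
    group <- rep(c("treatment", "control"), c(config$n_treat, config$n_control))
    vals <- matrix(0, n_genes, n_s,
                   dimnames = list(genes, paste0(tag, "_s", seq_len(n_s))))
    for (i in seq_along(labels)) {
      idx <- which(pathway_of == labels[i])
      z <- rnorm(n_s)                       # shared pathway factor per sample
      eps <- matrix(rnorm(length(idx) * n_s), length(idx), n_s)
      noise <- config$sigma *
        (sqrt(config$rho) * matrix(z, length(idx), n_s, byrow = TRUE) +
           sqrt(1 - config$rho) * eps)
      vals[idx, ] <- mu[idx] + noise +
        outer(effects[idx], as.numeric(group == "treatment"))
    }
    list(values = vals, group = group)
  }

  structure(list(
    expr1 = make_experiment(eff1, "e1"),
    expr2 = make_experiment(eff2, "e2"),
    gene_sets = gene_sets,
    truth = list(
      pathways = tibble::tibble(
        pathway = labels,
        label = label_of
      ),
      genes = tibble::tibble(
        gene = genes, pathway = pathway_of,
        label = rep(label_of, each = gpp),
        effect1 = eff1, effect2 = eff2
      )
    ),
    config = config
  ), class = "ec_simulation")
}

#' Enumerate simulation configurations over a parameter grid
#'
#' Produces one configuration per grid cell and repetition, with a
#' deterministic derived seed per row, suitable for full-factorial benchmark
#' sweeps (the full 9 x 9 x 9 grid with 100 repetitions enumerates 72,900
#' configurations).
#'
#' @param base A [sim_config()] providing every non-grid parameter and the
#'   base seed.
#' @param pde_grid,symmetry_grid,p_match_grid Numeric vectors of
#'   probabilities in (0, 1).
#' @param reps Repetitions per grid cell.
#'
#' @return A tibble with columns `pde`, `symmetry`, `p_match`, `rep` and
#'   `seed` (distinct per row, derived from the base seed).
#' @export
grid_configs <- function(base = sim_config(), pde_grid = seq(0.1, 0.9, 0.1),
                         symmetry_grid = seq(0.1, 0.9, 0.1),
                         p_match_grid = seq(0.1, 0.9, 0.1), reps = 1) {
  if (!inherits(base, "sim_config")) abort("`base` must be a `sim_config`.")
  for (g in list(pde_grid, symmetry_grid, p_match_grid)) {
    if (length(g) == 0 || any(g <= 0 | g >= 1)) {
      abort("Grids must be non-empty with values strictly inside (0, 1).")
    }
  }
  if (reps < 1) abort("`reps` must be >= 1.")
  out <- tidyr::expand_grid(pde = pde_grid, symmetry = symmetry_grid,
                            p_match = p_match_grid, rep = seq_len(reps))
  out$seed <- (as.integer(base$seed) %% 100000L) + 7919L * seq_len(nrow(out))
  out
}
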