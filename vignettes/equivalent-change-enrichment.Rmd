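---
title: "Equivalent change enrichment: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equivalent change enrichment: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`eqenrich` compares two treatment-versus-control experiments gene by gene
and asks which pathways are enriched for genes that changed *equivalently*
(same direction and similar magnitude) or *inversely* (similar magnitude,
opposite direction). This vignette is the package's account of the model,
of every tunable that matters, of the numerical choices in the
implementation, and of what the simulation-based tests do and do not
establish about real data.

```{r setup, message = FALSE}
library(eqenrich)
```

## The gene-level model

The inputs are two per-gene differential-expression tables over a shared
gene universe: an effect size (log2 fold change, standardized or plain mean
difference — any scale, as long as both experiments use the same one) and
the p-value of its test. For gene $i$ the equivalent change index is

$$
\mathrm{ECI}_i \;=\; \operatorname{sign}(\hat\beta_{i1}\hat\beta_{i2})\,
\frac{\min(|\hat\beta_{i1}|,|\hat\beta_{i2}|)}
     {\max(|\hat\beta_{i1}|,|\hat\beta_{i2}|)} \in [-1, 1].
$$

The index is symmetric in the two experiments, invariant to a common
positive rescaling, and flips sign when one effect is reflected. It carries
*concordance*, not direction: a gene down-regulated 2-fold by both
treatments scores +1 exactly like a gene up-regulated 2-fold by both. When
either estimated effect is exactly zero the index is defined as 0 — the
printed ratio is 0/0 at (0, 0), and "no evidence of change in either
experiment" is the only reading consistent with the statistic's purpose;
sign(0) forces the same value when exactly one effect vanishes.

Because a large ECI can arise from two noisy estimates, each index is
weighted by $1 - \max(p_{i1}, p_{i2})$: a gene keeps its ECI only when
*both* experiments measured its change with confidence. Genes missing a
p-value keep weight 1 (with a warning) rather than being dropped — the
weighting is a refinement, not a requirement for the index to exist.

### Ranking

Genes are ranked by the *weighted* ECI, in decreasing order, ties broken by
gene identifier so the ordering is reproducible. Ranking by the raw ECI and
weighting only inside the enrichment statistic would be defensible too; we
rank by the weighted index so that the ordering and the weights that enter
the running sum cannot disagree — otherwise a high-ECI gene with
uninformative p-values would occupy a top rank while contributing zero
weight, distorting the running fractions around it.

## The pathway-level test

With genes ranked $1..G$, membership indicator $I_h$ for a pathway $S$ and
complement $R$, the running fractions are

$$
F_S(x) = \frac{\sum_{h \le x} I_h\,|\widehat{\mathrm{ECI}}_{g(h)}|^{\omega}}
              {\sum_{h \le G} I_h\,|\widehat{\mathrm{ECI}}_{g(h)}|^{\omega}},
\qquad
F_R(x) = \frac{1}{|R|} \sum_{h \le x} (1 - I_h),
$$

and the enrichment score is the value of $F_S - F_R$ at the rank where
$|F_S - F_R|$ is maximal. At $\omega = 0$ its magnitude is exactly the
classical two-sample Kolmogorov–Smirnov statistic between in- and
out-of-pathway ranks (the test suite verifies this against a brute-force
KS oracle over every membership pattern of small universes). The default
$\omega = 1$ weights in-pathway genes by their statistic's magnitude, the
same device GSEA uses to blunt the KS test's sensitivity to inter-gene
correlation. Only in-pathway weights enter $F_S$; out-of-pathway statistics
influence nothing but the ordering.

Although the supremum itself is unsigned, the score keeps the sign of
$F_S - F_R$ at the supremum: positive means concentration at the
equivalently changed top, negative at the inversely changed bottom. This
matches how normalized scores for inversely changed pathways are
conventionally reported. When several ranks attain the supremum the
earliest rank wins — a fixed, documented tie-break.

### Null distribution, NES, FDR

Sample-label permutation is unavailable to a statistic that already
condenses two experiments into one number per gene, so significance comes
from a *gene-sampling* null: enrichment scores of random gene sets of the
same size drawn without replacement from the universe. Scores are
normalized sign-stratified — NES = ES / mean |same-sign null scores| — and
the p-value is the one-sided empirical tail within the same-sign null with
a +1 pseudo-count in numerator and denominator, so no p-value is exactly
zero and a score beating all $k$ same-sign nulls gets $1/(k+1)$. If no
same-sign null score exists the result is flagged and the p-value falls
back to the pooled two-sided null. False discovery rates are
Benjamini–Hochberg across all tested pathways; the "scaling" of the raw
statistic is exactly this normalization. The ratio-of-tails FDR used by
the 2005 GSEA implementation would be an alternative; BH is simpler,
better understood, and the two rarely disagree at the 0.25 call threshold.

Pathways are intersected with the universe before testing (absent genes
silently dropped, counts reported), sets covering the whole universe are
rejected as degenerate, and size bounds of 10–500 genes apply by default —
conventional enrichment practice; no bounds are inherent to the statistic.
Null score vectors are cached per pathway size within a call, which is
exact (the null depends only on size) and makes collections with many
same-size sets cheap.

## Parameters that matter

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `omega` | 1 | exponent, ≥ 0 | weighted KS; 0 recovers the classical KS statistic |
| `n_perm` | 1000 | permutations | p-value floor 1/(k+1) ≈ 0.002 comfortably below the 0.25 FDR call threshold |
| `min_size`, `max_size` | 10, 500 | genes | conventional enrichment bounds; below 10 the KS statistic is dominated by single genes |
| `fdr_threshold` | 0.25 | BH FDR | the conventional, deliberately permissive enrichment cut-off |
| `n_top` | 5 | genes | reported leading genes in the direction of enrichment |
| `gene_fdr` (ORA) | 0.05 | BH FDR | customary gene-level significance for list-based ORA |

## The simulator

`simulate_dataset()` emulates the structure the method targets: two
experiments, 5 treated + 5 control samples each, a universe of 500 genes
partitioned into ten disjoint 50-gene pathways — one planted *equivalent*,
one *inverse*, one *DE-only* (differentially expressed in each experiment
independently, with no cross-experiment coupling) and seven untouched
background pathways. Within a pathway, baseline log2 expression is
equicorrelated at `rho` through a one-factor Gaussian construction
(`x = sqrt(rho) z_s + sqrt(1-rho) ε`), which hits the target correlation
exactly and cheaply; pathways are mutually independent and non-overlapping
by design. Planted effects: a pathway gene is DE in experiment 1 with
probability `pde`, up-regulated with probability `symmetry`, with magnitude
uniform on [`effect_low`, `effect_high`]; with probability `p_match` the
*same* effect (negated, for the inverse pathway) is planted in experiment 2,
otherwise experiment 2 receives none. Coupling conditional on experiment-1
DE, with "no effect" for uncoupled genes, is the reading of
equivalent-change probability adopted here; an independent re-draw in
experiment 2 would blur the equivalent/DE-only distinction the benchmark
depends on.

Values the design left open were fixed once at what a microarray-scale
study would call realistic and are all exposed in `sim_config()`: 50 genes
per pathway, |log2FC| ~ U(0.5, 2), `rho = 0.3`, `sigma = 1`, baselines
N(7, 1) shared across experiments. Effect sizes and p-values are then
estimated from the simulated matrices by group mean difference and Welch's
t-test (`de_table()`); with Gaussian data and ≥ 3 replicates a moderated
test would change essentially nothing, and real studies supply their own
DE tables anyway.

What the simulator does *not* emulate: count noise and mean–variance
coupling of RNA-seq, overlapping pathways, inter-pathway correlation,
batch effects, and effect-size distributions with heavy tails. Passing
tests therefore demonstrate correctness of the machinery and its behaviour
under controlled concordance, correlation and symmetry — not performance
on any particular real dataset.

## Benchmarking and its two honest wrinkles

`run_benchmark()` sweeps `pde` × `symmetry` × `p_match`, runs ECEA,
GSEA-intersection and ORA-intersection per simulated dataset, and scores
detection with direction required: the equivalent pathway counts only when
called with positive NES, the inverse only with negative NES — the stricter
reading of "detected", and the one the direction labels imply. The DE-only
pathway called in either direction is a false positive. Desk-scale defaults
(20 repetitions per cell; the tests use 1000 permutations and universes of
500–1000 genes) keep full runs in minutes; the 9×9×9×100 grid enumeration
is exact bookkeeping (`grid_configs()`, 72,900 configurations with
distinct derived seeds) and is not simulated by default.

Two behaviours deserve explicit framing rather than silent assertion:

1. **Extreme symmetry makes the DE-only label semantically false.** With
   independent DE in both experiments at symmetry $s$, a gene DE in both is
   concordant with probability $s^2 + (1-s)^2$ — 0.82 at $s = 0.1$. At high
   `pde` the "DE-only" pathway then genuinely fills with equivalently
   changed genes, and an equivalent-change detector *should* flag it; its
   false-positive rate against the truth label rises accordingly. The
   false-positive property is therefore asserted at balanced symmetry
   (0.5), where concordance-by-chance is at its minimum and the label means
   what it says.
2. **Within-pathway correlation inflates the gene-sampling null.** The
   permutation null treats genes as exchangeable; correlated blocks
   occasionally ride a shared noise factor into coherent ECI blocks that
   the null cannot explain. This is the familiar KS/GSEA sensitivity to
   dependence — $\omega = 1$ blunts but does not remove it. Calibration
   properties (uniform null p-values, FDR-threshold-bounded false-positive
   fraction) are asserted under independence, the regime the null actually
   models; under `rho = 0.3` background pathways cross the permissive 0.25
   threshold more often than the nominal rate, as the README example shows.

## Numerical and degenerate-input choices

* ECI at zero effects: 0 (see above); non-finite effects are rejected.
* Ranking ties: lexicographic by gene id; supremum ties: earliest rank.
* A pathway sharing no genes with the universe, or equal to it, is an
  error (the latter is dropped with a warning inside `ecea()` so one bad
  set does not kill a collection).
* All in-pathway weights zero at $\omega > 0$ is an error pointing at the
  p-value weighting; inside the permutation loop a zero-weight random set
  falls back to unweighted proportions instead (a measure-zero event for
  continuous statistics).
* The enrichment score is computed in O(|S|) from member positions (the
  supremum can only occur at a member rank, just before one, or at the end
  of the list); the step-function path and the fast path are verified
  equal in the tests.
* Reproducibility: every stochastic entry point takes a seed; derived
  seeds (grid rows, per-method offsets) stay below $2^{31}$.

## Known limitations

Beyond the two wrinkles above: the ECI compares *estimated* effects, so
with few replicates its sign is noisy for small effects (at |log2FC| = 0.5,
σ = 1 and n = 5 per arm, each experiment's estimate has standard error
≈ 0.63); the p-value weighting, not the index itself, is what keeps such
genes from driving enrichment. The method consumes two experiments only;
more than two would need a different index. No leading-edge analysis
beyond the reported top genes, and no multilevel p-value refinement — at
`n_perm = 1000` the p-value floor of ≈ 0.002 is adequate for a 0.25 FDR
call threshold but not for ranking deeply significant pathways against
each other.
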