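---
title: "Inferring lncRNA–TF ceRNA networks, modules and prognosis with cernaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring lncRNA-TF ceRNA networks, modules and prognosis with cernaforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaforge)
library(dplyr)
```

## The model

Competing endogenous RNA (ceRNA) theory holds that transcripts sharing
miRNA-response elements compete for a limited pool of miRNAs, so a
lncRNA that sponges the miRNAs targeting a transcription factor (TF)
indirectly de-represses that TF. Two observable signatures follow, and
both are required here before a lncRNA–TF pair is called a ceRNA pair:

1. **Shared-miRNA excess.** With a universe of `N` miRNAs, a lncRNA
   targeted by `m_l` of them and a TF targeted by `m_t`, the number of
   shared miRNAs under independence is hypergeometric. The pair statistic
   is the upper tail `P(X >= k)` with `X ~ Hypergeom(N, m_l, m_t)`,
   evaluated by `hypergeom_upper_tail()` through `stats::phyper()`
   (log-space internally). Pairs with `p < 0.05` pass.
2. **Co-expression.** Sponging implies positive coupling of the two
   transcripts' abundances, so the surviving pairs are filtered by
   Pearson correlation `PCC > 0.6` across the expression cohort.

Both thresholds are *strict* inequalities — a pair at exactly `p = 0.05`
or `PCC = 0.6` is dropped. No multiple-testing correction is applied to
the pair p-values by default (the procedure screens, the correlation
filter disciplines); Benjamini–Hochberg adjustment is available in the
over-representation helper where it is conventional. The retained pairs
plus TF–TF protein–protein interaction (PPI) edges form a mixed, typed
network (`assemble_network()`): ceRNA edges are always lncRNA–TF, PPI
edges always TF–TF, self-loops and duplicates are removed. By default
PPI edges are restricted to TFs already present in a significant ceRNA
pair (`include_all_ppi = TRUE` lifts this), because otherwise the PPI
catalogue — not the ceRNA evidence — would dominate the node set.

The miRNA universe `N` defaults to the union of source miRNAs observed
in both interaction tables and can be fixed by the caller (e.g. 386 for
a StarBase-scale catalogue). Whether correlations should use all samples
or tumor-only is a genuinely open choice; the functions take whatever
expression matrix they are given, so the caller subsets columns to pick
the convention.

## Topology and the rewiring null

`degree_distribution_fit()` regresses `log10 f(k)` on `log10 k` over
degrees `k >= 1` with positive frequency and reports slope, intercept
and R². This is the network-analyzer convention, chosen deliberately
over maximum-likelihood exponent estimation because an R² only exists
for the regression formulation; it needs at least three distinct degree
classes and errors otherwise (a star graph is the canonical degenerate
input).

`average_path_length()` averages BFS distances over unordered pairs of
distinct nodes *within the same component* — the common tool default,
needed because thresholded biological networks are routinely
disconnected. The null model (`apl_null_test()`) generates
degree-conserved random networks by repeated double-edge swaps
(`rewire_degree_preserving()`), performed independently per edge-type
class so that ceRNA edges stay bipartite and PPI edges stay TF–TF; a
swap is rejected if it would create a self-loop or duplicate edge. The
swap loop is a small C++ routine because a thousand replicates at ten
attempted swaps per edge is the standard budget and graph randomisation
is exactly where mature network packages drop to compiled code. The
empirical p is the count of replicates with strictly shorter APL divided
by the replicate number — no +1 continuity correction, because the
plain-ratio definition is the one being reproduced; at `n_random = 1000`
a p of 0 should be read as `p < 0.001`.

Hubs (`select_hubs()`) are the top `floor(fraction × |V|)` nodes by
degree, default fraction 0.10; ties at the cutoff break by higher
betweenness, then lexicographic id, making the selection deterministic
and order-independent. `hub_subnetwork()` is the vertex-induced subgraph.

## MCODE-style module detection

`mcode()` implements the classic two-phase molecular-complex detection:

* **Vertex weighting** (`mcode_vertex_weights()`): for each node `v`
  with degree ≥ `degree_cutoff` (default 2), take `v` plus its
  sufficiently-connected neighbors, find the highest k-core of that
  neighborhood graph, and set
  `weight(v) = k_max × density(core)` (loop-free density
  `2|E|/(|V||V−1|)`). The center of a K₅ therefore weighs
  `4 × 1 = 4.0`; isolated and pendant nodes weigh 0.
* **Complex prediction**: seeds are unvisited nodes in decreasing weight
  order (ties: higher degree, then id); expansion is breadth-first to
  `max_depth` (default 100), admitting a neighbor `w` when
  `weight(w) > seed_weight × (1 − node_score_cutoff)` with
  `node_score_cutoff = 0.2`; nodes join at most one complex.
  Post-processing drops complexes with an empty 2-core (`k_core = 2`),
  removes singly-connected nodes when `haircut = TRUE` (the default;
  `fluff` is off by default), keeps the largest component if trimming
  disconnected the complex, and finally retains complexes with
  `score = density × size` strictly greater than `score_min = 5`.

On cliques the score equals the clique size, which makes the filter
interpretable: `score > 5` keeps K₆ and larger (or comparably dense,
larger-but-sparser groups) and discards triangles. The defaults mirror
the conventional desktop-tool settings; the haircut/fluff flags are
exposed because published analyses rarely state them and module
membership can depend on them.

## Risk scores and survival

`cox_screen()` fits one univariate Cox proportional-hazards model per
gene via the survival package with Efron handling of tied event times
(better than Breslow under ties, and ties are guaranteed in day-resolution
registry data). Wald CIs and p-values are reported, matching forest-plot
convention; monotone-likelihood non-convergence is flagged
(`converged = FALSE`) rather than errored inside a screen.

The module risk score is the linear combination
`score_s = Σ_i r_i · Exp_{i,s}` over the module's genes with the fitted
Cox coefficients as weights (`risk_score()`). `stratify_by_mean()`
splits at the cohort mean: strictly greater is high-risk, everything
else — including exact ties, which the greater/less-than phrasing leaves
unassigned — goes low, for determinism. `module_prognosis()` chains
fit → score → split → Kaplan–Meier → log-rank; per-gene coefficients are
fitted on the analysis subset by default (`coef_source = "full"` uses
the whole cohort instead, since either reading of the procedure is
defensible). Overall survival is the intended endpoint. The tumor-vs-
normal comparisons for hub genes use the Wilcoxon rank-sum test by
default (robust on log expression, exact for small untied samples,
normal approximation with tie correction otherwise); a t-test is
selectable.

## PWM scanning with exact p-values

`pwm_scan()` scores every window on both strands as
`Σ_j log2(pwm[j, base_j] / background[base_j])`. Zero matrix entries get
a 1e-3 pseudocount so scores stay finite; scores are discretised on a
1/1000 grid and the *exact* null distribution of the discretised window
score under the 0-order background model is computed by dynamic
programming (column-by-column convolution). The p-value of a hit is the
exact tail probability of its score; hits with `p < 1e-4` (strict) are
reported. Windows containing non-ACGT letters are skipped; a motif wider
than the sequence returns an empty table, not an error. The background
defaults to uniform, the common scanner default, and can be replaced by
observed base composition.

One consequence of exactness worth knowing: the score distribution is
discrete, so the achieved level of the test is at most — and often
noticeably below — the nominal threshold. At width 6 under a uniform
background no word can reach `p < 1e-4` at all (the smallest possible
tail is `4^-6 ≈ 2.4e-4`), and for a sharp width-8 motif the achieved
level sits near `1.5e-5`. The familiar `2·L·threshold` estimate of
false hits on background is therefore an upper bound; the tests calibrate
observed false-hit counts against the achieved level obtained by
enumerating all `4^w` words independently of the scanner.

Promoters (`promoter_regions()`) are `[TSS − 2000, TSS + 2000)` in
0-based half-open coordinates with the TSS at `start` on `+` genes and
`end − 1` on `−` genes, clipped at contig boundaries (so a promoter is
4 kb wide unless clipped). Enhancer-to-lncRNA assignment is taken from
an explicit `region_id → gene_id` table — no distance heuristic is baked
in, because there is no single community convention. Likewise motifs map
to TFs through an explicit two-column table, since motif databases key
by motif id, not gene id.

`build_crosstalk_network()` then keeps a ceRNA edge (lncRNA, TF) of the
top-20% hub lncRNAs (by degree, same tie policy as hub selection) iff
the TF has at least one hit in a region linked to that lncRNA; its edge
set is a subset of the input ceRNA edges by construction.

## What the synthetic data emulate — and what they do not

The generators produce inputs whose statistical structure matches each
stage's assumptions exactly, so planted signal is recoverable and null
features are calibrated:

* `generate_interactions()` wires each miRNA to each target
  independently at `baseline_rate`, then adds `shared_boost` common
  miRNAs to both members of every planted pair — guaranteeing overlap
  excess while non-planted pairs satisfy the hypergeometric null.
* `generate_expression()` induces pair correlation through a shared
  standard-normal latent factor
  (`x = √ρ·z_shared + √(1−ρ)·z_own`), which hits the target
  correlation exactly in expectation and is trivial to verify; group
  differences are additive mean shifts on designated genes.
* `generate_survival()` draws exponential event times with hazard
  `baseline_hazard × exp(Σ coef·expr)` and independent exponential
  censoring — proportional hazards holds by construction and closed-form
  checks exist (null cohorts are i.i.d. exponential).
* `generate_regions_with_motifs()` writes the motif *consensus* at
  planted sites (reverse-complemented on `−`), rather than sampling from
  the PWM, guaranteeing a maximal-score, recoverable site.

Default study conditions used throughout the tests and the acceptance
script, fixed once: a 386-miRNA universe, `baseline_rate = 0.05`,
`shared_boost = 8`, `ρ = 0.8`, 400 expression samples (the pair-recovery
runs use 25 lncRNAs × 20 TFs with 10 planted pairs, enough non-planted
pairs to bound the false-positive rate); survival effects at hazard
ratio 3 with exponential censoring around 20–40%; sharp (0.97-max)
planted motifs. Simulation sizes (20 seeds for recovery runs, 1000
rewiring replicates on a 300-node network, 100–200 background sequences
for scanner calibration) were chosen as the smallest runs whose pass/fail
criteria have sound statistical coverage.

These data deliberately do **not** mimic real TCGA-scale marginals:
no batch effects, no library-size or GC artefacts, no subtype-correlated
expression structure, no dependent censoring, and genes belong to at
most one planted pair (a gene in several ceRNA pairs would need a
multi-factor covariance model). Passing tests therefore demonstrate that
the procedures recover the structure they assume, with calibrated error
rates — not that the biological claims of any particular cohort would
replicate.

## Numerical choices and degenerate inputs

* Hypergeometric tails come from `phyper(k−1, …, lower.tail = FALSE)`;
  invalid configurations (`k > min(m_l, m_t)`, `m > N`) are errors, and
  `k = 0` returns exactly 1.
* Correlations use pairwise-complete observations, require ≥ 3 pairs and
  error on zero variance; inside the pair filter an undefined correlation
  drops the pair (with a count message) instead of aborting the run.
* The rewiring routine warns and returns a copy when the graph is too
  constrained to swap (e.g. a triangle); replicate seeds are derived from
  the master seed so the null is reproducible end to end.
* Score discretisation at 1/1000 of a log2 unit keeps the DP exact with
  respect to the discretised scores while bounding the state space; the
  scanner and its p-values use the *same* discretisation, so reported
  p-values are monotone in reported scores by construction.
* All generators run under `withr::with_seed()`: fixed seed, identical
  bytes out, and the caller's RNG stream is left untouched.
* MEME letter-probability rows off from 1 by less than 1e-3 are
  renormalised silently (common in published motif files); larger
  deviations are errors, as is any non-ACGT alphabet.

## Limitations

* The pair test treats miRNA target sets as fixed and independent draws;
  correlated targeting (family seeds, clustered MREs) inflates the null
  overlap and is not modelled.
* The power-law R² is a descriptive regression diagnostic, not a test of
  scale-freeness; use the MLE literature for inference about exponents.
* MCODE results can depend on the haircut/fluff flags when reproducing
  published module memberships; both are exposed.
* The scanner's 0-order background ignores dinucleotide composition
  (CpG islands in promoters will inflate hit counts relative to a
  higher-order model).
* Only univariate Cox models are provided — no penalised multivariate
  fits, time-dependent covariates or competing risks.
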