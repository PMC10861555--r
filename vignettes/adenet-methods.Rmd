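---
title: "Two-stage adaptive elastic-net inference of gene regulatory networks"
author: "adenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage adaptive elastic-net inference of gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adenet)
```

## The problem and the model

Paired single-nucleus RNA and ATAC measurements from the same barcodes make
it possible to ask, per gene, which accessible chromatin regions and which
transcription factors (TFs) statistically explain its expression. adenet
implements a two-stage parametric approach:

1. **CRE stage.** For each modeled gene, all accessible peaks within
   500 kb of the transcription start site (TSS) are candidate
   cis-regulatory elements (CREs). The gene's (pseudocell) expression is
   regressed on the candidates' (pseudocell) accessibility with an
   adaptive elastic net; peaks whose coefficients survive bootstrap
   significance filtering are the gene's CREs.
2. **TF nomination.** Significant CREs and the promoter
   (−2000..0 bp from the TSS, strand-aware) are scanned for TF binding
   motifs (or annotated from a precomputed peak × motif matrix). TFs with
   a motif in any of those peaks — optionally restricted to motifs
   *enriched* against a GC-matched background — and with detectable
   expression are candidate regulators.
3. **TF stage.** The gene's expression is regressed on its candidate TFs'
   expression (single cells preferred), again with the adaptive elastic
   net and bootstrap filtering, giving a signed, weighted TF→gene network.

Both stages solve, for response $y$ (one gene across $n$ pseudocells or
cells) and predictor matrix $X$ ($p$ peaks or TFs),

$$
\hat\beta \;=\; \Bigl(1 + \tfrac{\lambda_{2,\mathrm{abs}}}{n}\Bigr)\,
\arg\min_\beta\; \lVert y - X\beta\rVert_2^2
\;+\; \lambda\bigl(\lambda_2 \lVert\beta\rVert_2^2
\;+\; \textstyle\sum_j \hat w_j |\beta_j|\bigr),
$$

with adaptive weights $\hat w_j = |\hat\beta_j(\mathrm{enet})|^{-\gamma}$
computed from a pilot elastic-net fit ($\hat w_j \equiv 1$). Predictors
whose pilot coefficient is exactly zero receive an infinite weight and are
excluded from the adaptive stage. The L2 term stabilizes the strongly
collinear predictors typical of single-cell data (correlated peaks,
co-regulated TFs); the adaptive L1 term yields sparse, selection-consistent
models that can be ranked.

### The $\lambda_2$ parameterization

We implement the ridge weight $\lambda_2$ *relative* to the adaptive L1
term, with a single overall level $\lambda$ chosen by 10-fold
cross-validation (CV-minimum by default; a `"1se"` rule is available).
Smaller $\lambda_2$ therefore means a relatively stronger L1 penalty and a
sparser model. The absolute ridge level
$\lambda_{2,\mathrm{abs}} = \lambda^\ast \lambda_2$ at the selected path
point feeds the $(1 + \lambda_{2,\mathrm{abs}}/n)$ rescaling of the
selected coefficients, which undoes the double shrinkage of the combined
penalties. Defaults: $\lambda_2 = 0.25$ for the CRE stage, $0.5$ for the
TF stage, $\gamma = 1$.

The solver is an exact cyclic coordinate descent (C++, active-set updates,
warm starts along a 50-point log-spaced path from $\lambda_{\max}$ down to
$10^{-3}\lambda_{\max}$, or $10^{-2}$ when $p > n$ to avoid chasing dense
ill-determined path ends). Predictors are z-scored inside the solver and
coefficients returned on the original scale, so downstream
"coefficient × mean expression" scores are in interpretable units. Unit
tests verify the solution against a closed-form soft-threshold solution on
orthonormal designs (to $10^{-8}$) and against a 10,000-step
proximal-gradient oracle (objective gap $< 10^{-6}$); `glmnet`, under the
exact parameter mapping $\alpha = 1/(1+2\lambda_2)$, serves as an
independent cross-check.

### Bootstrap significance

Standard errors come from refitting on `n_boot` row-resamples (defaults:
1000 for the CRE stage, 100 for the TF stage; the test suite and
acceptance script scale these to 100/50 for runtime) while holding the
selected $\lambda^\ast$ and the adaptive weights fixed — the bootstrap
quantifies the sampling variability of an already-specified model, and
re-running CV inside each resample would be computationally prohibitive.
$p_j = 2\{1 - \Phi(|\hat\beta_j| / \mathrm{se}_j)\}$, two-sided normal,
centered at the full-data estimate; predictors with $p \ge 0.05$ are
dropped. No multiple-testing correction is applied across a gene's
predictors (the raw $p < 0.05$ rule is the method's convention). A
degenerate standard error ($< 10^{-12}$) gives $p = 0$ for a nonzero
coefficient and $p = 1$ otherwise. Under a global null ($y \perp X$) the
whole pilot–adaptive–bootstrap cascade passes about 4% of predictors at
$p < 0.05$ — close to, and slightly below, the nominal level, because most
predictors are already discarded by the pilot.

## Micropooling

To reduce single-cell sparsity before the CRE stage, cells are pooled into
pseudocells: Louvain communities of the joint neighbor graph (supplied
directly, or built as a k-nearest-neighbor graph with $k = 20$ from a
supplied embedding) are each split by k-means on the embedding coordinates
into $\lceil \text{size}/\text{target}\rceil$ groups, so pseudocells never
mix communities. Profiles are arithmetic means of member cells, so
size-weighted pseudocell means conserve the global mean exactly, and
`target_size = 1` is the identity.

By default one partition (target 10) aggregates both modalities, keeping
the regression rows exactly aligned. A dual mode pools ATAC more
aggressively (target 100, as sparser data warrant) and aligns each RNA
pseudocell to the ATAC pseudocell holding the plurality of its members;
how to align rows across two different targets is not defined by the
method itself, so the single-partition default avoids that ambiguity.

## Normalization

Stage 2 fits on library-size-normalized expression (`normalizeCells()`):
at single-cell resolution the per-cell depth factor multiplies the
response *and* every TF predictor, and terms of the response proportional
to depth alone cannot be absorbed by the true regulators — any
depth-correlated decoy TF will absorb them instead. Removing depth removes
this false-positive channel. Stage 1 consumes raw ("non-binarized")
values on both sides: pseudocell averaging suppresses the depth factor by
$\sqrt{\text{target}}$, and with few simulated features a depth estimate
is itself signal-contaminated, so dividing by it would re-inject
correlated noise. `log1p` is available for raw counts but off by default;
the synthetic data are already on a normalized scale, and the fitted model
is linear in whatever scale is supplied.

## Motif annotation

Motif scanning is plain log-odds scoring of JASPAR-style position
frequency matrices (pseudocount 0.01, per-motif background) against both
strands, with a hit when the best window reaches `rel_threshold = 0.80` of
the score range (minimum achievable mapped to 0, maximum to 1 — a common
matching convention; the threshold is configurable because no canonical
value exists). `N` bases score as background (zero log-odds). A
precomputed peak × motif matrix can be supplied instead, which is how the
synthetic pipeline runs genome-free.

The enrichment variant tests each motif's hit count in a gene's CRE set
against a GC-decile-matched background of up to 200 non-CRE peaks
(one-sided Fisher, Benjamini–Hochberg across motifs, adjusted $p < 0.05$).
Because enrichment demands more than presence, its nominations are always
a subset of the presence-based ones, and genes whose candidate sets empty
out are skipped — the expected, documented behavior of the stricter mode.

Promoter conventions are deliberately two: TF nomination uses the
asymmetric −2000..0 bp promoter upstream of the TSS, while the CRE class
label ("promoter" / "gene body" / "intergenic") uses ±2000 bp around the
TSS. Both constants are arguments.

## Scoring, centrality, perturbation

With state directions $s_g = +1$ (state A-up) or $-1$ (state B-up) from a
differential-expression table, a TF's axis score is
$\mathrm{mean\_expr}(TF)\times\sum_g s_g\,\beta_{TF,g}$: positive scores
mark state A-promoting regulators. Cell-type scores replace $s_g$ with
membership in marker sets. Scores are linear in both factors and negate
exactly when all directions flip.

The network graph has one edge per significant TF→gene link, weight
$|\beta| \times$ mean TF expression and the sign of $\beta$. PageRank
(damping 0.85) is computed on the *edge-reversed* graph, so regulators
accrue rank from the genes they target; on the regulatory orientation TFs
are sources and would receive no rank from their targets. The forward
orientation remains available. Betweenness uses the original directed
graph with distance $1/\text{weight}$ (zero-weight edges dropped).

In-silico perturbation applies a rule per TF — knockdown to zero, scaling,
or setting to an expression quantile (default 0.95 for "upregulation",
our choice of magnitude) — recomputes each modeled gene's prediction
$\hat y = X_{\mathrm{perturb}}\hat\beta$, substitutes predictions into the
expression profiles (unmodeled genes keep observed values), and projects
both the baseline and the perturbed profiles through caller-supplied
linear embedding loadings. The baseline substitutes the *unperturbed*
predictions for the same genes, so the identity perturbation produces
exactly zero displacement and displacements reflect the perturbation
only. Propagation is single-step by construction; no iterative cascade.

## Model comparison

$\mathrm{AIC} = -2\,l(\hat\beta) + 2k$ with Gaussian log-likelihood at the
maximum-likelihood residual variance $\hat\sigma^2 = \max(RSS/n,
10^{-12})$ (floored so a perfect fit has finite likelihood) and $k$ the
number of nonzero slope coefficients. The intercept is excluded from $k$:
both the full-CRE and the promoter-only model always carry one, so
including it would shift both AICs equally anyway.
$\Delta\mathrm{AIC} = \mathrm{AIC}_{\mathrm{CRE}} -
\mathrm{AIC}_{\mathrm{prom}}$; negative favors distal regulation;
$e^{\Delta\mathrm{AIC}/2}$ is the relative probability. The Jaccard index
of two empty sets is defined as 1 (identical sets), with a warning.

## The synthetic generator

`simulateMultiome()` is first-class, tested code; it defines the
conditions under which the pipeline is validated. Default regime: 2,000
cells, 50 genes, 30 TFs, 50 candidate peaks per gene of which 5 are true
CREs (one of them the promoter peak), 3 true TFs per gene, effect
magnitudes uniform in $[0.5, 2]$ with 30% of distal CRE effects
repressive, expression noise sd 0.5, two cell states in equal proportion,
seed 7.

The generative chain makes the two stages mutually consistent: each
gene's latent drive is $D_g = \sum_t \theta_t \cdot TF_t$ over its true
TFs (whose expression is a state-dependent mean plus Gaussian noise,
sd 0.6, clipped at zero); true-CRE accessibility is
$\mu_k + (q_k/\beta_k)\,L_g^\ast + e_k$ with $L_g^\ast$ the standardized
drive, $q_k > 0$ summing to 1 and $e_k$ independent noise (sd 0.5); and
expression is $\textrm{base}_g + \sum_k \beta_k\,\mathrm{acc}_k +
\varepsilon$. Expression is therefore *exactly* the planted linear model
in the true CRE accessibilities and, up to independent noise, the planted
linear model in the true TF expressions — so recovery failures indicate
implementation bugs, not model misspecification. Each true CRE carries
its own independent component, keeping the five jointly identifiable
despite their shared latent factor. Decoy peaks are independent noise, a
third of them with their own state shift (a deliberate confounder
exercise). Motifs are sharp random-consensus PFMs; every true TF's motif
is guaranteed a placement in a true CRE (plus the promoter half the
time), with 2% background placements. A lognormal size factor (sd 0.1)
multiplies both modalities of a cell — the realistic depth confounder the
normalization section addresses. DEG directions follow the planted state
shifts, which arise only through the TFs, and the 2-D embedding separates
the two states.

What the generator does *not* emulate: zero-inflated counts and dropout,
batch effects, doublets, sequence-level motif placement (hits are planted
in the incidence matrix), nonlinear or combinatorial regulation, and more
than two cell states. Passing tests therefore demonstrate correctness of
the estimation machinery under the model class the method assumes — they
do not certify performance on real tissue data.

Problem sizes in the test suite and acceptance script (2,000 × 50 genes
end-to-end; 800 × 20 for the enrichment comparison; 200 replicate genes
for the null calibration; bootstraps 100/50) were chosen as the smallest
regimes that exercise every code path at stable metrics.

## Numerical choices and degenerate inputs

- Coordinate descent tolerance $10^{-10}$ on the standardized coefficient
  scale, max $10^5$ sweeps; ties in CV pick the largest $\lambda$ at the
  minimum (first index).
- Constant response: warning, all-zero fit. All pilot coefficients zero:
  empty model, $r^2 = 0$. Constant predictors are pinned at zero via an
  infinite penalty weight. Fewer rows than CV folds: error.
- $r^2$ may be negative (worse than the intercept-only model) and is kept
  so; zero-variance response flags `NA`.
- Zero candidate peaks in a window: the gene is flagged and skipped, not
  an error — genes without accessible promoter peaks are still modeled
  from distal candidates.
- Per-gene RNG streams derive deterministically from the global seed and
  the gene id, so results are independent of gene order and of
  parallelization strategy; k-means uses multiple starts under a fixed
  seed, with a deterministic chunking fallback when a community has fewer
  unique coordinates than clusters.
- Empty pseudocell / empty graph / empty CRE set inputs error with
  specific messages.

## Interface choices

The package is organized Bioconductor-style (S4 classes `OmicsMatrix`,
`FitResult`, `MotifSet`, `PeakMotifHits`, `GRNGraph`,
`PseudocellAssignment`; `GRanges` for peaks and genes; camelCase
exports). It is used from R: each pipeline step is one exported function
(`buildPseudocells`/`aggregateCells`, `fitGeneCres`, `scanMotifs`/
`candidateTfs`/`enrichedTfs`, `fitGeneTfs`, `tfAxisScore`/
`pageRankScores`/`betweennessScores`/`simulatePerturbation`,
`compareModels`, `simulateMultiome`), and `runPipeline()` ties them
together with TSV outputs and a manifest; `scripts/acceptance.R` is the
scripted entry point for reproducing the validation numbers. External
coordinates are BED-convention (0-based half-open) everywhere; internal
`GRanges` are converted at the boundary and peak ids
(`"chrom:start-end"`, BED coordinates) are the cross-referencing keys
between matrices and interval data.

## Known limitations

- Linear, single-step models only: no TF–TF interaction terms, no
  time-lagged effects, no iterative perturbation cascades.
- The bootstrap holds the selected penalty fixed, so its standard errors
  ignore model-selection variability (documented choice; re-selection per
  resample is computationally prohibitive and the method's convention is
  a fixed model).
- Motif scanning is a simple PWM threshold scan — no dinucleotide
  background, no methylation awareness, no footprint information.
- Centrality rankings depend on the edge-weighting convention
  ($|\beta| \times$ mean expression) and the reversed-PageRank choice;
  alternative conventions are exposed but not reconciled.
- The heritability, CUT&RUN and cross-dataset evaluations that motivate
  the method on real data are out of scope here; validation is against
  planted synthetic truth.

## A worked example

```{r example, eval = FALSE}
library(adenet)
sim <- simulateMultiome(n_cells = 600, n_genes = 12, n_tfs = 10, seed = 7)
res <- runPipeline(sim, out_dir = "run1",
                   stage1 = enetConfig(l2_weight = 0.25, n_boot = 100),
                   stage2 = enetConfig(l2_weight = 0.5, n_boot = 50),
                   seed = 11)
evaluateRecovery(res$cre_links, sim$truth$true_cre_links)
head(res$axis_scores)
head(res$pagerank)
```
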