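---
title: "katzRank: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{katzRank: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(katzRank)
```

# The model

katzRank scores candidate disease genes by propagating a
differential-expression signal over a weighted protein–protein interaction
network. Two biological assumptions drive the construction: a gene is a
plausible disease gene if it is differentially expressed between cases and
controls, or if its protein interacts strongly with the proteins of other
plausible disease genes. Formalizing the second assumption *recursively* —
neighbours of high-scoring genes score high — leads to a Katz-style fixed
point over the interaction matrix $W$ ($w_{ij}\in[0,1]$, symmetric, zero
diagonal):

$$ s \;=\; \varphi W s + \delta d + \eta x
   \quad\Longleftrightarrow\quad
   s \;=\; (I-\varphi W)^{-1}\,(d + \eta x), $$

with $d=(1,\dots,1)^\top$ a uniform background, $\delta$ fixed to 1 (only
relative scores matter, so $\delta$ is a free overall scale and is not
exposed as a tunable), $x \ge 0$ the per-gene activity, $\varphi$ the
coupling to network neighbours and $\eta$ the weight of the expression
evidence. For $\varphi < 1/\rho(W)$ the Neumann series
$\sum_k \varphi^k W^k$ converges and the inverse is entrywise nonnegative;
consequently every score is at least $\delta = 1$, activities only ever
*add* score (monotonicity), and $s(\eta)-s(0)$ is exactly linear in
$\eta$. With uniform activity ($x = d$) and binary weights the score is
proportional to $(I-\varphi W)^{-1}d$ and the ranking coincides with
classical Katz centrality for any $\eta$ — the test suite asserts this
reduction on random binary graphs.

The **activity** $x_g$ is the magnitude-only rank statistic
$\lvert \log_2(\bar r^{\text{dis}}_g / \bar r^{\text{ctl}}_g)\rvert$, where
$\bar r$ are mean within-sample ranks after replacing every sample's
expression values by their ranks (1 = lowest, ties averaged). Ranking makes
values comparable across platforms; the absolute value makes the signal
direction-free, so swapping case/control labels leaves $x$ unchanged.

When some disease genes are known, the **seeded variant**

$$ s_1 = (I-\varphi W)^{-1}(x_1 + x_2) $$

adds a 0/1 indicator $x_2$ of the known genes to $x_1$, the normalized
$d+\eta x$.

# Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| $\varphi$ | network coupling (unitless; valid range $[0, 1/\rho(W))$) | calibrated | small $\varphi$ ranks by expression, large $\varphi$ by network proximity |
| $\eta$ | activity weight (unitless) | calibrated | background chance that an unexpressed gene is causal shrinks as $\eta$ grows |
| `scoreScale` | edge-score divisor at load time | 1000 | STRING confidence scores are per-mille; scores are clamped into $[0,1]$ after division |
| `tol`, `maxIter` | Jacobi stopping rule | $10^{-10}$, 10{,}000 | machine-precision agreement with dense direct solves at the problem sizes we target |
| `hMax` | ROC cutoff sweep | 100 | matches candidate sets of about 100 genes |

$\varphi$ and $\eta$ are calibrated by scanning a grid and minimizing the
mean r-ratio of known disease genes across diseases
(`calibrateParameters()`), ties broken toward the smaller $\varphi$, then
the smaller $\eta$ (preferring the less propagation-heavy, more
parsimonious model). The grid is configuration: `benchmarkEvaluation()`
uses $\varphi \in \{0, 0.1, 0.3, 0.6, 0.9\}\cdot\varphi_{max}$ and
$\eta \in \{0, 1, 5, 20, 50\}$, dense enough to separate the three
information regimes (expression-only, network-only, combined) while keeping
a full calibration at 2,000 genes in seconds.

# Numerical choices

* **Spectral bound.** `maxPhi()` returns $1/\rho(W)$ with $\rho$ from power
  iteration on the sparse symmetric $W$ (relative tolerance $10^{-10}$).
  The norm-ratio estimate is used rather than the Rayleigh iterate so that
  bipartite components (eigenvalues $\pm\rho$) still converge. An edgeless
  network returns `Inf` (any $\varphi$ is admissible).
* **Solver.** Jacobi iteration $s^{(t+1)} = \varphi W s^{(t)} + b$ starting
  from $s^{(0)} = b$, the first Neumann term — deterministic and one sweep
  ahead of a zero start. $W$ has zero diagonal, so the iteration matrix is
  exactly $\varphi W$ and convergence is guaranteed under the
  $\varphi$-bound, which is validated before iterating. Stopping:
  max-norm change $< 10^{-10}$ or error after 10,000 sweeps.
* **Ties.** Average ranks everywhere (within-sample expression ranks,
  candidate ranking, hence r-ratios) — unbiased and standard. In
  `topGeneOverlap()` all genes tied at the $k$-th score enter the top-$k$
  list.
* **Degenerate inputs.** Self-loops are dropped but their genes kept as
  isolated nodes; duplicate/reciprocal edges merge keeping the maximum
  weight (conservative retention of the strongest evidence); an
  all-constant expression column ranks to all-equal values; candidate
  requests larger than a chromosome return the whole chromosome with a
  warning; an empty known-gene set reduces $s_1$ to the $x_1$ term with a
  warning; genes missing from the activity vector get $x_g = 0$.
* **Cutoff rule.** `optimalCutoff()` walks the ROC curve at step
  granularity $h \to h+1$ and returns the smallest $h$ whose step ratio
  $\Delta TPR/\Delta FPR$ drops below 1 ($\Delta FPR = 0$ counts as
  $\infty$); past that point sensitivity gains no longer compensate
  specificity losses. On the published operating-point table shipped with
  the package the coarse tabulated steps all stay above 1, consistent with
  the drop being a fine-granularity feature between tabulated rows.
* **Hypergeometric tail.** Summed in log-space from `lchoose()` terms with
  a max-shift, exact for $k=0$; the suite checks it against both
  `phyper()` and exhaustive subset enumeration on every universe of size
  $\le 12$.

# Interpretation choices where the method is underdetermined

Several details of the procedure admit more than one reading; the package
fixes them as follows and treats them as its own conventions.

* **Log base.** Activities use $\log_2$ (microarray convention). Any other
  base rescales $x$ uniformly and is absorbed by $\eta$, so the choice
  only affects reported magnitudes, not calibrated rankings. Ranks are
  ascending (1 = lowest expression); the direction is immaterial after the
  absolute value, but exact $x$ values depend on it.
* **Normalization of $x_1$.** "Normalized" is taken as division by the
  vector maximum, putting $x_1$ on $[0,1]$ and making it commensurate with
  the unit entries of $x_2$; sum-normalization is available via
  `normalize = "sum"`.
* **Candidate sets.** A locus resolves to a chromosome and midpoint;
  the set contains the genes overlapping the interval first, then the
  nearest flanking genes by midpoint distance, ties broken by gene
  identifier — deterministic and byte-identical across runs. Coordinates
  are 0-based half-open on disk (BED convention), 1-based inside R
  (GRanges convention). The benchmark gene is always included, displacing
  the farthest other member if needed.
* **FPR accounting.** The top-$h$ members of *every* candidate set are
  predictions; false positives aggregate across sets
  ($\sum \min(h,N) -$ TP over $\sum(N-1)$ negatives). This joint
  accounting reproduces the sensitivity/specificity arithmetic of the
  shipped operating-point table.
* **Probe handling.** Multiple probes per gene are averaged on the raw
  scale before ranking. Missing values are an error unless column-median
  imputation is requested.
* **Enrichment universe.** Defaults to the genes carried by the catalog
  (typically intersected with the network); raw P-values are flagged at
  $\alpha = 0.05$, with Benjamini–Hochberg values reported alongside
  rather than used for the flag, since the flagging convention is a raw
  threshold.

# What the synthetic generators emulate — and what they do not

`makeToyNetwork()` draws an Erdős–Rényi graph with uniform weights and
half-normal activities, keeping the largest connected component. It exists
to exhibit the $\varphi$ trade-off: at $2\%$ of $\varphi_{max}$ the score
ranking tracks $x$ (Spearman $> 0.9$), at $98\%$ poorly expressed but
well-connected genes climb into the top ranks. Both behaviours are asserted
over ten seeds in the suite.

`makePlantedBenchmark()` builds the full evaluation substrate:

* a background random graph (default 2,000 genes, edge probability 0.005 —
  mean degree about 10, comparable to confidence-thresholded interaction
  networks) with weights uniform on $[0.15, 0.95]$, the typical span of
  normalized confidence scores;
* one near-clique module per disease (internal edge probability 0.8 plus a
  ring guaranteeing connectivity, weights boosted by 0.5 and clamped at 1)
  — a module rather than an exact clique, to avoid trivially separable
  structure;
* a pleiotropic pool (default 12 genes) whose members join several disease
  modules, giving the cross-disease structure that global top-gene overlap
  and the pleiotropy–rank correlation need to exist at this scale;
* per-disease activities in which only half the module genes (default
  `signalFraction = 0.5`) carry an elevated signal (half-normal around
  `activitySignal = 1` against background scale 0.15, magnitudes typical
  of $\lvert\log_2\rvert$ rank ratios at moderate sample sizes) — the rest
  stay at background, emulating disease genes invisible in expression
  data, which is precisely the case network propagation is meant to
  rescue;
* per known gene, a locus-style candidate set of the 100 nearest genes on
  its synthetic chromosome, with other true genes of the same disease
  excluded so each set contains exactly one truth.

What the generator does **not** emulate: platform-specific probe noise,
correlated co-expression backgrounds, scale-free degree distributions,
incomplete and biased interaction coverage, or literature-biased edge
confidence. Passing the planted-benchmark criteria therefore shows that
the implementation recovers structure *of the kind the method assumes*,
not that the method attains any particular accuracy on real cohorts.

# Randomization controls

`shuffleActivity()` permutes activities by repeated random transpositions
(default $10\times$ the gene count — far beyond mixing, a concrete reading
of "sufficiently many"); `randomKnownSets()` draws set sizes uniformly on
the integers 1–32 (the observed spread of known disease-gene counts;
discrete rather than continuous because set sizes are integers) and fills
them without replacement. Replacing $x_1$ and $x_2$ by these counterparts
collapses the cross-disease overlap of top-ranked genes relative to the
planted configuration. One honest caveat: the control randomizes the
*inputs* only, not the network, so structurally central genes — here the
boosted modules — still recur in randomized top lists more than a true
null would allow; the comparison is therefore relative (planted $\gg$
randomized), and the gap widens as the selection fraction $k/n$ shrinks
toward the regime of genome-scale networks.

# Problem sizes and reproducibility

The reference evaluation (`benchmarkEvaluation()` over
`makePlantedBenchmark()` defaults, ten seeds) uses 2,000 genes, 10
diseases, modules of 10, candidate sets of 100 — sizes at which a full
calibration, evaluation and leave-one-out pass completes in a few seconds
per seed on one core while keeping candidate sets at the realistic ~100
genes. All generators take explicit seeds, preserve the caller's RNG
state, and are bit-reproducible; `scripts/acceptance.R` derives every
stream from its single `--seed` argument.

# Known limitations

* Scores from one network load: the edge-list format cannot represent
  isolated genes, so writing and reloading a network keeps exactly the
  genes incident to an edge.
* The Jacobi solver targets sparse desk-scale networks (up to ~$10^5$
  edges); no preconditioning or sparse-direct alternatives are provided.
* `optimalCutoff()` operates at integer step granularity; curves whose
  trade-off crosses 1 between integer cutoffs report the step's left
  endpoint.
* Calibration re-solves every disease at every grid point; grids much
  finer than the defaults scale linearly in cost.
* Candidate-set construction assumes one locus record per gene and ignores
  strand and overlapping transcripts.
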