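---
title: "Methods: weighted co-expression networks with differential betweenness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted co-expression networks with differential betweenness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexdiff)
```

This vignette documents the statistical model behind each stage of the
pipeline, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the methodology left genuine choices.

## The model

Expression of gene $i$ in sample $s$ is treated, on the log scale, as

$$x_{is} = \mu_i + b_i E_{m(i),s} + c_i^\top S_s + \varepsilon_{is},$$

where $E_m$ is the latent *eigengene* of module $m$ (genes not in any module
have $b_i = 0$), $S$ collects hidden technical components (batch, ischemic
time residue, library effects), and $\varepsilon$ is gene-level noise. A
binary trait $t$ couples to a module through its eigengene:
$E_m = \lambda\, z(t) + \sqrt{1-\lambda^2}\, g$ with $g \perp t$, so
$\mathrm{cor}(E_m, t) = \lambda$ exactly. The analysis never observes $E$,
$S$, or the module membership; it reconstructs them from the co-expression
structure. That is precisely what the synthetic generator plants, which is
why recovery is assertable: the module eigengene that weighted co-expression
analysis defines (the first principal component of a module) coincides with
the planted factor up to estimation noise.

## Cohort matching

Cases are matched to controls `ratio`-to-one (default 2:1) by minimizing the
total absolute difference of propensity-score linear predictors over all
assignments — each case is replicated `ratio` times and the rectangular
assignment problem is solved exactly (Hungarian algorithm). This mirrors
optimal full-matching behavior at the scale relevant here without
reimplementing a matching framework. Categorical covariates are one-hot
encoded in the propensity model; exact distance ties are broken toward the
lexicographically smaller control id so results are reproducible. The
balance report gives standardized mean differences before/after matching.
With 75 cases and 256 candidate controls the 2:1 match retains exactly 150
controls, 225 samples in total — an arithmetic identity of the design that
the acceptance script recomputes.

## Filtering, transformation, adjustment

* **Count filter.** A gene is removed iff the fraction of samples with
  count $< 10$ exceeds $0.9$ in *both* trait groups (strict inequalities).
  Keeping genes adequately expressed in either group preserves
  condition-specific expression.
* **Variability filter.** Of the survivors, the $\lceil 0.5\,n\rceil$ genes
  with the largest MAD of raw TPM across all retained samples are kept. MAD
  is computed before the log transform. Note the fractional rule is not
  idempotent by construction: it keeps the top half of whatever it is
  given.
* **Transform.** $\log_2(x+1)$.
* **Sample QC.** Within each trait group, the sample network adjacency is
  $A_{uv} = 1 - d_{uv}/\max d$ on Euclidean distances over genes;
  connectivity $k_u = \sum_{v \ne u} A_{uv}$ is standardized to $Z.k$ and
  samples with $Z.k < -2.5$ are flagged in a single pass (no
  re-standardization loop). The max-distance normalization is the standard
  sample-network convention; the cutoff and a correlation-based variant are
  configurable.
* **Surrogate adjustment.** Each gene is regressed on the trait plus known
  covariates; the top `n_sv` (default 3) right singular vectors of the
  row-standardized residual matrix are the surrogate variables, and their
  projection is removed from each gene while means and the protected trait
  direction stay intact. This is an intentionally simplified residual-PCA
  two-step procedure, not a full permutation-calibrated surrogate analysis.
  Two consequences are worth knowing. First, the estimated components are
  orthogonal to the protected design by construction, so recovery of
  planted components must be judged against their design-orthogonal
  projection. Second, when the number of removed components exceeds the
  number of true technical components, the next residual principal
  component is typically a *module eigengene*, and real biological
  structure is removed — the pipeline defaults therefore pair three
  removed components with the three components the generator plants.

**Stage order.** Outlier removal runs on the log-TPM matrix *before*
surrogate estimation. A gross outlier (several median distances away)
dominates the residual covariance, so adjusting first both wastes surrogate
degrees of freedom on outlier directions and masks the outlier from the
$Z.k$ statistic. Flagging aberrant samples before covariance-based latent
structure estimation is the conservative order.

## Network construction

Unsigned similarity $s_{ij} = |\mathrm{cor}(x_i, x_j)|$ (a signed variant is
available but not the default), power adjacency $a_{ij} = s_{ij}^\beta$ with
$\beta \ge 1$, and topological overlap

$$\mathrm{TOM}_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad l_{ij} = \sum_u a_{iu} a_{uj},$$

computed as a matrix product and verified in the tests against a naive
triple loop. Conventions: $a_{ii} = 0$ for connectivity, $\mathrm{TOM}_{ii}
= 1$ so the clustering dissimilarity $1 - \mathrm{TOM}$ has a zero diagonal.

**Soft-threshold selection.** For each candidate $\beta$ (grid 1–20), the
connectivity distribution is summarized in 10 equal-count bins; because the
bins are equal-count, the regression uses the bin *density*
(count/(n · width)) so its slope estimates the power-law exponent $-\gamma$.
The fit index is the signed $R^2 = -\operatorname{sign}(\text{slope})\cdot
R^2$, which a positive-slope (non-scale-free) fit cannot satisfy. The
chosen $\beta$ is the smallest reaching $R^2 \ge 0.85$, else the argmax with
a warning; an all-equal connectivity profile raises an error rather than a
fit. On synthetic data whose background is nearly independent noise this
criterion is satisfied at small powers ($\beta$ 3–5), which is expected: the
criterion asks only for approximate scale-freeness of the degree
distribution, and planted-module data is not scale-free in the way tissue
transcriptomes are. Module *detection* benchmarks therefore fix $\beta = 6$
(the customary unsigned-network power at these sample sizes) so that the
unit under test is the clustering, not the threshold heuristic.

## Module detection and statistics

Average-linkage hierarchical clustering of $1-\mathrm{TOM}$ with a *static*
cut. The cut is placed on the absolute dissimilarity scale (default 0.98):
TOM dissimilarity is bounded by 1, co-expressed branches merge well below
the cut, and background genes chain just under 1, so an absolute cut close
to — but below — 1 separates them. A quantile-of-merge-heights variant is
available (`cut_method = "quantile"`), but on planted-module data nearly all
merge heights concentrate within $10^{-3}$ of the top, so a high quantile
lands above the background chaining level and collapses everything into one
cluster; the absolute convention is the default for that reason. Branches
smaller than `min_module_size` (default 30) go to the reserved
`"unassigned"` label. Dynamic branch-trimming (adaptive cut with a PAM
stage) is intentionally out of scope: the static cut is deterministic,
parameter-transparent and sufficient for planted-structure recovery.

Eigengenes are first right singular vectors of the gene-standardized module
submatrix, unit-variance, sign-anchored to correlate nonnegatively with the
module's mean standardized expression. Trait association uses Pearson
(point-biserial) correlation against the 0/1 trait with the two-sided
$t = r\sqrt{(n-2)/(1-r^2)}$ p-value; module-trait significance is judged on
raw p-values (a BH column is emitted alongside for transparency, since the
study design treats each module as a planned comparison). Per gene,
$GS_i = |\mathrm{cor}(x_i, t)|$ and $MM_i = \mathrm{cor}(ME_{m(i)}, x_i)$,
with hubs ranked by $|MM|$ within modules.

## Differential betweenness centrality

For every trait-significant module (raw $p \le 0.05$ by default), case and
control networks are rebuilt separately: expression restricted to the
module's genes and the group's samples, similarity → adjacency with the
*shared* $\beta$ → TOM. Edge length is $1/\mathrm{TOM}$ (zero TOM = no
edge), and betweenness

$$BC(v) = \sum_{i \ne v \ne j} \frac{g_{ivj}}{g_{ij}}$$

is accumulated Brandes-style over the Dijkstra shortest-path DAG, counting
paths whose lengths tie within a relative tolerance of $10^{-12}$ (exact
ties only arise in symmetric fixtures). Pairs are unordered; the ordered
convention would double every value uniformly and leave the ranking
unchanged. Genes are ranked by $|BC_\text{case} - BC_\text{control}|$; a
gene with large betweenness in one condition only is a *coordinator
candidate* — it carries shortest-path traffic (information flow, in the
co-expression metaphor) under one phenotype but not the other. The
implementation is validated against exhaustive simple-path enumeration on
small graphs, closed forms (path, star, cycle), and an independent graph
library.

## Enrichment and the regulatory network

Over-representation uses the one-sided hypergeometric upper tail with the
universe fixed to the network-analyzed genes (standard ORA practice —
testing a module against the genome would confound module membership with
expression-filter survival). Sets are intersected with the universe before
the ≥ 5 size filter; each collection (pathways, TF targets, miRNA targets)
forms its own BH family, mirroring separate database queries; significance
is adjusted $p \le 0.05$. Gene-set databases are user-supplied GMT files,
never bundled. The TF–miRNA–mRNA network wires every enriched regulator to
the key genes its target set contains, appends optional curated literature
edges, and exports GraphML and SIF.

## The synthetic generator

Defaults describe the desk-scale analog of a skin-cohort study at roughly
one-tenth size: 880 genes, 22 cases / 44 controls, three planted modules of
120/100/80 genes, mean within-module gene-eigengene correlation 0.8 with a
±0.15 per-gene spread and random loading signs, one module trait-coupled at
$\lambda = 0.4$, three hidden surrogate components carrying half the
variance of background genes, 15% of background genes at near-zero baseline
(targets for the count filter), two outlier samples displaced by five times
the median inter-sample distance and allocated across both trait groups
(aberrant samples occur in both arms of real cohorts), TPM by
exponentiation and per-sample normalization to $10^6$, counts by Poisson
thinning at two million reads. The same seed yields bit-identical output.

Choices worth flagging:

* **Random loading signs.** Modules mix positively and negatively regulated
  genes. Besides realism under an unsigned network, balanced signs prevent
  the per-sample TPM normalization from absorbing eigengene signal into a
  compositional offset — with one-signed loadings the realized
  gene-eigengene correlation would be biased low by construction.
* **Loading spread.** `within_module_cor` is a *mean*; per-gene loadings
  spread ±0.15 around it. Without heterogeneity, hub ranking and the GS–MM
  coupling would be pure noise.
* **Outlier allocation.** With $\ge 2$ outliers, both groups receive at
  least one. A group containing a gross outlier has its connectivity spread
  inflated, which is the regime the $Z.k < -2.5$ rule expects; in a clean
  group of this size the rule's single pass flags a borderline sample
  occasionally — that is a property of the statistic, not a bug.
* **What is not emulated.** Read-level sequencing noise, GC/length bias,
  isoform structure, overdispersion beyond Poisson, non-Gaussian eigengene
  dynamics, and correlated covariates beyond a mild trait shift. Passing
  recovery tests on this generator shows the pipeline recovers the factor
  structure it assumes; it does not certify performance on tissue data with
  pervasive weak correlation.

## Validation sizes and numerical choices

The test and acceptance runs use the generator defaults (880 genes, 66
samples) with 20 replicates for recovery statistics, random 6–50-gene
matrices for the TOM oracle, and $n \le 8$ graphs for exhaustive betweenness
enumeration — sizes chosen so the whole suite completes in about a minute
while keeping estimation noise far from the decision boundaries.
Tolerances: $10^{-12}$ for linear-algebra identities (TOM oracle,
permutation equivariance), $10^{-9}$ for shortest-path comparisons (tie
tolerance interacts with length sums), exact equality for combinatorial
quantities (matching counts, ORA enumeration). Degenerate inputs error
loudly rather than warn: zero-variance genes at similarity, all-equal
connectivity at threshold selection, undersized groups at QC.

## Known limitations

* The static cut has one global height; nested or close modules that a
  dynamic trimming would separate may merge or shed tails into
  `"unassigned"`.
* Residual-PCA adjustment with `n_sv` larger than the true latent rank eats
  biological structure (see above); there is no internal estimate of the
  number of components.
* Betweenness is computed within module subgraphs, as the module-level
  question demands; it says nothing about cross-module bridging.
* The betweenness path-count convention (unordered pairs, full tie
  counting) is fixed and documented; absolute BC values are convention-
  dependent and only ranks and differences should be interpreted.
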