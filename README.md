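# coexdiff

Weighted gene co-expression network analysis for case-control RNA-seq
cohorts, with differential betweenness centrality for coordinator-gene
discovery. The package targets the common situation in population
transcriptomics (e.g. comparing diseased and healthy tissue donors from a
biobank): an imbalanced cohort with confounded covariates, expression driven
by latent technical structure, and the scientific question of which gene
*modules* — not which single genes — track the phenotype, and which genes
reorganize their network role between conditions.

## What it computes

Starting from a gene-level count/TPM matrix and sample metadata with a
binary trait:

1. **Cohort matching.** Each case is matched to `r` controls by globally
   optimal assignment on propensity-score distance (logistic regression of
   the trait on sex/age/race or any covariates), with standardized mean
   differences reported before and after.
2. **Filtering and adjustment.** Genes with counts below 10 in more than 90%
   of samples of *both* groups are dropped; the top 50% by MAD of TPM are
   kept and log2(x+1)-transformed. Aberrant samples are flagged per group in
   a Euclidean sample network (adjacency `1 − d/max(d)`, standardized
   connectivity `Z.k < −2.5`) and removed; hidden technical components are
   then estimated by residual PCA (trait-protected) and regressed out.
3. **Network and modules.** Unsigned similarity `s_ij = |cor(x_i, x_j)|` is
   raised to a soft power β chosen by the scale-free model-fit criterion
   (signed R² of the log-log degree regression ≥ 0.85); the topological
   overlap matrix `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)` defines
   a dissimilarity `1 − TOM` that is clustered (average linkage, static
   cut) into modules with an "unassigned" sink.
4. **Module-trait statistics.** Module eigengenes (first principal
   component), eigengene-trait correlations with t-based p-values, per-gene
   gene significance `GS = |cor(x_i, trait)|` and module membership
   `MM = cor(ME, x_i)` with intramodular hub ranking.
5. **Differential centrality.** For each trait-significant module, case and
   control networks are rebuilt separately with the shared β; betweenness
   centrality `BC(v) = Σ g_ivj / g_ij` with edge length `1/TOM` is computed
   by Brandes accumulation, and genes are ranked by `|BC_case − BC_control|`
   to nominate coordinators whose information-transfer role differs between
   conditions.
6. **Enrichment and regulation.** Hypergeometric over-representation of
   module genes against user-supplied GMT collections (sets ≥ 5 in-universe
   genes, BH-adjusted p ≤ 0.05), and assembly of a typed TF–miRNA–mRNA
   network exported as GraphML/SIF.

A synthetic-data generator (`simulate_dataset()`) plants the exact structure
the analysis assumes — latent module eigengenes with a trait-coupled module,
hidden surrogate components, gross outlier samples, a 1:2 case:control
imbalance — so that every stage is validated against ground truth.

## Worked example

```r
library(coexdiff)

sim <- simulate_dataset(simulation_config(seed = 42))
cfg <- pipeline_config(counts = sim$counts, tpm = sim$tpm,
                       metadata = sim$metadata, seed = 42)
res <- run_pipeline(cfg)
res
#> Co-expression pipeline run
#>   matched cohort: 22 cases / 44 controls
#>   genes: 880 -> 859 (count filter) -> 430 (MAD filter)
#>   outliers removed: 2; final samples: 64
#>   soft threshold beta = 3 (signed R^2 = 0.858)
#>   modules: 3 (+ 76 genes unassigned)
#>   trait-significant modules: M1
```

The matched cohort keeps all 22 cases and 44 optimally matched controls; 430
of 880 genes survive the count and MAD filters; the two planted outlier
samples are flagged and removed. Three modules are detected and exactly one
associates with the trait:

```r
res$trait_stats$module_trait
#> # A tibble: 3 × 5
#>   module n_genes    cor p_value p_adjusted
#>   <chr>    <int>  <dbl>   <dbl>      <dbl>
#> 1 M1         158 0.365  0.00303    0.00909
#> 2 M2         120 0.0991 0.436      0.654
#> 3 M3          76 0.0292 0.819      0.819
```

M1 is the planted trait-coupled module (target eigengene-trait correlation
0.4; realized 0.37 after preprocessing). Differential betweenness inside it
ranks coordinator candidates — genes whose shortest-path load differs
sharply between the case and control networks:

```r
head(res$centrality, 3)
#> # A tibble: 3 × 6
#>   gene_id module bc_case bc_control delta  rank
#>   <chr>   <chr>    <dbl>      <dbl> <dbl> <int>
#> 1 G0036   M1         216       5191 -4975     1
#> 2 G0068   M1        3170          0  3170     2
#> 3 G0023   M1         266       2203 -1937     3
```

G0068 carries heavy betweenness in cases and none in controls — the
signature of a condition-specific coordinator. `autoplot()` methods exist
for the scale-free fit, the sample-QC report, module-trait associations and
centrality tables; `tidy()`/`glance()` return tibbles for every fitted
object.

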