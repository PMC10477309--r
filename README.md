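# digestnet

Time-resolved co-occurrence networks and genome-resolved mapping for
anaerobic digester microbiomes.

## The problem

Anaerobic digesters turn wastewater sludge into methane through a relay
of hydrolysers, fermenters, syntrophs, and methanogens. Which
populations actually cooperate — e.g., which syntrophic benzoate or
acetate oxidizer feeds which hydrogenotrophic methanogen — cannot be read
off a single community profile. It *can* be read off a dense time
series: populations that co-vary across months of operation and across
process configurations are candidates for metabolic interaction, and
genome-resolved data (MAGs plus their transcription) can say what each
candidate is equipped to do. `digestnet` is for microbial ecologists and
process engineers holding exactly these data: ASV count time series with
sample metadata, physicochemical process parameters, MAGs with 16S
sequences and annotations, and per-gene read counts from matched
metagenomes/metatranscriptomes.

## What it computes

* **Co-occurrence network.** Nodes are ASVs observed in ≥ 25% of
  samples, sized by mean relative abundance. Default edges are biweight
  midcorrelations (median/MAD-weighted robust correlation) of
  relative-abundance traces, tested with `t = r·sqrt(n−2)/sqrt(1−r²)`,
  Benjamini–Hochberg corrected, kept at `q < 0.05` with `r > 0`. A
  sparse inverse-covariance alternative (CLR transform → graphical lasso
  → StARS penalty selection, `λ_min ratio = 0.1`) is available as
  `edge_method = "clr_glasso"`.
* **Indicator taxa.** Group-equalized IndVal (`stat = sqrt(A·B)`) per
  configuration, permutation-tested (999 permutations) with BH control
  across ASVs.
* **Community structure.** Bray–Curtis dissimilarity, hierarchical
  clustering, PCoA (negative eigenvalues reported), seeded PERMANOVA
  (pseudo-F, R², permutation p), core-microbiome screen (≥ 80%
  prevalence), exhaustive best-environmental-subset search (bioenv-style
  maximum rank correlation), natural-spline alignment of physicochemical
  series to sampling dates.
* **Genome linking.** 16S V4 extraction with the 515F/806R primers
  (IUPAC-degenerate matching), ASV–MAG pairing at > 99.5% identity over
  the query (≤ 1 mismatch / 273 bp) with lowest-common-ancestor taxonomy
  concordance, MAG quality tiers (HQ: > 90% complete, < 5%
  contamination, full rRNA operon; MQ: > 50%, < 10%, ≥ 1 rRNA gene), TPM
  expression, MAG-level aggregation, and the bacterial
  metagenome-vs-metatranscriptome abundance correlation (Spearman ρ, t,
  df).
* **Methanogen subnetworks.** Two-hop neighborhoods of hydrogenotrophic
  methanogen nodes (merged when they touch), with syntroph/methanogen
  guild enrichment tested by 10,000 seeded node draws and, in parallel,
  by the exact multivariate hypergeometric probability.
* **Synthetic data.** A first-class generator that plants correlated
  guild modules, configuration shifts, compositional multinomial counts,
  configuration-coupled parameters, MAG fixtures at exact 16S mismatch
  distances, and coupled MG/MT gene counts — with ground truth returned
  for every plant.

## Worked example

Simulate the default desk-scale study (40 biweekly samples across four
operating configurations, 300 ASVs, five planted methanogen–syntroph
modules), then run the analysis:

```r
library(digestnet)

sim <- simulate_timeseries(default_scenario(seed = 7L))
tab <- filter_low_abundance(sim$table)
tab
#> <abundance_table> 300 ASVs x 40 samples
#>   configurations: CEPT (9), SER (6), SOI (15), SOII (10)
#>   dates: 2016-10-13 to 2018-04-12

net <- build_network(tab, network_config(), taxonomy = sim$taxonomy)
glance(net)
#> # A tibble: 1 × 5
#>   n_nodes n_edges  density mean_weight avg_clustering
#> 1     300      33 0.000736       0.790         0.0667

d <- bray_curtis(tab)
permanova(d, tab$samples$configuration, n_perm = 999, seed = 7L)
#>   pseudo_f    r2 p_value n_perm  seed df_among df_within
#> 1     5.36 0.309   0.001    999     7        3        36

ind <- indicator_test(tab, n_perm = 999, seed = 7L)
net <- set_node_indicators(net, ind)
subs <- extract_subnetworks(net)
subs
#> <subnetwork_set> 5 subnetwork(s)
#>   #1: 4 nodes (1 seed(s), s = 2, m = 1)
#>   ...

guild_enrichment(net, subs[[1]], n_perm = 10000, seed = 7L)
#>   subnetwork size s m p_empirical      p_exact
#> 1          1    4 2 1       3e-04 0.0001970276
```

Reading the numbers: the network recovers 33 edges among 300 nodes, and
the configuration explains 31% of community dissimilarity (PERMANOVA
R² = 0.309, p = 0.001, the permutation floor). Each planted module
surfaces as one methanogen-seeded subnetwork of four nodes; drawing four
random nodes from the parent network yields ≥ 2 syntrophs and ≥ 1
hydrogenotrophic methanogen with probability ≈ 0.0002 (empirical 3e-04
from 10,000 draws, exact 1.97e-04), so the subnetworks' guild composition
is far from chance.

End-to-end runs with provenance, stage toggles, and flat-file outputs go
through a config:

```r
cfg <- simulate_inputs("study_dir", seed = 1L)   # writes a full input bundle
res <- run_pipeline(cfg)                          # prep → … → enrichment
```

`tidy()`, `glance()`, and `autoplot()` methods cover the network,
ordination, indicator, bioenv, and subnetwork results.

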