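---
title: "Methods: time-resolved co-occurrence networks with genome-resolved annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved co-occurrence networks with genome-resolved annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digestnet)
```

# The analysis in one paragraph

Engineered methanogenic ecosystems — anaerobic digesters converting
wastewater sludge to methane — are driven by metabolic interactions among
populations that no single-sample survey can resolve. `digestnet`
implements the time-series route to those interactions: amplicon sequence
variant (ASV) counts sampled biweekly across operating configurations are
turned into a weighted co-occurrence network; nodes are annotated with
configuration indicator status (permutation-tested indicator value
analysis), with a metagenome-assembled genome (MAG) linked by 16S V4
homology and taxonomy concordance, and with transcript abundance (TPM);
finally, subnetworks centered on hydrogenotrophic methanogens are
extracted and their syntroph/methanogen composition is tested against
permutation and exact multivariate hypergeometric nulls. A synthetic-data
module generates inputs with the statistical structure the analysis
assumes, so the whole pipeline is testable without any external download.

# Statistical components

## Edge inference

Two edge methods are provided because the field uses both and they answer
slightly different questions.

**Robust correlation with FDR control (default).** For every pair of
node ASVs, the biweight midcorrelation of their relative-abundance traces
is computed: with $u_i = (x_i - \mathrm{med}\,x)/(9\,\mathrm{MAD}_x)$ and
Tukey weights $w_i = (1-u_i^2)^2\,\mathbf{1}[|u_i|<1]$, each trace is
median-centered, weighted, and normalized, and the correlation is the
inner product of the transforms. Observations beyond nine MADs get zero
weight, so a single spike in a time series cannot manufacture an edge.
When a trace's MAD is zero (mostly-absent taxa) the standard degenerate
rule applies: that trace falls back to Pearson standardization, with a
warning. Two-sided p-values come from the correlation t-test
($t = r\sqrt{n-2}/\sqrt{1-r^2}$), are Benjamini–Hochberg adjusted across
all node pairs, and edges are the pairs with $q < \alpha$ (default 0.05),
restricted to positive correlations by default since the network's
interpretation is co-occurrence. Nodes are ASVs observed in at least 25%
of samples, sized by mean relative abundance.

**Sparse inverse covariance (`clr_glasso`).** Counts are centered
log-ratio transformed (pseudocount 1, exposed), and an
$\ell_1$-penalized precision matrix is estimated by a graphical lasso
written for this package (blockwise coordinate descent, compiled; the
penalty path runs from $\lambda_{max}$, the largest absolute off-diagonal
covariance, down to $0.1\,\lambda_{max}$ over 20 log-spaced points). The
penalty is selected by stability (StARS): 20 subsamples of size
$\min(n, \lfloor 10\sqrt{n}\rfloor)$, edge instability
$\overline{2\xi(1-\xi)}$ monotonized from the sparse end, densest penalty
with instability at or below 0.05. Edges carry sign-carrying partial
correlations.

Why keep both: correlation edges are marginal associations and inherit
the compositional closure of relative abundances — when one guild blooms,
everything else's *share* shrinks together, which manifests as weak
positive correlation among unrelated taxa. The precision-matrix route on
CLR data is the standard defense against exactly that artifact. At the
package's desk scale the correlation+FDR method recovers planted
structure with precision and recall above 0.9 and is the default (it also
matches how the published networks of this kind weight their edges); the
closure caveat is why the realized false-discovery proportion on strongly
compositional data can sit slightly above the nominal FDR level, and why
`clr_glasso` exists. A further honest limitation: StARS is a
large-graph criterion — with only a handful of variables the instability
average is dominated by a few flickering pairs and selection becomes
erratic; at realistic node counts (hundreds) it behaves as intended.

## Indicator value analysis

For ASV $i$ and configuration $k$, specificity
$A_{ik} = \bar{x}_{ik} / \sum_j \bar{x}_{ij}$ uses group-equalized means
of relative abundance (so unbalanced configuration durations do not bias
it), fidelity $B_{ik}$ is the within-group prevalence, and the statistic
is $\sqrt{A\cdot B}$ with best group the argmax. The permutation test
shuffles sample-to-configuration labels (group sizes preserved), compares
the permuted best-group statistic against the observed one,
$p = (1+\#\{\text{perm} \ge \text{obs}\})/(1+B)$, and controls FDR across
ASVs by Benjamini–Hochberg at $q<0.05$. Defaults: 999 permutations;
singleton configuration groups (no group-combination search). Operating
on relative abundances makes the statistic invariant to per-sample
sequencing depth.

## Community-level statistics

Bray–Curtis dissimilarities, complete-linkage hierarchical clustering
(Newick export), classical-scaling PCoA (negative eigenvalues reported,
variance fractions over positive eigenvalues only), and PERMANOVA with
the Gower-centered pseudo-F and freely permuted labels, seeded, with
exact enumeration available at small n. The best environmental subset
search standardizes each parameter, evaluates *every* subset up to
`max_size` by the Spearman correlation between community distances and
Euclidean environment distances, and returns the full ranking, not just
the winner (with a guard refusing more than $2^{20}$ subsets).
Physicochemical series are aligned to biological sampling dates by a
natural cubic spline that passes exactly through measurements and refuses
to extrapolate. The natural end condition was chosen over the common
`fmm` flavor for cross-language reproducibility; the two differ only in
the boundary intervals. The manual plausibility check that practitioners
do by eye is automated: interpolated values whose distance from the
mid-range exceeds 1.5 times the measured half-range are flagged
`out_of_range` rather than silently kept.

## Genome linking

MAG 16S sequences are reduced to their V4 region by locating the
515F/806R primer sites (IUPAC-degenerate, zero-mismatch matching; the
reverse primer is matched as its reverse complement). ASVs are compared
end-to-end and ungapped against the extracted regions; identity is
matched positions over the *query* (ASV) length — the convention implied
by counting mismatches along a 273 bp fragment — and a pair is accepted
above 99.5% identity (so at most one mismatch over 273 bp), provided the
two lineages agree when truncated to the shallower of their deepest
annotated ranks. Ties are broken deterministically (quality score
`completeness − 5·contamination`, then lexicographic id), so the accepted
pair set never depends on input file order. MAG quality tiers follow
community standards: high quality needs >90% completeness, <5%
contamination and a full rRNA operon; medium quality >50%, <10% and any
rRNA subunit gene. Expression is TPM-normalized
($\mathrm{tpm}_g = (c_g/l_g)/\sum_h (c_h/l_h) \times 10^6$), summed to
MAG level, and the genome-vs-transcript abundance correlation is reported
as Spearman's $\rho$ with the t statistic and $df = n-2$, excluding
methanogen MAGs by default since their transcription is known to decouple
from genome abundance.

## Subnetworks and enrichment

Hydrogenotrophic methanogen nodes seed breadth-first neighborhoods of
radius 2 (primary and secondary co-occurrence); neighborhoods sharing any
node merge, and subnetworks are numbered by descending size (ties by
smallest member id). Guild composition is tested by drawing
subnetwork-sized node sets uniformly without replacement from the parent
network (default 10,000 draws, seeded) and, in parallel, by the closed
form: the multivariate hypergeometric probability summed over qualifying
syntroph/methanogen count pairs. The default criterion is *at least* the
observed counts jointly — the standard enrichment direction — with an
exact-counts mode provided because "the probability of observing $s$ and
$m$" is ambiguous between the two. The empirical probability is reported
raw (it can be 0); an $(r+1)/(B+1)$ convention is available by flag when
the value feeds downstream inference.

# The synthetic-data generator

The generator is the package's study stand-in, and its defaults are the
desk-scale mirror of a two-year biweekly campaign: 40 samples in four
configuration blocks sized 15/9/10/6 (the proportions of the study
design's 16/10/11/6 configuration groups), 300 ASVs, multinomial depth
20,000 per sample (column sums exact), matching the scale of a
quality-filtered amplicon library. Latent log-abundances are normal with
a shared per-sample factor inside each of five 4-member guild modules
(one hydrogenotrophic methanogen, two syntrophs, one fermenter;
intra-module correlation 0.9, the regime of strongly co-occurring
consortia), and each module is up-shifted 4 log2 units in its home
configuration — a conditionally-dominant effect chosen so that planted
indicators are unambiguous rather than borderline for the statistics
under test. Taxonomy strings give module members the methanogen and
syntroph lineages a digester survey would name, so the shipped
taxonomy-to-guild table drives guild labels end to end.
Physicochemical parameters are linear in configuration plus noise, with
20% of interior measurements dropped so interpolation is exercised. MAG
fixtures embed each ASV's V4, mutated at an exact mismatch count, between
concrete primer-site realizations inside random flanks. Matched
metagenome/metatranscriptome tables couple transcript to genome
log-abundance with a configurable coefficient; transcriptional noise is
drawn *per MAG and sample* (an organism-level state shared by its genes —
per-gene noise would average away under MAG-level aggregation), and
methanogen MAGs get a +3 natural-log transcript inflation independent of
genome abundance. All randomness flows from mandatory seeds.

What the generator does **not** emulate — and hence what green tests do
not certify about real data: sequencing error and chimeras, batch
effects, autocorrelated (rather than exchangeable) residual noise along
the time axis, taxa appearing or vanishing mid-series, phylogenetic
correlation between taxonomy and abundance, and the long-tailed rank
structure of real communities. Closure is emulated (counts are
multinomial draws from latent compositions), which is why the
compositional caveat above is visible in the package's own tests.

# Numerical choices and degenerate inputs

* Correlation values are clamped to $[-1, 1]$ after the normalized inner
  product; $|r| = 1$ short-circuits the t-test to an exact $p = 0$ flag.
* Constant vectors: bicor falls back to Pearson standardization on the
  MAD-zero side only; a vector constant after biweighting is an error;
  ASV–parameter correlations of constant series are `NA`, never 0.
* Sample pairs with all-zero combined abundance have undefined
  Bray–Curtis dissimilarity and are flagged `NA` with a warning.
* The graphical lasso declares convergence when the mean absolute change
  of the working covariance's off-diagonal falls below $10^{-4}$ of the
  mean absolute off-diagonal of the input; a penalty value whose solve
  does not converge is dropped from the path with a warning.
* "At least 80% of samples" prevalence is implemented as
  $\ge \lceil 0.8\,n\rceil$; the node threshold "at least 25%" as a
  $\ge$ comparison on the prevalence fraction.
* Permutation p-values use the $(1+k)/(1+B)$ convention everywhere
  except the enrichment probability, whose raw-fraction default mirrors
  how such probabilities are usually quoted.
* All tie-breaks (best indicator group, ASV–MAG pairing, subnetwork
  numbering) are deterministic and documented at the function level.

# Problem sizes used by the test suite

The suite runs the full default scenario (300 ASVs × 40 samples) for the
recovery checks; oracle equivalences use 6–10 sample fixtures where
exhaustive enumeration is feasible (all 20 relabellings for PERMANOVA,
all 210 four-node draws for enrichment); null calibration uses 200 seeded
replicates of 12–30 variable data sets; the graphical-lasso structure
check uses 9 variables × 200 observations with heterogeneous block
strengths (0.75/0.55/0.35), the regime where stability selection is
well-behaved at small dimension. These sizes were chosen so the whole
suite completes in well under a minute on one core while still exercising
every code path at meaningful scale.

# Known limitations

* Correlation edges on relative abundances inherit compositional
  closure; use `clr_glasso` when conditional independence is the target.
* The bounded variant of stability selection is approximated by standard
  StARS over the full penalty path; at path length 20 the saving of the
  bounded search is negligible.
* IndVal's permutation null assumes exchangeable samples; strong
  temporal autocorrelation within configurations would make it
  anti-conservative. The package permutes freely (no strata), matching
  the cited standard practice.
* The identity denominator for ASV–MAG pairing is the query length;
  alignments with internal indels are not scored (a hit requiring gaps is
  simply not found by the ungapped scan).
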