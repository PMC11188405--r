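---
title: "Systems genetics of DH populations: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Systems genetics of DH populations: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sysgenet` dissects a quantitative trait in a doubled haploid (DH)
population by combining four statistical layers: phenotype QTL mapping,
weighted co-expression network construction, QTL mapping of module
eigengenes, and genome-wide eQTL analysis with colocalization-based gene
prioritization. This vignette is the package's account of the underlying
models, the tunable parameters and why their defaults are what they are,
the synthetic data the tests rest on, and the known limits of both.

## The scan engine

A DH line is a single recombinant gamete made homozygous: every marker
carries one of two parental alleles, coded 0/1, with no heterozygotes.
At a putative QTL position between flanking markers the genotype is not
observed, but its conditional distribution is exact under the assumption of
no crossover interference. With the Haldane map function
$r = (1 - e^{-2d/100})/2$ for a distance of $d$ cM, and both flanks observed
as the parent-0 allele,

$$p_0 \;=\; \frac{(1-r_L)(1-r_R)}{(1-r_L)(1-r_R) + r_L\,r_R},$$

with the analogous expressions for the other flank configurations; a missing
flank conditions on the nearest observed marker on that side, and two
missing sides give $p_0 = 1/2$. We chose Haldane precisely because it makes
this conditioning exact under crossover independence; the Kosambi function
is available for distance/fraction conversion where a user's map was built
with interference in mind. Interval mapping regresses the trait on the
conditional expectation $E[\text{genotype}\,|\,\text{flanks}]$
(Haley–Knott regression) at every grid position, and

$$\mathrm{LOD} = \frac{n}{2}\,\log_{10}\!\frac{RSS_0}{RSS_1}.$$

Haley–Knott is a deliberate simplification of full interval-mapping maximum
likelihood: for DH designs, where the conditional genotype distribution is
two-point and missingness is modest, the regression approximation is close
to the likelihood scan but orders of magnitude faster — which matters when
the same engine must scan thousands of transcripts and thousands of
permutations. The grid walks in 1-cM steps, restarting at every marker so
that markers are always evaluated exactly.

Composite interval mapping (CIM) adds background markers as covariates to
both the null and full models, excluding any cofactor within 10 cM of the
test position so a linked cofactor cannot absorb the local signal.
Cofactors are chosen by forward selection under the extended BIC
(penalty $k(\log n + 2\gamma\log m)$, $\gamma = 1$, cap 5). Classical BIC
is the textbook choice, but with a hundred-plus correlated candidate
markers the best single-marker deviance gain under the null is routinely
8–11 — above $\log n \approx 5$ — so plain BIC admits a spurious cofactor
in about half of null scans; the EBIC candidate-count term restores the
intended behaviour (no cofactor on pure noise in ≳90% of scans) while a
marker explaining 20% of variance at $n = 200$ is still selected
essentially always.

Significance is empirical: trait values are permuted across lines,
genotypes fixed, the genome rescanned under the same model, and the
threshold is the type-7 $1-\alpha$ quantile of genome-wide maxima. Every
threshold object stores its seed and maxima. Permutation counts are a
compute/precision dial: 1000 by default, 200 in the test-suite studies
(the 5% quantile of 200 maxima is accurate to a few hundredths of a LOD,
enough for peaks that clear the threshold by whole LOD units).

Peak calling takes local maxima at or above the threshold, merges maxima
within 10 cM (ties to the smaller cM), and reports 1.5-LOD support
intervals with physical coordinates interpolated from flanking markers.
One rule here is ours: a maximum only counts as a distinct QTL if the LOD
dips at least the 1.5-LOD drop below it in the saddle toward every higher
peak on the chromosome. Without this *prominence* requirement, any strong
QTL under plain interval mapping spawns satellite "QTL" 15–40 cM away —
noise wiggles on its own linkage-correlation ridge that clear the
genome-wide threshold. The prominence constant is deliberately the same
1.5 LOD as the support-interval rule: a peak inside another peak's support
region is a shoulder, not a locus.

## The co-expression network

The network layer is the unsigned WGCNA construction: adjacency
$a_{ij} = |\mathrm{cor}(x_i,x_j)|^\beta$, topological overlap

$$\omega_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i,k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_u a_{iu}a_{uj},$$

average-linkage clustering of $1-\omega$, eigengenes as first principal
components (unit variance, sign-aligned with the module mean profile, with
the first member as fallback for degenerate means), iterative merging of
modules whose eigengenes correlate at 0.75 or above, and a hard
$|r| \ge 0.75$ edge list for export. Unsigned adjacency is intentional:
module–trait correlations of both signs are expected within one network.

$\beta$ is selected as the smallest power in 1–20 whose scale-free fit —
the signed $R^2$ of $\log_{10} p(k)$ on $\log_{10} k$ over ten equal-width
connectivity bins, positive when frequency decays — reaches 0.8. Two guards
are ours. First, eligibility requires mean connectivity of at least 1:
past that point the adjacency has decayed to near-zero and the fit index
rewards an empty network. Second, when no power qualifies, the fallback
takes the smallest connected power within 0.05 of the best fit rather than
the argmax, because near-equal fits must not push $\beta$ toward the
degenerate high end.

Module detection substitutes a deterministic static cut for dynamic hybrid
tree cutting: the tree is cut at 0.95 of its maximum merge height, branches
under 30 members are unassigned, and — replacing the PAM stage of the
dynamic algorithm — unassigned transcripts with eigengene correlation
$|kME| \ge 0.5$ are rescued into their best module. The 0.95 was calibrated
once on the planted-module generator (three blocks of 50/80/120 among 750
noise transcripts, loading 0.8): it separates all blocks on every seed
tried while leaving pure noise fully unassigned; 0.99 would swallow noise
into a single pseudo-module under average linkage, 0.90 occasionally fuses
the smallest block. The rescue step matters at higher powers, where
genuine members fragment off their block before the cut.

Module–trait association is plain Pearson correlation of eigengenes with
traits, $p$ from the $t$ distribution on $n-2$ degrees of freedom, pairwise
deletion, at least 5 shared lines. When the causal subnetwork is assembled,
"trait-associated" is made reproducible as BH-adjusted $p < 0.05$ across
the module × trait grid — eyeballing a heatmap is not a rule a pipeline
can apply.

## eQTL and integration

Each transcript's log2 abundance is scanned as a trait. Running a full
permutation test per transcript is quadratic waste; instead a pooled
*global permutation threshold* samples 100 transcripts without replacement,
permutes each 10 times, rescans, and pools the 1000 genome-wide maxima;
their 95th percentile is applied to every transcript. Scans default to
interval mapping rather than per-transcript CIM — across thousands of
transcripts the cofactor machinery costs far more than it changes, and for
single-eQTL architectures the two engines agree on the primary peak
location (CIM remains one flag away). An eQTL is **cis** when the gene has
a known position on the peak's chromosome within 4 Mb of the peak's
nearest marker — read as a gene–marker distance, with the alternative
shared-window reading available — **trans** otherwise, and **unplaced**
when the gene has no position. Trans-hotspots are counted in 10-cM bins
with a Poisson upper tail against the genome-wide mean bin count,
BH-adjusted.

Network QTL scans every module eigengene with the CIM engine against a
module-specific permutation threshold, labelling peaks
`qModule<k>_<chrom>_<i>`. Colocalization of two peaks requires the same
chromosome and either overlapping support intervals or peaks within 10 cM
(OR-combined — support intervals are the better-calibrated object, but
peak distance rescues short intervals from razor-thin misses). Candidate
genes inside trait-associated modules are then tiered: `cis-colocal`
(cis-eQTL colocalizing with a trait pQTL — the gene's own regulatory
variation tracks the trait locus), `trans-colocal`, `module-only`.
Fisher enrichment of functional categories uses the one-sided
hypergeometric test with the universe defaulting to all transcripts that
survived expression filtering — enrichment against the whole array would
flatter any expressed-gene set.

## Expression preprocessing

Two-colour arrays are normalized within array by MA-lowess (span 0.3
default; dye-swapped arrays sign-flipped before pooling) and between
arrays by quantile normalization (tie-averaged; every column gets the
row-mean order statistics exactly). Probes are kept only if intensity
exceeds 20 in at least 30% of samples — the reading of the filter under
which low-signal probes are the ones removed — then values below 20 are
floored to 20 as background and log2-transformed; replicates are averaged
on the log2 scale. Parental differential expression uses the pooled
Student $t$ (not Welch — the equal-variance test is the named method),
BH control at FDR 0.05, and a 2-fold geometric change computed after
flooring; fold change on the floored scale is a choice, made because the
floor is declared the background level and ratios below it are noise.

## The synthetic generator and what passing means

`simulate_study()` draws each DH line as one F1 gamete: a Markov walk over
the marker grid with Haldane transition probabilities, two homozygous
classes, physical positions proportional to genetic ones. The default
genome is compact by design — 3 chromosomes × 100 cM × 40 Mb, one marker
per 2 cM, 96 lines as in the classical DH seed-quality design — dense
enough that the 4-Mb cis window is a meaningful test, small enough that
the full pipeline runs in seconds. Expression follows a one-factor model
per module, $x = \lambda z + \sqrt{1-\lambda^2}\,\varepsilon$ with the
latent $z$ receiving a configurable share `hub_r2` of its variance from a
hub marker's genotype; the module's first transcript is its hub gene,
physically placed at that marker, so cis-eQTL, mQTL and pQTL truths are
planted jointly. Traits are variance-component sums of module latents and
direct marker effects plus Gaussian noise, with correlated sibling traits
(shared-core correlation 0.9, emulating a panel of fibre fractions mapping
to the same loci) and independent decoys. Missingness defaults to zero
and is available as an option.

The recovery studies in the test suite use these conditions: 200 lines
for power at planted effects of $R^2$ 0.2–0.3, 50 scan replicates, 200
permutations per threshold, 10 clustering seeds, 20 end-to-end
replicates. One benchmark fixes the network power at $\beta = 5$ rather
than using automatic selection: the planted factor structure is *not*
scale-free, so the fit index is flat and noisy at this scale (selected
powers ranged 1–7 across seeds, with recovery collapsing at both
extremes), whereas $\beta$ 4–6 keeps mean connectivity in the unit range
and recovery above 0.92 on every seed — fixing the analysis power for a
given dataset is exactly what a practitioner does after inspecting the
fit curve.

What passing these tests shows: the engine computes the statistics it
claims (to $10^{-8}$ against independent oracles), controls genome-wide
type-I error at its nominal level, and recovers architecture it is
designed to detect at realistic effect sizes. What it does not show:
robustness to segregation distortion, genotyping error, batch effects,
non-Gaussian expression noise, overlapping or nested modules, or
trans-regulatory cascades — none of which the generator emulates. Real
microarray data also carry probe-level artefacts (cross-hybridization,
saturation) that enter upstream of this pipeline.

## Numerical conventions

Coordinates are cM floats and 1-based inclusive bp internally; BED I/O
converts at the boundary. Additive effects are half the parent-0 minus
parent-1 class difference, so a positive sign sources the trait-raising
allele to the parent coded 0. Equal-LOD peak ties resolve to the smaller
cM, then chromosome order. Saturated fits (numerically zero residual)
report LOD at a guard ceiling of 300 with a flag rather than infinity.
Permutation quantiles are type-7. All pipeline randomness derives from one
root seed through named per-stage substreams (`stage_seed()`), so stages
rerun independently yet deterministically; generator output is
byte-identical under a fixed config and seed.

## Known limitations

The merged representative of peaks within 10 cM keeps the maximum-LOD
record; a joint refit of merged peaks might place the representative
better when two true QTL sit 10–15 cM apart. The static cut + rescue is
simpler and more predictable than dynamic hybrid cutting but will split
or miss modules with strongly unequal within-module correlation. The GPT
applies one threshold to all transcripts, ignoring per-transcript
distributional differences — that is its design trade-off. And interval
mapping's satellite-peak suppression via prominence is a heuristic: a
genuine secondary QTL closer than the prominence saddle allows will be
absorbed into its neighbour.
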