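---
title: "From two-color SNP-array signals to a binned RIL linkage map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From two-color SNP-array signals to a binned RIL linkage map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilmap)
```

rilmap implements the computational chain behind a genotyping-array study of
a recombinant inbred line (RIL) population: designing allele-specific probes
from a read pileup, preprocessing two-channel hybridization signals, calling
genotypes against a parents/F1 training set, filtering markers and samples,
building a binned genetic map under the Haldane mapping function, refining
calls along the map, and scanning the genome for recombination-rate
variation and segregation distortion. Because the package is exercised
end-to-end on synthetic data, this vignette describes both the analysis
methods and the generative model they are tested against, and is explicit
about what the synthetic world does and does not share with real arrays.

## The population model

A RIL population is produced by selfing a single F1 plant for $t-1$
generations. Per locus, selfing halves heterozygosity each generation
(AB → ¼ AA, ½ AB, ¼ BB; homozygotes breed true), so at generation $t$ the
expected genotype proportions are

$$p_{AA} = p_{BB} = \tfrac{1}{2}\left(1 - 2^{-(t-1)}\right), \qquad
  p_{AB} = 2^{-(t-1)},$$

which at $t = 7$ (an F7 plant, F7:8 seed) gives the familiar
$63/128,\; 2/128,\; 63/128$. `expected_ril_probs()` iterates this
transition rather than hard-coding the result.

Linkage is preserved by simulating whole gametes: each meiosis draws a
Poisson number of crossovers with mean equal to the chromosome's genetic
length in Morgans and places them uniformly on the cM scale — the Haldane
no-interference model, chosen to match the Haldane mapping function used in
map construction. Between two loci $d$ cM apart the per-meiosis
recombination fraction is $r = (1 - e^{-d/50})/2$, and the *observed*
recombinant fraction among selfed RILs converges to the Haldane–Waddington
value $R = 2r/(1+2r)$; `pairwise_recfrac()` inverts this when estimating
$r$ from RIL genotypes (`ril_correction`, on by default — switching it off
demonstrably inflates map lengths).

Chromosomes carrying a single marker skip the crossover machinery (the
marginal transmission of one locus is a fair coin); configurations with
thousands of single-marker chromosomes are the package's way of simulating
*unlinked* loci, used whenever a binomial error model for genotype-frequency
checks is wanted.

Segregation distortion is modeled as zygote viability selection at the
marker nearest the midpoint of a configured interval: genotypes AA/AB/BB at
that anchor survive with relative weights $w^2 : w : 1$. Rejected lines are
replaced by freshly simulated lines subjected to the same selection, so
population size is preserved and linked markers are distorted purely through
hitchhiking. With $w = 3$ the post-selection expectation at the anchor is
$\delta = p_{AA} - p_{BB} \approx 0.79$, decaying with genetic distance from
the anchor. A one-episode selection is the simplest mechanism consistent
with one-sided distortion regions; it does not attempt to model when during
line development the selection acted.

## The signal model and why its parameters look the way they do

Each SNP is interrogated by four probes — two alleles × forward/reverse
strand replicates. A sample's signals are centered on the cluster center of
its genotype (`cluster_centers`, linear intensities; defaults 2048/128 for
homozygote bright/dim channels and 724/724 for heterozygotes, i.e. log2
values 11/7 and ~9.5). Noise is multiplicative: Gaussian on the log2 scale
with `noise_sd` (default 0.35). Three artifact layers motivate the
preprocessing stages:

* a per-probe affinity offset (`probe_effect_sd`, default **3** log2 units),
  constant across arrays — removed by per-probe median centering;
* a per-array brightness offset (`array_effect_sd`, default 0.2) — removed
  by quantile normalization and median polish;
* optional 3×3 high-intensity blobs on the probe grid
  (`spatial_defect_rate`) — removed by the spatial filter.

The affinity spread deserves a comment because it is load-bearing. On real
hybridization arrays probe-to-probe affinity differences span several log2
units and dwarf the allele contrast. That property is what makes
between-array quantile normalization safe: all arrays — including the F1
training arrays, which are heterozygous at *every* SNP — then have nearly
the same whole-array intensity distribution. If the affinity spread were
small, an all-heterozygous array would have a much narrower distribution
than a segregating array, and quantile normalization would rank-stretch it,
smearing the AB training cluster. The default of 3 log2 units places the
generator in the realistic regime; setting `probe_effect_sd` well below 1
reproduces the pathological one, which can be instructive but is not how
arrays behave.

The 16 training hybridizations (6 parent-A, 5 F1, 5 parent-B) are generated
alongside the RIL arrays. `miscluster_rate` (default 0.0067) draws a
training point from a wrong cluster; the default was chosen so that the
expected share of accepted training sets with exactly one misclustered
signal is about 9.8%, the share observed on the real array this package
emulates (solving $16\rho/(1+15\rho) = 0.098$).

## Preprocessing

`process_signals()` applies, in order: log2 transform → quantile
normalization between arrays (mean of order statistics, mid-rank ties;
missing entries leave and re-enter as missing) → per-probe median centering
→ optional spatial-defect masking → median-polish summarization of the
strand replicates into one (A, B) signal pair per SNP per sample. Quantile
normalization and probe centering are idempotent, which the tests assert.

The spatial filter reconstructs the slide grid from the probe layout and
masks probes deviating from the local median surface by more than
$k$ local MADs (radius 3, $k = 5$). The MAD is floored at $10^{-8}$ so that
gross outliers on a flat background are still caught. Probes whose whole
neighborhood is missing are left unmasked with a warning. This is a
deliberately simple stand-in for published spatial-artifact methods; its
contract — remove scratch/bubble-like outliers before summarization — is
all the downstream stages rely on.

Median polish runs on the 2 × arrays replicate matrix per (SNP, allele)
with at most 10 iterations and a $10^{-8}$ convergence tolerance; the
per-array summary is the overall effect plus the array column effect. For
complete two-replicate data this summary equals the replicate mean and the
vectorized implementation agrees with `stats::medpolish()` exactly; with
masked cells the median-polish fixed point is not unique and small
(≪ noise) differences from the reference routine can occur.

## Genotype calling

Per SNP, k-means with $k = 3$ partitions the 16 training points,
initialized deterministically from the expected-label group means (no seed
sensitivity on 16-point problems). Clusters inherit the majority expected
label of their members; a label conflict rejects the SNP. A training set is
`GTS_perfect` when every point clusters with its expected label,
`GTS_one_off` with exactly one disagreement, and `rejected` otherwise —
"three distinct clusters" is operationalized purely by this label-agreement
rule, not by a separation statistic.

Cluster covariances come from 5–6 points each, so they are shrunk toward
the pooled diagonal covariance: $\Sigma_c = (1-\lambda)S_c + \lambda D$.
The default is $\lambda = 0.5$. The statistical argument: with $n$ points
per cluster, the squared Mahalanobis distance of a new point under the
*estimated* covariance is approximately a scaled $F_{2,n-2}$, whose heavy
tail at $n \approx 5$ pushes 2–3% of perfectly ordinary points past the
confidence cutoff below. Equal weighting between the cluster's own shape
and the 13-degree-of-freedom pooled diagonal removes that artifact without
erasing genuine shape differences; lighter shrinkage (e.g. 0.1) measurably
inflates the no-call rate far beyond what the real study reported.

A test point is assigned by Mahalanobis distance: $d_0$ to the nearest
cluster (the tentative call), $d_1$ to the nearest other cluster, and the
confidence is $d_1/(d_1+d_0)$, which lies in $[\tfrac12, 1]$ by
construction. Calls with confidence not exceeding `nc_threshold`
(default 0.6, the low-confidence definition) become no-calls (NC).

## Marker and sample filtering

Applied in narrative order by `filter_markers()`:

1. **Redundancy dedup.** Markers with byte-identical call vectors
   (including NC patterns) form a group; the member with the largest
   minimum pairwise Bhattacharyya distance among its three training
   clusters represents the group (ties → lower marker id). Group membership
   is kept so members can be re-attached to their representative's bin.
2. **Low-confidence filter.** Calls with confidence ≤ 0.6 are
   low-confidence; markers whose low-confidence count exceeds the
   across-marker median by more than one *unscaled* MAD are dropped (the
   raw median absolute deviation, not the 1.4826-scaled estimator — "1 MAD
   unit" is read literally).
3. **Segregation filter.** A χ² goodness-of-fit of (AA, AB, BB) counts
   against the generation-$t$ expectation, Bonferroni-corrected over tested
   markers. The AB category participates only when its expected count
   $n \cdot p_{AB}$ is at least 5 (the Cochran validity rule); below that
   the test compares AA against BB. At the study scale
   ($n \approx 120$, expected AB ≈ 1.9) the 3-category statistic is badly
   anticonservative — simulation puts its Bonferroni family-wise error
   above 0.4, versus ≈ 0.02 for the homozygote test — so pooling is the
   difference between a filter that works and one that throws away good
   markers.
4. **Sample QC.** Samples with heterozygous share above 0.2 (of called
   genotypes), homozygous share below 0.15 (of all markers — the
   "uninformative" rule is about how little usable signal a sample
   carries, so NC counts against it), or more than 10 no-call regions
   after refinement are removed.

## Map construction

`build_linkage_map()` mirrors a standard RIL mapping run with the
parameters fixed up front: linkage p-value cutoff $10^{-10}$, marker
missing-call threshold 0.15, Haldane distances, minimum group size 2.
Grouping is single-linkage over the two-locus independence χ² on the 2×2
homozygote table (Fisher's exact fallback when an expected cell is
below 5). Ordering minimizes the sum of adjacent recombination fractions:
groups of ≤ 10 markers are solved exactly by Held–Karp dynamic programming;
larger groups use a greedy chain extended at either end plus 2-opt segment
reversals, with all ties broken by ascending marker id and the final
orientation canonicalized. Adjacent markers with zero observed recombinants
merge into bins; bin positions are cumulative Haldane distances.

Two behaviors worth knowing: (i) the linkage cutoff interacts with sample
size — with fewer than ~110 informative lines even perfect cosegregation
cannot reach $p < 10^{-10}$, so grouping needs either the study's sample
size or a looser cutoff; (ii) because ordering *minimizes* adjacent
recombination, sampling noise lets it locally reorder near-cosegregating
markers into slightly-too-short chains, so recovered map lengths sit a few
percent below truth (about 8–14% at 200 markers × 120 lines). This mild
compression is shared by ML-style ordering tools and is why the
length-recovery check uses a ±15% band.

## Refinement

Two rules run per sample along each linkage group, regions first (the
larger pathology), then loci:

* **Region rule.** A maximal stretch of consecutive short runs (each below
  3 loci) containing at least two distinct call values and spanning ≥ 12
  loci is an unresolvable mosaic and becomes NC entirely.
* **Locus rule.** A locus differing from *both* immediate neighbors is
  re-examined: if six consecutive uniform same-call loci flank it on both
  sides with a common (non-NC) call, it takes that call; otherwise it
  becomes NC. Loci within six positions of a chromosome end are never
  modified — conservatism at the boundary beats manufacturing calls there.

The singleton trigger (differs from both neighbors) is a deliberate
reading of "a locus call different from its flanking loci": the
alternative — triggering whenever a locus differs from either neighbor —
would blank every genuine crossover boundary, since there one flank is
uniformly the old allele and the other uniformly the new one. Under the
chosen reading refinement never touches a call inside a uniform block of
its own value, is idempotent (asserted on hundreds of randomized block
sequences), repairs the vast majority of isolated errors, and shifts the
heterozygous fraction down and the NC fraction up — the directions observed
on the real data. What it cannot repair: errors within six loci of a true
breakpoint or chromosome end (they become NC or stay), and adjacent error
pairs. It will also erase genuine short double-crossover or gene-conversion
tracts; no attempt is made to distinguish them.

## Genome scans

* **Local recombination rate** (`local_recomb_rate()`): per linkage group,
  markers whose genetic order contradicts the physical order are removed
  (longest nondecreasing subsequence after orientation), cM is
  lowess-smoothed against Mb with span 0.1, and the least-squares slope of
  each sliding 5-marker window is reported in cM/Mb and log10(cM/Mb)
  (smoothed slopes are floored at $10^{-6}$ before the log).
* **Segregation-distortion scan** (`segregation_scan()`): per marker,
  $\delta = p_{AA} - p_{BB}$ with a 1-df χ² against equality
  (heterozygotes excluded, matching the $p_{AA}/p_{BB}$ formulation),
  Benjamini–Hochberg control at 5%, and SDR intervals defined as maximal
  runs of ≥ 3 consecutive significant markers favoring the same allele.
  The run rule is this package's operationalization — the source study
  showed its distortion regions graphically without a numeric rule. The
  cross-validated cubic smoothing spline of $\delta$ against position is
  reporting-only and can be disabled in simulation loops.
* **Collinearity** (`collinearity()`): per group, $R^2$ of cM on Mb after
  resolving orientation by the rank-correlation sign, plus the fraction of
  markers on the group's majority chromosome.
* **Bin polymorphism** (`bin_polymorphism()`): a bin is covered when any
  member marker shows ≥ 2 distinct non-NC calls across an accession panel;
  the replaceability of non-polymorphic markers by bin-mates is reported.
  The panel generator marks markers polymorphic with a spatially
  autocorrelated Markov state (stationary share 0.53, persistence 0.9 per
  marker step) — haplotype-block-like sharing, not a population-genetic
  model. Bin-level coverage numbers depend strongly on markers-per-bin, so
  at desk scale (few markers per bin) they sit well below what an
  11,000-marker array achieves.

## What the synthetic world does and does not establish

The generator reproduces the statistical structure the methods assume:
selfing-equilibrium genotype frequencies, Haldane linkage, three Gaussian
signal clusters with array/probe/spatial artifacts, a 6+5+5 training
design, depth-calibrated pileups and nested gene models. Passing tests
therefore show the chain is *self-consistent* — each stage removes the
artifact layer it targets and recovers the simulated truth. They cannot
show robustness to what is not simulated: dye-specific bias, saturation,
cross-hybridization between paralogous probes, batch structure beyond a
scalar array effect, genotyping errors correlated across samples, or
assembly errors in the physical positions. Interpret accuracy numbers as
upper bounds that real data will erode.

## Problem sizes and runtime choices

The default configuration — 7 chromosomes with the study's linkage-group
lengths, ~2,000 markers, 120 RILs, 16 training arrays — runs the full
pipeline in about two minutes on one core, and is the scale at which the
package's own checks operate: genotype-frequency checks use 2,000 unlinked
loci × 200 lines, map recovery one 100-cM chromosome with 200 markers ×
120 lines, error-rate control 200 null replicates of 2,000 markers, and
distortion recovery 20 seeded replicates with a viability weight of 3.
These sizes were chosen as the smallest at which the binomial/χ² error
models apply comfortably; everything scales linearly except all-pairs
recombination matrices (quadratic in markers after dedup).

## Known limitations

* The probe designer optimizes melting temperature only (SantaLucia
  nearest-neighbor tables, natural-log concentration term, target 80 °C,
  effective strand concentration $10^{-7}$ by default — the last two are
  conventions, as the source protocol names neither); it does not screen
  secondary structure or cross-hybridization.
* The quality threshold for pileup candidates is interpreted on the PHRED
  scale only.
* Map construction is a compact stand-in for a full MST-based mapper: the
  published parameters are honored where they have an in-repo meaning
  (p cutoff, missing threshold, Haldane, minimum group size), and recorded
  but inert otherwise.
* `benjamini_hochberg()` delegates to `stats::p.adjust`; it exists so the
  scan's correction is explicit, testable against a brute-force step-up
  oracle, and swappable.
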