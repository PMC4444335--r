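---
title: "Methods: Tamp fitness landscapes from pooled chemostat competitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Tamp fitness landscapes from pooled chemostat competitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tampscape)
```

# Overview

`tampscape` analyzes pooled competition screens of telomeric amplicons
(Tamps): diploid strains that each carry one extra copy of everything from a
chosen initiation point to the proximal telomere. The pipeline runs in five
stages — bar-seq counting, per-replicate fitness regression, replicate
aggregation with filtering, genome-ordered segmentation, and cross-condition
driver analytics — and is paired with a simulator that plants a known
fitness landscape so every stage can be validated against ground truth.
This vignette documents the model, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

# The measurement model

## From reads to trajectories

Each read carries three barcodes: a 6 bp multiplexing barcode identifying
the sample (condition x chemostat x time point), a strain-identifying
barcode (the deletion-collection barcode marking the Tamp's initiation
gene, 20 bp by default), and a random replicate barcode marking the
independent transformant (12 bp by default; some processed exports use
10 bp, so the length is configurable). Demultiplexing and barcode matching
are exact by default, with a configurable Hamming radius; a barcode table
whose entries collide within twice the radius is rejected at load time.
Read-count conservation (assigned + unassigned + unknown-barcode = total) is
asserted in the test suite.

A lineage's trajectory value at time point *t* is

$$ y_t = \log_2\frac{(c_t + 1)/N_t}{(c_0 + 1)/N_0}, $$

with the pseudocount applied to read counts, not frequencies, and the
denominator being total assigned reads in the sample (robust to junk
reads). The t0 point (identically 0) is retained internally and implied in
the 9-time-point CSV interchange schema (`gene, mer, replicate, t1..t9,
g1..g9`).

## From trajectories to per-Tamp fitness

Relative fitness per replicate is the OLS slope of \(y\) on generations with
a free intercept: t0 sampling noise enters every ratio, and a free intercept
absorbs it (the assay does not force the line through the origin). At least
3 non-missing points are required (`min_points = 3`; two points always fit
perfectly and carry no error information); sparser trajectories are reported
as `NA`, mirroring the screen's treatment of insufficient reads. Slopes are
averaged (unweighted) across the technical-replicate chemostats per
biological replicate, then optionally shifted so a neutral reference strain
is exactly 0.

Two defenses handle the strain-construction error rate (half of
genome-wide-pool transformants carry truncated amplicons or unrelated
aneuploidies):

* **Variance filter.** Tamps whose biological replicates have sample SD
  above a threshold are dropped. The published pipeline states only the
  outcome (~20% of Tamps excluded), not the cutoff, so the default is
  SD > 0.05 and `calibrate_variance_threshold()` can pick the cutoff that
  removes any target fraction.
* **Mode aggregation.** With more than 15 biological replicates the Tamp
  fitness is the mode of the replicate distribution — Gaussian KDE with
  Silverman (`nrd0`) bandwidth, argmax over a 512-point grid spanning
  `[min − bw, max + bw]` — which tracks the correctly constructed majority
  even at 40% contamination; with 15 or fewer, the arithmetic mean. The SE
  is reported as SD/sqrt(n) for both paths for comparability (a 200-resample
  seeded bootstrap SE for the mode is available by flag).

# Segmentation and breakpoint classification

Neighboring Tamps share everything telomere-ward of the more telomeric
initiation point, so the fitness profile is expected to be piecewise
constant: plateaus separated by steps wherever a driver or anti-driver gene
enters the amplified region. The profile (per condition, ordered by
chromosome and initiation position, dropped Tamps excluded) is segmented by
a native circular binary segmentation engine:

* statistic: standardized mean difference between an arc \((i, j]\) and its
  complement, scaled by the segment SD (a constant under permutation, so the
  test is calibration-exact);
* acceptance: within-segment permutation test, default 10,000 permutations,
  split accepted at p < α = 0.05 (the screen's published setting), with
  early termination once the exceedance count guarantees p ≥ α;
* constraints: every resulting plateau keeps at least `min_width = 2` points
  (the published minimum); ties break to the smallest start index, then the
  smallest arc; adjacent segments with numerically equal means are merged;
* determinism: permutations consume R's RNG, so a seed fixes the output;
  recursion is depth-first with a deterministic stack order.

Segmentation runs per chromosome (arms are not segmented separately), but a
boundary is only classified when both flanking segments lie on one arm:
`delta` = telomere-side mean − centromere-side mean, evaluated in that arm's
telomere direction (+ coordinates on the right arm, − on the left).
`delta < 0` is a Downstep (a candidate driver lies in the boundary region:
Tamps that include it are fitter), `delta > 0` an Upstep (anti-driver).
Boundaries involving a centromere-spanning segment are reported as
`cross_centromere` and excluded from gene-level analyses, since "toward the
telomere" is undefined there. Breakpoint regions span the interval between
the flanking Tamps' initiation positions plus, by default, one additional
gene on the centromere side, compensating for boundary insensitivity at the
screen's 3–4 gene resolution.

Calibration of the permutation test was verified directly: on pure-noise
profiles (n = 40, SD 0.015) the false-split rate is 5.5% at α = 0.05. A
consequence worth knowing: CBS without post-hoc split pruning produces
roughly α false boundaries per tested segment, so on landscapes with very
few true breakpoints the false-discovery share rises even though the
absolute false-positive rate is fixed.

# The simulator

`plant_landscape()` draws, per condition and chromosome, breakpoints at
gene-start positions (3 per chromosome by default, segment levels iid
N(0, 0.1), matching the screen's segment density of roughly 250 segments
over ~1,600 Tamps x 3 conditions and its observed fitness range) with a
configurable fraction of breakpoints shared across conditions (default
0.06, reflecting how few regions act in all conditions). `make_truth()`
assigns each Tamp Poisson(26) biological replicates (the stated average;
the distribution itself is not published, and Poisson asserts nothing
beyond the mean), a per-Tamp neutral host background drawn uniformly from
[−0.05, 0.04] (the fitness range of the neutral deletion strains used as
hosts), and applies the strain-construction error model: each replicate is
aberrant with probability 0.5 (genome-wide pool; the targeted pool ran
nearer 0.2), realized as a truncation at a uniformly chosen gene boundary
telomere-ward of the initiation gene — uniform is the least-assumptive
choice; the observed size-dependence of truncation emerges naturally — or,
with probability 0.05, as an unrelated aneuploid event modeled as a
N(0, 0.1) fitness offset.

Selection is deterministic exponential ratio dynamics,
\(f_i(g) \propto f_i(0)\,2^{s_i g}\), renormalized at each sampled
generation; all stochasticity is multinomial read sampling at the
configured depth (an optional binomial bottleneck exists but is off by
default). The fitness unit is log2-frequency-ratio change per generation.
Pairwise GFP competitions are generated in natural-log units — their slope
is \(s\ln 2\) — and `gfp_competition_fitness(log2 = TRUE)` applies the
conversion so both assays agree on shared truth. Per-sample read depth is
not published (only lane totals), so it is a free parameter defaulting to
10^6 reads/sample; competitions default to 25 generations sampled at 10
time points and a dilution rate of 0.17 h^-1 (informational).

**What the simulator does not emulate:** within-chemostat drift and clonal
interference; de novo mutation during the assay; PCR/sequencing biases
beyond multinomial sampling; position-dependent truncation rates; nutrient
dynamics (no chemostat ODEs). Passing recovery tests therefore show the
*analysis* is correct under the stated error model, not that the model
captures every failure mode of real pools.

# Resolution limits and validated regimes

The per-Tamp host background (uniform on [−0.05, 0.04], SD ≈ 0.026) is
shared by all replicates of a Tamp, so no amount of replication removes it:
it is the effective per-point noise floor of the landscape. Steps below
~0.05 are therefore at or below the assay's designed resolution, and
end-to-end runs recover them only sporadically — while the fitted profile
itself tracks landscape-plus-background to within ~0.005 at depth 2x10^5.
The segmentation engine's planted-breakpoint recovery is validated in the
regime the 26-replicate design targets: steps ≥ 0.05 against per-point
noise SE 0.015, where precision and recall exceed 0.9 over 50 seeded
landscapes.

Problem sizes used by the test suite and the acceptance script were chosen
to exercise every code path at desk scale: toy genomes of 1–2 chromosomes
with 8–40 genes, pools of up to ~26 replicates x 3 chemostats x 10 time
points at depths up to 10^6, 60-point segmentation profiles, and 2,000–
5,000 permutations per tested split (10,000 by default in production runs).

# Statistical machinery

The analytics layer implements the tests the screen's analysis relies on,
with independent cross-checks in the test suite:

* exact Wilcoxon rank-sum: full enumeration of all C(nA+nB, nA) rank
  assignments (mid-ranks for ties) for combined n ≤ 12, two-sided p as the
  doubled smaller tail capped at 1; tie-corrected normal approximation
  above;
* Fisher's exact test: two-sided hypergeometric summation of all tables as
  or less probable than the observed one (with a 1e-7 relative tolerance on
  the probability comparison, as is conventional);
* Holm–Bonferroni: step-down multiplication with enforced monotonicity,
  capped at 1;
* Downstep-vs-Upstep contrast: pooled-variance two-sample t-test by default
  (the published analysis says only "unpaired, two-tailed"); Welch by flag;
  the degenerate all-equal case returns t = 0, p = 1;
* pleiotropy: between-condition sample variance (n − 1 denominator).

aCGH population frequencies invert the mixture model
\(\hat c = p\,2^{\overline{\log_2 r}}\) over the region's probes (arithmetic
mean, which matches the mixture algebra) with
\(f = (\hat c - c_{base})/(c_{clone} - c_{base})\) clamped to [0, 1]; when
the clonal copy number is unknown it is the population copy rounded up to
the next integer above baseline, and frequencies under the 6% detection
limit are flagged.

# Design decisions and open points

* **Initiation coordinate.** Whether a Tamp's initiation position is the
  deleted gene's start or end is ambiguous at the screen's resolution; both
  are supported (`init_at`), defaulting to the gene start.
* **Genes spanning the centromere** are assigned to the arm holding their
  midpoint — deterministic and unbiased.
* **Coordinates** are 0-based half-open in memory and 1-based inclusive in
  all files, following the common genome-arithmetic/community-format split.
* **Technical replicates** are fitted per chemostat and then averaged;
  fitting a single pooled regression instead is a documented alternative
  the schema supports, but per-chemostat fits are robust to one failed
  chemostat.
* **Union regions.** When another condition's breakpoint splits a segment,
  the region inherits the covering segment's mean for that condition.
* **Reporting.** The cross-condition "summed fitness" display is treated as
  reporting, not inference: a per-region sum in the report writer.
* **Cross-centromere counting.** Whether published region counts exclude
  cross-centromere boundaries is not stated; `tampscape` reports them in
  region tables but never classifies or gene-annotates them.

# Limitations

Segmentation assumes plateaus; smoothly varying fitness (e.g. a genuine
per-kilobase cost of amplification) would be approximated by a staircase.
The variance filter reproduces a stated exclusion outcome only by
calibration, since the original rule is not published. The classifier's
requirement that both flanking segments sit on one arm is conservative on
sparse profiles, where a single segment often spans the centromere. And all
validation is against the simulator's error model: replicate barcodes
attached to structurally wrong amplicons in ways that error model does not
generate (e.g. barcode swaps) would pass undetected.
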