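# tampscape

Genome-wide fitness screens of **telomeric amplicons (Tamps)** — segmental
amplifications that start at a genomic position and extend to the nearest
chromosome end — measure how aneuploidy-scale copy-number changes affect
cellular fitness. In the assay this package analyzes, thousands of barcoded
diploid yeast strains, each carrying one Tamp, compete in nutrient-limited
chemostats for ~25 generations; strain frequencies are read out at ten time
points by sequencing a three-barcode cassette (multiplexing barcode, a
strain-identifying "Tamp" barcode, and a random replicate barcode marking
each independent transformant). `tampscape` turns those reads — or a
simulated equivalent — into per-amplicon relative fitnesses, a segmented
genome-wide fitness landscape, classified fitness breakpoints, and candidate
driver genes, for geneticists studying aneuploidy and experimental
evolution.

## The model

For each replicate lineage *i*, relative fitness is the slope of

> log2( f_i(t) / f_i(0) ) versus generations,

estimated by ordinary least squares with a pseudocount of 1 added to read
counts, and normalized so a neutral reference strain sits at 0. Biological
replicates of a Tamp are aggregated by the **mode** of their fitness
distribution (Gaussian KDE, Silverman bandwidth) when more than 15
replicates are available, otherwise by the mean; the mode is robust to the
large fraction of mis-constructed (truncated) amplicons the strain
construction produces. Tamps whose replicates disagree strongly (sample SD
above a threshold) are excluded.

The genome-ordered fitness profile is segmented by **circular binary
segmentation** (native implementation): recursively, the arc (i, j]
maximizing

> T = (mean_in − mean_out) / ( s · sqrt(1/k + 1/(n−k)) )

is accepted as a change if its within-segment permutation p-value is below
α = 0.05 and every resulting plateau keeps ≥ 2 points. Each boundary is a
**Downstep** (fitness falls toward the telomere; flags a driver gene whose
amplification raises fitness) or an **Upstep** (fitness rises toward the
telomere; flags an anti-driver), with cross-centromere boundaries left
unclassified. Downstream analytics include cross-condition region unions,
common-effect calls (>5% in all conditions), driver-candidate filtering
against evidence gene lists, amplicon fitness prediction, pleiotropy
(between-condition variance), exact Wilcoxon rank-sum and Fisher tests, and
Holm–Bonferroni correction. A seeded chemostat simulator (deterministic
exponential selection + multinomial read sampling, with the documented
strain-construction error model) makes every stage testable without the
original sequencing data.

## Worked example

Simulate one chromosome of 24 Tamps under sulfate limitation (26 replicates
per Tamp on average, 3 chemostats, 50% aberrant replicates), estimate
fitness, and segment the landscape:

```r
library(tampscape)

genome    <- toy_genome(n_chromosomes = 1, chromosome_length = 120000,
                        genes_per_chromosome = 24, seed = 300)
landscape <- plant_landscape(genome, n_breakpoints = 3,
                             conditions = "sulfate", sharing_fraction = 0,
                             effect_sd = 0.12, seed = 301)
cfg    <- sim_config(mean_replicates = 26, tech_replicates = 3,
                     depth = 2e5, aberrant_prob = 0.5)
truth  <- make_truth(genome, landscape, cfg, seed = 302)
counts <- simulate_pool(truth, conditions = "sulfate", seed = 303)

fitness  <- tamp_fitness(to_trajectories(counts), reference = cfg$reference_id)
profile  <- build_profile(fitness, genome, "sulfate")
segments <- segment_profile(profile, seed = 304)
classify_breakpoints(segments, genome)
```

```
   arm region_start region_end   delta            class
1    L        25042      32653  0.0678           Upstep
2 <NA>        48152      62775      NA cross_centromere
3    R       103452     111623 -0.1116         Downstep
```

The three planted breakpoints (at 22,386, 62,775 and 111,623 bp; the planted
steps were −0.07, +0.10 and −0.08) are all recovered: an Upstep on the left
arm, an unclassifiable boundary at the centromere, and a Downstep of −0.11
on the right arm. The Downstep's candidate region plus one centromeric gene
is returned by

```r
breakpoint_region_genes(classify_breakpoints(segments, genome)[3, ], genome)
#> [1] "CHR1_g020" "CHR1_g021" "CHR1_g022"
```

`run_pipeline(pipeline_config(), outdir)` chains all stages (simulate or
ingest → fitness → segmentation → cross-condition analysis → report) with a
YAML-serializable configuration and a JSON manifest; identical config and
seed give identical outputs.

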