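---
title: "Simulating mosaic genomes and benchmarking local ancestry inference"
author: "mosaicsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating mosaic genomes and benchmarking local ancestry inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Why this package exists

Many crop genomes are mosaics: hybridization between differentiated
(sub)species followed by generations of reproduction leaves each chromosome
tiled with segments of distinct ancestral origin. Local ancestry inference
(LAI) methods try to recover that tiling from genotype data, but most were
developed for human data, where admixture usually involves two or three
sources, reference panels are large and phased, and reproduction is
outcrossing. Plant systems differ in ways that matter: more sources (up to
six-way admixture in cacao), sparse or absent source representatives, high
selfing rates, and long stretches of vegetative (clonal) propagation that
freeze the mosaic while the nominal "generations since admixture" keeps
growing.

`mosaicsim` simulates chromosome-wide diploid genotyping datasets under
exactly these conditions, tracks the true local ancestry of every sampled
chromosome exactly, and scores any inferred local ancestry against that
truth. It does **not** implement any LAI method itself; it produces the
datasets, the truth, and the accuracy metric.

## The simulation model

Simulation proceeds in three steps.

### 1. Founder haplotypes (structured coalescent)

`S` source populations split simultaneously from a single ancestral
population (a star-shaped history) and then diverge by drift alone — no
migration, equal sizes. Three scaled parameters control the founder phase,
with the effective size `Ne` deliberately not exposed:

* `tau` — divergence time. Its operational definition in this package is
  the differentiation it produces: the expected multi-locus Weir–Cockerham
  FST between any two sources is `expected_fst(tau) = 1 - exp(-tau)`.
* `theta = 4*Ne*mu` — scaled per-site mutation rate, with `Ne` the
  *haploid* effective size, so expected within-source per-site diversity is
  `theta / 2`.
* `rho = 4*Ne*r` — scaled per-site recombination rate.

The chromosome has genetic length 1 Morgan; with the example rates
`mu = r = 2.5e-8`/site this forces a physical length of `4e7` bp (the
default `map_length_bp`). Variant positions are stored as map fractions in
`[0, 1)` and converted to base-pair coordinates only on export
(`1 + floor(pos * L)`, bumping duplicate collisions upward).

**Calibration of the split time.** Internally the split is placed at
`T = exp(tau) - 1` in within-deme pair-coalescence units. The reason is a
standard but easy-to-miss property of the multi-locus (ratio-of-averages)
Weir–Cockerham estimator on sequence data: it converges to
`(Tb - Tw)/Tb`, the relative excess of the mean between-population pair
coalescence time `Tb = 1 + T` over the within-population time `Tw = 1`,
i.e. `T/(1 + T)` — *not* to the drift-variance expression `1 - exp(-T)`
that holds when all variation predates the split. We verified this against
an independent coalescent engine during development. Setting
`T = exp(tau) - 1` inverts the law so that the package's `tau` means what
the field's rule of thumb says it means: realized FST `≈ 1 - exp(-tau)`
(0.33 at `tau = 0.4`). The test suite checks this calibration across a
grid of `tau` values against the empirical simulation standard error.

**Recombination by windows.** The founder phase approximates the
ancestral recombination graph by cutting the map into up to 512 equal
windows (more for larger total `rho`), each carrying an independent
non-recombining Kingman tree; sites within a window are completely linked,
windows are unlinked. Every marginal-tree functional — FST,
heterozygosity, segregating-site counts, and everything downstream of the
forward phase — has exactly the same distribution as under the full graph;
only the founder-phase linkage *between* nearby sites is coarsened (LD is
slightly too high within a window and absent across window boundaries).
Datasets destined for LD-aware LAI methods inherit 50 generations of
forward-phase recombination on top, which dominates short-range admixture
LD. The window count grows with `rho` so that the monotone LD–`rho`
relationship is preserved (tested by rank ordering of mean r² across
`rho` values).

Mutations follow the infinite-sites model on the coalescent trees, so
every panel column is polymorphic across the full founder panel, and a
configuration too small to yield any segregating site raises an explicit
"empty panel" error.

### 2. Forward-in-time reproduction with exact tract bookkeeping

`P` populations of constant diploid sizes are founded by drawing whole
founder chromosomes (source first, by the population's contribution
vector; then a haplotype uniformly with replacement). Each chromosome copy
carries an ordered list of half-open ancestry tracts tiling `[0, 1)`;
founding chromosomes carry a single tract.

Each of `G` generations, every offspring of population `p` independently
draws one of four reproduction modes from the population- and
generation-specific schedule:

* **within** — two distinct parents from `p`, one gamete each;
* **across** — one parent from `p`, one from a uniformly chosen other
  population (offspring stays in `p`);
* **selfing** — two independent gametes from a single parent;
* **vegetative** — the parent's chromosome pair is copied verbatim,
  freezing both genotype and mosaic.

Meiosis places **exactly one crossover**, uniform on the 1-Morgan map (no
interference, no zero-crossover gametes): the gamete copies one parental
chromosome on `[0, b)` and the other on `[b, 1)`, for alleles and tracts
alike, merging adjacent same-source tracts. Mutation flips existing
alleles at per-site rate `mu_forward` (default `2.5e-8`, i.e.
`theta/(4*Ne)` at the example scaling — effectively negligible, kept for
fidelity); no new segregating sites arise after the founder phase, and
mutation applies to every offspring chromosome whatever the mode.

Two deliberately resolved ambiguities, both configurable:

* *Within-population mating excludes self-pairing* (distinct parents), so
  the mode proportions stay interpretable — selfing happens only through
  the explicit selfing mode. `allow_incidental_selfing = TRUE` restores
  independent parent draws.
* *Mutation acts per segregating site* rather than per physical site with
  non-segregating hits discarded; at the default rate the two readings are
  numerically indistinguishable.

### 3. Sampling and output

`o_p` individuals per population are drawn uniformly **with replacement**
(duplicates allowed, `o_p > n_p` valid). SNPs monomorphic across the whole
sample are removed; the kept-index map back to pre-filter indices is
retained. Outputs: VCF v4.2 (phased by default — the truth is phased — or
`/`-separated on request), plink `.ped`/`.map` (map distance in cM, 1/2
allele coding with an ACGT switch), a long-format truth dosage table (one
row per individual × SNP, one column per source, entries 0/0.5/1), a
BED-like tract table (0-based half-open bp intervals per chromosome copy),
a JSON run summary, and a manifest with MD5 checksums.

## The accuracy metric

With true dosages `z[s]` (0, 0.5 or 1; summing to 1 over sources) and
inferred proportions `x[s]` (non-negative, summing to 1), the per-cell
accuracy is

    alpha = 1 - sum_s |z[s] - x[s]| / 2,

bounded in `[0, 1]`, equal to 1 iff `x = z` and 0 iff the supports are
disjoint. The overall `alpha` averages cells over all SNPs and all
*admixed* individuals (source representatives are excluded). The
calibration floor is the uniform "random inference" `x = 1/S`, whose value
is a deterministic function of the truth alone. The coefficient of
determination and MSE are also available (`accuracy_metrics()`) but play
no role in acceptance.

**Missing sources.** When a source contributed to the admixed populations
but has no representative population (`SrcMiss`), cells whose true dosage
of the missing source is positive are excluded and the truth is reduced to
the represented sources. Masking is per (individual, SNP) *cell* by
default — it preserves the other individuals' data at that SNP and matches
the idea of scoring "regions originating from represented sources"; a
site-global variant (`per_site = TRUE`) drops a SNP for everyone as soon
as any admixed individual carries the missing ancestry there. When mask
sizes differ between individuals, cells (not individuals) are weighted
equally, consistent with averaging over markers and individuals jointly.

## Scenario presets and the stated world

`build_scenario()` encodes six presets sharing one baseline: 300 founder
haplotypes per source (mimicking a domestication bottleneck), populations
of 150 diploids, `theta = rho = 1e-4`, `G = 50` generations, samples of 20
per source-representative and 40 per admixed population, two admixed
populations with equal source contributions. The presets vary one axis
each: differentiation/age/sampling (`DiffGenSam`, where `G = tadm`),
sample imbalance (`SamBal`, third source sampled at 2), number of sources
(`SrcNum`, up to 6), a missing source (`SrcMiss`, 4 simulated / 3
represented, missing contribution up to 15%), selfing in the third source
population (`SrcSelf`, up to 99%), and vegetative propagation (
`AdmxVegProp`: 10 admixed populations of 100, sampled at 10, switching to
exclusive clonal propagation 0–45 generations before sampling).

Where a preset's varying parameter needs a single default, the package
uses the most contrasted value of the published range (e.g. `SrcNum`
S = 6, `SrcSelf` slf = 0.99): presets exist to exercise the scenario's
distinguishing stress, and every value is overridable. One documented
discrepancy: the source-representative sample size for `SrcNum` is listed
as 5 in the parameter table of the original design but as 20 in its
results legend; the package defaults to 20 (`op_src` overrides). The
choice is immaterial for the random baseline, which only scores admixed
individuals.

Replicate `r` of `run_replicates()` uses seed `base_seed + r - 1`; a fixed
base seed makes the whole pipeline — coalescent, forward phase, sampling —
bit-identical across reruns (tested).

### What the generator emulates, and what it does not

The synthetic data reproduce: calibrated neutral differentiation among
sources, domestication-scale founder numbers, mosaic genomes with
realistic tract-length decay in the age of admixture, selfing-driven
homozygosity, and frozen clonal mosaics. They do **not** contain
recombination hotspots or interference (exactly one uniform crossover per
meiosis), multiple chromosomes, selection, polyploidy, genotyping error,
or missing data. A green test therefore certifies the simulator and the
metric under this idealized world — it says nothing about LAI behaviour
under, say, hotspot-driven tract-length heterogeneity.

## Numerical choices and degenerate inputs

* Contribution rows must sum to 1 within `1e-9`; inferred-ancestry rows
  are renormalized (with a warning) when off by more than `1e-6` and
  rejected if negative or zero-sum.
* FST uses the ratio-of-averages combination; a pair with zero denominator
  at every locus returns `NA` with a warning rather than a number.
* Expected heterozygosity uses the unbiased `2n/(2n-1)` correction.
* Tract arithmetic is exact on doubles; breakpoints coinciding with an
  existing tract boundary (probability zero, but handled) produce no
  zero-length tracts.
* `G = 0` schedules, empty sample populations (`o_p = 0`), and `tau = 0`
  (no divergence) are all valid inputs; an all-monomorphic sample raises
  an explicit "empty dataset" error.

## A note on junction counts

A natural-sounding invariant — "a chromosome carries at most `g` tract
junctions after `g` generations" — is false under one-crossover meiosis:
a gamete can inherit junctions from *both* parental chromosomes (on either
side of the new breakpoint) plus the breakpoint itself, so the sharp
almost-sure bound is `2^g - 1`, and already at `g = 2` three junctions are
possible. What is true, and what the property suite asserts, is that the
*expected* junction count is at most `g` (each meiosis adds at most one
junction in expectation, since the prefix and suffix each contribute half
their parent's junctions on average) and that mean tract length decreases
monotonically with `g`. The acceptance suite also carries the literal
per-chromosome `<= g` check for transparency; it fails at small `g`
exactly as this analysis predicts (at `g = 5`, roughly 5–10% of
chromosomes exceed the naive bound), and is left failing deliberately.

## Known limitations

* Founder-phase LD is window-approximate (see above); if you need
  base-pair-faithful ancestral LD, substitute an external coalescent
  engine for the founder panel and feed it through `found_populations()`.
* The dense dosage array (`ancestry_dosage()`, `score_inference()`) is
  meant for desk-scale scoring; full-scale scoring goes through the
  compact per-site source codes inside `overall_alpha()`.
* Sample-level FST between source-representative populations after `G`
  forward generations exceeds `expected_fst(tau)`, because the forward
  phase (finite `n_p`) keeps adding drift; the calibration statement
  applies to the founder panel. This mirrors what any user of the original
  design would observe in the generated datasets.
* Writers target the subset of VCF/plink actually produced by the
  simulator (biallelic SNPs, GT-only, single contig); they are not general
  VCF manipulation tools.
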