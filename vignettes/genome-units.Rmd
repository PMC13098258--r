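---
title: "Genome units, nGUN, and association testing in MAG collections: methods"
author: "magun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome units, nGUN, and association testing in MAG collections: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`magun` treats a cohort-scale MAG collection as a two-level partition
defined purely by average nucleotide identity:

* **species clusters** — groups of MAGs above 95% ANI, the conventional
  prokaryotic species boundary;
* **genome units** — groups of same-species MAGs above 99% ANI, a
  pragmatic sub-species stratum coarse enough to pool carriers across
  samples but fine enough to separate diverged lineages.

For a species with $n$ MAGs and $\mathrm{GUN}$ genome units, the
normalized genome unit number

$$\mathrm{nGUN} = 100 \cdot \mathrm{GUN} / n \in [100/n,\ 100]$$

measures within-species diversity per 100 recovered genomes. It drives
candidate selection for within-species association testing: a low nGUN
with many MAGs means few, well-populated units whose presence/absence
across samples can enter a regression with adequate carrier counts.

Both partitions come from average-linkage agglomerative clustering on
the distance $1 - \mathrm{ANI}$, cut at $1 - t$. Average linkage was
chosen (the level at which dereplication tools operate but rarely
document) because it is robust to a single spuriously high pairwise
estimate; single and complete linkage are available through the
`linkage` argument. Genomes are processed in sorted-id order and cluster
labels are assigned by decreasing size then smallest member id, so the
partition is reproducible down to tie-breaks.

# ANI estimation

Pairwise ANI uses bottom-$s$ MinHash sketching over canonical k-mers
(lexicographic minimum of k-mer and reverse complement; k-mers
containing non-ACGT characters are skipped). Hashes are a splitmix64
mix of the 2-bit k-mer encoding, truncated to 53 bits so they survive
storage in doubles. The merged bottom-$s$ Jaccard estimate $j$ maps to
ANI through the Mash distance closed form

$$D = -\tfrac{1}{k}\,\ln\!\frac{2j}{1+j}, \qquad \mathrm{ANI} = 1 - D,$$

clamped to $[0,1]$ with $j = 0 \mapsto 0$. Defaults $k = 21$, $s = 1000$
are the standard sketching regime for discriminating above 95% ANI.

**Accuracy by band.** The estimator's precision degrades as similarity
falls, which matters for interpreting validation bounds. By the delta
method, the ANI standard error is roughly
$\frac{1}{k}\left(\frac{1}{j} - \frac{1}{1+j}\right)\sqrt{j(1-j)/s}$:
about 0.001 at 99% ANI, 0.003 at 98%, but ~0.005 at 90% ANI, where the
first-order Mash inversion also undershoots the Hamming identity by
$\ln(1-d)+d \approx d^2/2 \approx 0.005$. Consequently the test suite
verifies agreement with the exhaustive Hamming oracle to within 0.01
for pairs at ANI ≥ 0.95 — the band where the 95% and 99% clustering
decisions are made — and only to within 0.035 below the species
boundary, where estimates over thousands of pairs include multi-sigma
deviations. Both clustering thresholds sit deep inside the accurate
band, so partition recovery is unaffected; sub-0.01 accuracy at 90% ANI
would require a larger sketch. Exact Hamming (indel-free inputs) and
exact full-set Jaccard oracles are exported for validation.

# Quality, representatives, and merging

MIMAG tiers are applied with strict inequalities exactly as the standard
prints them: high quality requires completeness > 90%, contamination
< 5%, all of 5S/16S/23S rRNA, and ≥ 18 tRNAs; medium quality requires
completeness > 50% and contamination < 10%; boundary values (exactly 90%
complete) fall to the weaker class. "Almost complete" is the
completeness > 90% and contamination < 5% pair alone.

Each species cluster gets a representative by the dereplication-style
score

$$\mathrm{score} = C - 5\,\mathrm{contamination} -
  0.1\,\mathrm{strain\ heterogeneity} + 0.5\log_{10} N_{50},$$

with configurable weights and ties broken to the smallest MAG id.
Merging a cohort collection A into a public reference B re-clusters the
union of representatives at 95% ANI and keeps the higher-scoring
representative per species, labelling each species `novel` (A-only, no
taxonomy label), `known_absent_from_B`, `higher_quality_replacement`
(shared, A wins), or `B_only`.

# Association layers

**Species level.** CLR-transformed relative abundance is regressed on
the disease indicator plus BMI, sex, and age by ordinary least squares —
abundance as response, disease as predictor, taken literally from the
modelling convention of cohort-scale abundance studies. Wald t-tests;
no robust errors. The Bonferroni divisor is the number of species that
entered the models after the prevalence filter (present in ≥ 1% of
samples, inclusive), and is recorded in the output. Zero replacement
before CLR: the composition is closed, every zero is replaced by half
the smallest nonzero relative abundance in the table, and rows are
re-closed — this keeps the transform invariant to per-sample rescaling.
All-zero samples are an error, not a silent drop.

**Within species.** Disease is regressed on genome-unit
presence/absence plus sex, age, and BMI by logistic regression; the
odds ratio $e^{\beta}$ is reported with its Wald p-value. Only units
with at least 100 carriers enter by default (`minCarriers`), the
operational version of "high case numbers". The Bonferroni divisor here
is the number of diseases tested. Degenerate designs — a constant
disease, a unit present in every (or no) analyzed sample — produce
flagged rows with `NA` p-values; fits whose fitted probabilities reach
the 0/1 boundary are flagged `possible_separation` but still reported.

Sex is coded 0 = male, 1 = female throughout; the cohort generator
defaults to 70% female, matching the composition of typical
volunteer-based microbiome cohorts.

# The synthetic cohort generator

The generator is the package's ground-truth instrument, not a fixture:
a random root genome is mutated along a star phylogeny — species
ancestors at rate $d_\mathrm{between\,species}/2$ per branch (default
pairwise 0.10), unit centers at $d_\mathrm{between\,units}/2$ (default
0.015), members at $d_\mathrm{within\,unit}/2$ (default 0.002) — with
substitutions only. The defaults place within-unit pairs near 99.8%
ANI, between-unit pairs near 98.5%, and between-species pairs near 90%,
i.e. clear margins around both thresholds. The star topology keeps every
pairwise distance analytically controllable, and the absence of indels
makes Hamming distance an exact divergence oracle. Validity checks
refuse configurations whose bands would collide with the thresholds
($2 d_\mathrm{within\,unit} < 0.01$,
$d_\mathrm{between\,units} \in (0.01, 0.05)$,
$d_\mathrm{between\,species} > 0.05$).

Quality metadata are drawn from tunable marginals (truncated-normal
completeness on (50, 100], exponential contamination clipped below 15,
log-normal N50, Bernoulli rRNA flags, Poisson tRNA counts). Abundances
are zero-inflated log-normal loads closed to relative abundances, with
presence forced wherever a MAG of the species was recovered. Phenotypes:
age ~ Uniform(23, 89), sex ~ Bernoulli(0.7), BMI ~ Normal(26, 4); each
configured disease is drawn from a logistic model whose intercept is
calibrated by root-finding to the target prevalence, with the planted
unit log odds ratio applied to carriers and a planted species effect
realized as a case-specific multiplicative load shift sized (by the
factor $D/(D-1)$ for $D$ species) so the CLR coordinate shifts by the
configured amount. MAG-recovery probabilities per species are left as
free parameters (each unit's MAGs originate from distinct random
samples) rather than being fitted to any observed recovery profile.

What the generator deliberately does **not** emulate: indels,
rearrangements, horizontal gene transfer, chimeric or composite bins,
read-level noise, and abundance-dependent assembly success. Passing
tests therefore demonstrate correctness of the clustering, metric, and
inference machinery under a clean divergence model — not robustness to
assembly artifacts, which on real data blur the 99% boundary and can
deflate GUN for species whose strains co-occur within samples.

# Defaults worth knowing

| Parameter | Default | Meaning |
|---|---|---|
| `k`, `s` | 21, 1000 | sketch k-mer length and size |
| `speciesThreshold` | 0.95 | species-level ANI cut |
| `unitThreshold` | 0.99 | genome-unit ANI cut |
| `minMags` (GUN report) | 10 | keep species with > 10 MAGs (strict) |
| `minPrevalence` | 0.01 | species present in ≥ 1% of samples |
| `minCases` | 100 | diseases with ≥ 100 cases |
| `minCarriers` | 100 | units with ≥ 100 carrier samples |
| `alpha` | 0.05 | family-wise level before Bonferroni |

The GUN report's MAG floor deserves a note: cohort analyses have used
both "more than 10 MAGs" (broad surveys) and "more than 100 MAGs"
(conservative, units only for deeply sampled species). The default is
10; passing `minMags = 100` reproduces the conservative variant. The
association layer always reports the species count that actually
entered its models and the corresponding corrected alpha, rather than a
fixed constant, because the filtered count depends on the abundance
table at hand.

Percentages in cohort summaries are rounded half-up to two decimals
(`roundHalfUp()`), matching how such tables are conventionally printed;
full-precision values stay in the TSV outputs.

# Problem sizes in the test suite

The suite validates clustering recovery on 20 seeded collections of 5
species × 1–4 units × 10 MAGs at 20 kb genomes (sketch vs exhaustive
Hamming oracle vs planted truth), association calibration on 1,000
simulated null tests per layer, odds-ratio recovery on 200 replicates
of n = 2,000 samples at a planted OR of 0.56, and byte-identical
reproduction of pipeline outputs under a fixed seed. Genome lengths of
20 kb keep exhaustive oracles cheap while leaving ~20,000 distinct
21-mers per genome, comfortably above the sketch size.

# Known limitations

* nGUN is not corrected for genome length, pangenome size,
  recombination, or horizontal transfer, all of which modulate how
  substitution divergence maps to unit boundaries.
* The sketch estimator is for indel-free or lightly diverged genomes;
  alignment-based ANI is out of scope.
* Association models are cross-sectional single-feature regressions; no
  FDR alternatives, mixed models, or mediation.
* The merge step assumes each input collection is already dereplicated
  at the species threshold; overlapping representatives within one
  collection are resolved by score but not reported specially.
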