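---
title: "Detecting congenic footprints and modifier genes in engineered mouse lines"
author: "congenicScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting congenic footprints and modifier genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(congenicScan)
```

## The problem

A gene-targeted mouse line is built by modifying embryonic stem cells of a
donor strain (classically a 129 substrain) and backcrossing the resulting
chimaeras into a recipient inbred background (usually C57BL/6). Selection
for the targeted allele at every generation guarantees that a chunk of
donor chromosome around the target — the *congenic footprint* — survives
the backcrossing, and residual donor segments elsewhere survive by chance.
Every gene inside the footprint is of donor genotype in KO animals and of
recipient genotype in WT littermates, perfectly confounded with the
knockout itself. The package characterizes this structure directly from
variant calls (VCF), without needing pedigree records.

## From call sets to the footprint

The central container is `GenotypeCalls`: one diploid genotype state
(`hom_ref` / `het` / `hom_alt` / `missing`) per site key
`(chrom, pos, ref, alt)`, with Phred site quality and read depth.
Multiallelic records are split one call per ALT; indels are matched by
exact allele strings, so inputs should be normalized (left-aligned)
upstream — the package deliberately performs no realignment of its own.
Missing genotypes are retained on reading but excluded from every set
operation. Chromosome-name dialects ("14" vs "chr14") are reconciled only
through an explicit `renameChromosomes()` call, never silently.

The pipeline stages and their rationale:

* **Hard filters** (`applyHardFilters`): `depth > 10` and `qual > 30`,
  strict inequalities — the conventional hard filter for caller output.
  Filtering is idempotent and partitions the input.
* **Replicate consensus** (`intersectReplicates`): the site keys called in
  *all* replicates of one genotype. Replicate genotype disagreement is
  flagged; under the default `strict` policy the consensus genotype
  degrades to `missing` (excluded downstream), under `majority` the modal
  genotype is kept. Strict is the default because a footprint variant
  should be fixed in the line and any discordance is evidence against it.
* **KO-linked dissection** (`dissectKoLinked`): a KO consensus call is
  KO-linked when its key is absent from the WT set or present with a
  different genotype state; WT `hom_ref` and `missing` count as absent.
  Genotype comparison ignores phase. The KO-linked set plus the
  genotype-matching set partitions the (non-missing) KO consensus exactly
  — a property the test suite checks on randomized inputs.
* **Chromosome scan** (`binVariants` + `flagChromosomes`): per-bin counts
  in 10-Mb windows; bins are right-open with breaks at multiples of the
  bin width applied to the 1-based position (the R `cut(..., right =
  FALSE)` convention: position 10,000,000 opens bin 1). Per chromosome a
  2×k table of KO vs WT bin counts feeds a Cochran–Armitage trend test
  with bin-index scores (bin midpoints are available as an option; the
  statistic is invariant to positive affine score changes, so the choice
  only matters for unequal bin widths, which do not occur here). The
  `significant` flag uses the raw per-chromosome p at `alpha = 0.05`;
  Bonferroni-adjusted p values are reported alongside for rigor.
* **Footprint measurement** (`estimateFootprint`): the min/max envelope of
  homozygous KO-linked positions on a chromosome, converted to
  centimorgans by linear interpolation in a genetic map (TSV of
  chrom/bp/cM anchors; linear extrapolation beyond the anchors; a
  constant-rate fallback, default 0.5 cM/Mb, covers unmapped
  chromosomes). Homozygous-only is the default because the fixed footprint
  is homozygous in KO animals; heterozygous KO-linked calls usually trace
  residual unlinked segments. The envelope is the reproducible
  formalization of reading the extent off a histogram; because isolated
  residual donor segments on the same chromosome can inflate it, a
  gap-tolerant mode (`gapTolerant = TRUE`) keeps the longest run of
  occupied 10-Mb bins with at most one empty internal bin.
* **Backcross estimate** (`estimateBackcrossGenerations`): the expected
  retained segment around a selected locus after `N` backcross
  generations is ≈ `200/N` cM (two one-sided expectations of 100/N each),
  so `N̂ = round(200/extent)`, floored at 1. Rounding to nearest is used
  because both published desk-scale checks (42.14 cM → 5, 11.94 cM → 17)
  are consistent with it; ceiling would reproduce them too, and nearest
  was chosen as the less biased convention.
* **Ploidy and Mendelian validation** (`ploidyProfile`,
  `mendelianAnnotate`): zygosity ("ploidy" in the congenic sense) is
  profiled per littermate *before* any consensus so replicate-to-replicate
  differences stay visible. If footprint inheritance is Mendelian, a
  heterozygous littermate carries the introgressed variants as het calls:
  the het sample is reduced to calls not shared with the WT littermate,
  then to het calls, and the fraction of KO-linked keys found there is the
  variant-level coverage. Gene-level coverage would need consequence
  annotation (VEP) and is out of scope.
* **eQTL screen** (`screenEqtl`, `selectCandidates`): per congenic gene,
  OLS of *pre-normalized* expression on the genotype dose code WT = 1,
  Het = 0.5, KO = 0; p from the two-sided slope t-test on `n − 2` df;
  selection at raw `P < 0.05`, required in both a control and a perturbed
  condition (the double requirement is the multiplicity control;
  Benjamini–Hochberg is available via `adjust = "BH"`). With only WT/KO
  samples the regression degenerates to a two-group comparison — allowed
  but flagged. Normalization itself is upstream by design.

## The synthetic cohort generator

`simulateCongenicCohort()` makes the breeding process that the `200/N`
rule summarizes executable. Per chromosome, meioses are modelled on the
genetic-map scale with crossovers as a Poisson process at 1 per 100 cM
(Haldane model — no crossover interference, the simplest model consistent
with the expectation the estimator inverts). Each backcross generation
draws a gamete from the carrier and selects an offspring carrying the
targeted allele; unlinked donor segments survive by chance (≈ 1/2 per
generation). The final intercross is modelled as fixation of the
N-generation carrier haplotype identical-by-descent: KO samples are
homozygous for it, the het littermate heterozygous, WT recipient-only.
This choice reflects how congenic lines are expanded (the footprint
haplotype becomes fixed in the colony) and keeps the generation count in
the simulation aligned with the generation count the `200/N` rule refers
to; modelling the intercross as two further recombining meioses would
shrink the footprint by roughly two generations' worth. Set
`intercross = FALSE` to emit heterozygous carriers instead.

Default conditions mirror a typical RNA-seq cohort: five chromosomes
(190/180/160/150/125 Mb) at a constant 0.5 cM/Mb, the target on the
125-Mb chromosome at 52.3 Mb, one WT, one het and three KO samples,
1 donor variant per Mb. Shared recipient-background calls (0.1/Mb,
homozygous in every sample) keep the WT histograms realistically non-empty
at roughly a ten-fold footprint-to-background per-bin contrast, and
per-sample "drift" variants (0.02/Mb, private, homozygous) model novel
colony variation. Emitted depth is Poisson (mean 30) and site quality
gamma-distributed around 60 with CV ≈ 0.22, concentrated so that
missingness is governed by the explicit `dropout` parameter rather than by
incidental filter failures. Identical config and seed give byte-identical
VCFs.

What the generator does *not* emulate: realistic mutation spectra,
RNA-seq's restriction of detectable variants to expressed exons, mapping
artefacts, crossover interference, and marker-assisted ("speed congenic")
breeding. Tests passing on simulated cohorts therefore demonstrate the
correctness of the set operations, the statistics and the estimator
plumbing — not robustness to every artefact of real sequencing data.

## Numerical choices and degenerate inputs

* Trend test with an empty row or all mass in one column: `z = 0`,
  `p = 1`, flagged `degenerate` rather than `NaN`.
* A chromosome present in only one genotype is skipped by the scan with a
  warning; it has no 2×k table.
* Zero-width footprints (a single qualifying variant) raise an error from
  `estimateFootprint` rather than implying an infinite backcross number.
* A perfect eQTL fit (zero residual variance, nonzero slope) reports the
  smallest representable positive p with a `perfect_fit` flag.
* Majority-policy genotype ties degrade to `missing` and stay flagged
  discordant.
* Consensus qual/depth are the per-site minima across replicates — the
  weakest supporting evidence, the conservative summary.

## Statistical behaviour worth knowing

The suite quantifies two intrinsic limitations rather than hiding them:

* The asymptotic normal p of the trend test differs from the exact
  fixed-margin permutation distribution on small tables (total counts
  ≤ 40) by up to a few hundredths to tenths — the permutation law is
  discrete, and the gap is approximation error, not Monte-Carlo noise. On
  tables of the size the 10-Mb scan actually produces (hundreds of
  counts) the approximation is excellent.
* The footprint extent after `N` backcrosses is approximately
  Gamma(2, 100/N) — coefficient of variation ≈ 0.71 — so a *point*
  estimate `round(200/extent)` from a single line is median-centred but
  widely dispersed: across simulated cohorts, roughly 70% / 22% / 10% of
  estimates land within ±2 of a true N of 5 / 10 / 17. The estimate
  should be read as an order-of-magnitude statement about a line's
  breeding history, not a generation count with unit precision.
* A bin-index linear trend has limited power for a footprint centred
  mid-chromosome (a symmetric bump contributes little linear component);
  the target chromosome still ranks first far more often than the 20%
  chance level (≈ 65–80% across simulated designs), and real footprints
  are typically an order of magnitude denser in variants than the
  1/Mb simulated here.

## Problem sizes in the test suite

The suite simulates cohorts on the five-chromosome, ~800-Mb genome above
(a few hundred variants per sample), uses 10^5-draw permutation oracles on
2×k count tables, 50 seeded cohorts per backcross depth for recovery
rates, 200 breeding chains for the segment-length expectation, and
10^3-gene count tables for the eQTL error rates — sizes chosen so the
whole suite exercises every stage in about two minutes on one core.
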