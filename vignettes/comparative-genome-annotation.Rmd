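---
title: "Comparative genome-annotation analyses for entomophthoralean fungi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative genome-annotation analyses for entomophthoralean fungi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(entomocomp)
```

## Scope and motivation

Entomophthoralean insect pathogens such as *Entomophthora muscae* carry
giant (0.5–1 Gb) genomes dominated by Ty3 LTR retrotransposons. Comparative
questions about such genomes are usually answered with a recurring battery of
post-annotation analyses: does the genome show repeat-induced point mutation
(RIP)? Which protein-domain families are expanded or contracted relative to
allied species? Which proteins carry the curated domain architectures of
circadian, light-sensing, RNAi or RIP-machinery candidates? How are
orthogroups shared across species, and which genes are potentially
species-specific? How old are the repeat expansions?

`entomocomp` packages those analyses as tested, reusable functions, plus
seeded synthetic-data generators with planted ground truth so that each stage
can be validated end to end without downloading any assembly. The numbered
scripts under `analysis/` run the whole workflow on synthetic data and write
their tables under `results/`.

## RIP detection

RIP converts C to T preferentially at CpA dinucleotides within duplicated
sequence. On both strands this depletes CpA and TpG (the substrate of the
mutation) and inflates TpA (its product). We quantify this per window with
the composite RIP index

* product index = TpA / ApT,
* substrate index = (CpA + TpG) / (ApC + GpT),
* composite index = product − substrate,

computed over 1 kb windows placed every 500 bp (both tunable via
`scan_windows(window_bp =, step_bp =)`). A window is scored RIPped when its
composite index is strictly greater than 0, and the genome-level summary is
the percentage of windows RIPped.

Numerical choices:

* **Coordinates** are 0-based and half-open throughout (BED convention), so
  window arithmetic is unambiguous.
* **Trailing partial windows are skipped.** Index variance explodes in short
  windows; contigs shorter than the window contribute nothing.
* **Undefined indices.** Any index with a zero denominator (e.g. in N-rich
  gaps) is undefined, and a window with an undefined composite index is never
  RIPped. By default such windows stay in the denominator of the percentage
  (`genome_rip_summary(denominator = "all")`), which is conservative — it can
  only understate RIP; `denominator = "defined"` excludes them.
* **Single-strand scanning.** TpA and ApT are self-complementary dinucleotide
  classes and CpA/TpG, ApC/GpT are complementary pairs, so all three indices
  are identical on the reverse complement; the test suite asserts this
  numerically on 1000 random windows.
* Dinucleotides containing N are skipped, so counts always sum to the number
  of N-free overlapping positions.

## The synthetic background genome is Markov, not i.i.d.

`simulate_genome()` draws contigs from a first-order Markov base model whose
stationary base composition matches the requested GC exactly and whose
dinucleotide odds are multiplied by `dinuc_bias` (defaults: TpA ×0.75,
CpA ×1.15, TpG ×1.15). This was a deliberate design decision, not a
convenience. Under any independent-bases model with pA = pT and pC = pG, the
joint distribution of dinucleotide counts is invariant under swapping
A with T and C with G, and that swap maps the composite index to
(substrate − product)/(product · substrate): exactly half of background
windows score composite > 0, and the "RIPped" call would be a coin flip on
unmutated sequence. The composite index works on real genomes because
unmutated DNA universally suppresses TpA (product index well below 1) and
mildly favours CpA/TpG (substrate index above 1). The default multipliers put
the background in that regime (background composite ≈ −0.35 at GC 0.5) while
remaining within the range observed in fungal genomes; both multipliers are
strand-symmetric (TpA is its own reverse complement; CpA and TpG are each
other's), so the model respects the strand invariance of the indices.
`dinuc_bias = NULL` restores a literal i.i.d. generator for experiments that
need one.

What the generator deliberately does **not** emulate: real repeat structure
(planted windows are mutated background, not TE copies), GC heterogeneity
and isochores, coding constraint, and assembly artefacts such as N gaps.
Passing the planted-recovery tests therefore shows the scan recovers the
dinucleotide signature at the stated rates, not that any particular genome
fraction of a real assembly is RIPped.

`plant_rip()` mutates each CpA's C to T and each TpG's G to A with the given
probability, identifying sites on the pre-mutation sequence; planting on one
strand only would understate the recoverable signal because the index is
strand-symmetric. At mutation rate 0.3, the test suite requires ≥ 95 % of
fully-planted 1 kb windows to be flagged and ≤ 5 % of background windows; at
the defaults the realized values are about 99 % and 4 %.

## Domain enrichment

`build_count_matrix()` counts, per species and domain, the number of distinct
proteins containing the domain (a protein with three copies counts once),
against explicitly supplied proteome totals — genes with no annotated domain
still belong in the denominators, so totals are never inferred from the
table. For every domain present in at least two genomes,
`pairwise_enrichment()` runs a two-sided Fisher exact test for each species
pair on domain-bearing versus other proteins, Bonferroni-corrects within the
domain (the family is the number of pairs, mirroring pairwise-Fisher
semantics; `global_bonferroni = TRUE` multiplies by pairs × domains instead),
and reports per species the number of significant pairs at `alpha` (default
0.01), the direction relative to the across-species median (zeros included),
and the fold: count/median above the median, median/count below it (`Inf`
for a zero count), fold 1 at the median. The two-sided p sums hypergeometric
probabilities no larger than the observed table's (the classical rule, with
the same 1 + 1e-7 relative tolerance as `stats::fisher.test`, which the test
suite uses as an independent cross-check next to an exhaustive enumeration
oracle over all tables with n ≤ 40). The reported odds ratio is the sample
odds ratio ad/bc, not the conditional MLE.

`presence_sets()` assigns each domain to its exact species subset (the cells
of an UpSet plot); the counts partition the domains. `chisq_2x2()` is the
Pearson chi-squared without continuity correction, used for comparing the
secreted fraction of under- versus overrepresented domain families.

## Architecture rules

`architecture_rule()` expresses a curated candidate as constraints on a
protein's domain-count multiset: required counts (exact or minimum),
forbidden domains, and alternative sets. The shipped rule sets
(`builtin_rulesets()`, a versioned YAML under `inst/extdata/`) cover the
circadian survey (FRQ; WC1 = exactly one each of GATA, PAS_3, PAS_9; WC2 =
GATA and PAS_3 with no PAS_9; rhodopsin = exactly one 7tm_1), the RNAi survey
(RDRP, Dicer, Ago = PAZ and Piwi, Dicer_Alt = Ribonuclease_3 plus DEAD or
PAZ), RID-like methyltransferases (≥ 2 DNA_methylase domains), and
single-domain light-sensing surveys. Choices on points the rule descriptions
leave open:

* "One each" is read as an exact count of 1 for WC1/WC2/rhodopsin, matching
  the "expected combination (and frequency)" curation;
  `builtin_rulesets(min_counts = TRUE)` relaxes exact to minimum for
  sensitivity analyses.
* A protein may satisfy several rules and is counted for each (e.g. Dicer and
  Dicer_Alt are reported independently); Dicer requires only Dicer_dimer.
* The RID rule counts DNA_methylase occurrences; true tandem adjacency would
  need domain coordinates the input table does not carry. This is a known
  limitation.
* PAS (PF00989) and GAF appear in the survey vocabulary but in no curated
  rule; they remain survey-only.

## Orthogroup statistics

`read_orthogroups()` consumes the OrthoFinder `Orthogroups.tsv` dialect plus
the unassigned-genes companion; collapsing isoforms to one peptide per gene
is the caller's responsibility (as it is upstream of clustering), and the
reader warns when gene ids look like transcript isoforms. Occupancy patterns
partition orthogroups; gene accounting partitions each species' gene universe
into assigned/unassigned, with "potentially species-specific" the sum of
unassigned genes and genes in single-species orthogroups. The pooled
expression filter removes genes with a pooled count strictly below 5
(a pooled sum over samples — the natural reading of counts "across this
pooled set"); genes absent from the quantification output count as zero.

`set_enrichment()` tests a gene subset against its background per domain with
the same exact test, including the pseudo-domain `no_Pfam` for genes lacking
any annotation — unannotated genes are an informative category in these
genomes, not missing data. By default significance is the raw p ≤ 0.001
threshold used for such orthogroup-set scans; `fdr = TRUE` switches to
Benjamini–Hochberg. The suite requires ≤ 0.3 % flags on 1000 null domains.

## Repeat landscapes

`kimura2p()` is the closed-form two-parameter distance
−½·ln((1 − 2P − Q)·√(1 − 2Q)); out-of-domain inputs are a saturation error,
and only the plain form is implemented (no CpG adjustment). Divergence bins
are left-closed, right-open, width 1 from 0 — the convention of
RepeatMasker's landscape script — and landscape percentages are of genome bp,
matching that script's y-axis. Classes below 1 % of total repeat bp merge
into "Other" with exact bp conservation; the composition display filter hides
classes that never exceed 0.1 % of the genome in any species. Per-element
divergence tables are consumed as inputs; re-aligning repeats is out of
scope.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on synthetic data:
a 600 kb assembly (1199 windows, 120 of them planted), 4 proteomes of 10,000
with 200 simulated domains at baseline Poisson mean 50, orthogroup tables of
1711 groups mirroring the study's occupancy proportions at one-tenth scale,
and 1000-domain null simulations — sizes chosen so the full battery of
statistical checks completes in minutes on a laptop while keeping binomial
noise well inside the asserted bounds. Every generator is a pure function of
its parameters and one global seed (fanned out per component, so adding a
generator never shifts existing streams), and callers' RNG state is left
untouched.

Two published-scale checks cannot run offline and fail honestly rather than
silently: the compiled 6144-genome size/gene-count summary (the per-genome
table is not redistributable with the package; supply it as
`inst/extdata/fungal_genome_dataset.tsv`) and the full-assembly RIP
percentages for *N. crassa*, *Z. radicans* and *E. muscae* (place the
assemblies under `tests/testthat/external/`).

## Known limitations

* Rule-based RID candidates use domain multiplicity, not tandem adjacency.
* The landscape module consumes RepeatMasker-derived divergence tables; it
  does not parse raw `.out`/`.align` files.
* The synthetic genome model is first-order; real genomes have longer-range
  structure, so planted-recovery rates are an upper bound on what identical
  parameters would achieve on real assemblies.
* Fisher denominators are whole annotated proteomes; with very small
  proteome totals the ≥ 2-genome presence filter is the only guard against
  degenerate tables.
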