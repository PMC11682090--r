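---
title: "Candidate variant screening under stratified modes of inheritance"
author: "moiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate variant screening under stratified modes of inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moiscan)
```

## The screening problem

`moiscan` addresses a recurring design in veterinary and rare-disease
genetics: a handful of affected individuals (cases) with whole-genome
sequencing, no parental samples, and large reference cohorts of unaffected
genomes. Bovine spastic syndrome — an adult-onset progressive neuromuscular
disorder of cattle — is the motivating example: a few affected Holstein
animals are screened against a primary ("tier-1") resequencing cohort and a
much larger global ("tier-2") cohort. Because neither the mode of
inheritance (MOI) nor genetic homogeneity can be assumed, the screen is
stratified into three genetic models, each applied as a filtering funnel
per case:

* **Recessive, shared** — one variant homozygous for the alternate allele
  in *every* case. This is the classical single-founder hypothesis.
* **Recessive, individual** — homozygous-alternate in one case, with each
  case treated as an isolated event (genetic heterogeneity allowed).
* **Dominant, individual** — the case carries the alternate allele (het or
  hom) and the allele is absent from all controls.

Each funnel has four stages, mirroring the way such screens are reported:

1. `ALL` — quality-passing variants satisfying the model's case-zygosity
   condition;
2. `PRIVATE_TIER1` — carrier thresholds applied against tier-1 controls;
3. `PROTEIN_CHANGING` — at least one annotation entry with a
   protein-changing consequence term;
4. `POST_TIER2` — carrier thresholds re-applied against the tier-2 cohort.

Stage sets are nested by construction, so counts are non-increasing along
the funnel; this invariant is asserted on every run in the test suite.

## What "private" means, and why heterozygous carriers are allowed

Under the dominant model, "private" is strict: the total alternate-allele
count over controls must not exceed
`dominant_max_control_alt_alleles_*` (default 0 — absent in all
controls). Under the recessive models, the default bounds only
homozygous-alternate controls (`recessive_max_control_homalt_*`, default
0) and leaves heterozygous carriers unbounded. The reason is biological: a
fully penetrant recessive allele is expected to segregate in the
heterozygous state in the source population, so demanding total allele
absence would discard exactly the candidates the recessive model predicts
— a recessive candidate that survives filtering *while* low-frequency
heterozygous carriers exist in control populations is the signature the
screen looks for. Both bounds are configurable per tier in
`filterConfig()` because published screens rarely state their carrier
caps.

`MISSING` genotypes are treated conservatively on both sides: a missing
case genotype excludes the variant for that case's filters (the evidence
for the required zygosity is absent), and missing control genotypes never
count as carriers. Low-coverage genomes therefore lose candidates rather
than gain spurious ones.

The default protein-changing term set is: missense, stop gained/lost,
start lost, frameshift, conservative/disruptive inframe
insertion/deletion, splice acceptor/donor, and generic protein-altering.
It deliberately includes inframe indels — small in-frame deletions are
legitimate protein-changing candidates — and excludes synonymous and
intronic classes. It is configurable because no single canonical set
exists.

## Normalization of variant input

The screen operates on a `VariantTable`: one record per (site, alternate
allele). Multiallelic sites are split; for the record of alternate allele
*j* a genotype is HOM_ALT only if both alleles are *j*, HET only if the
other allele is reference, HOM_REF if both are reference, and MISSING
otherwise — including genotypes that carry a *different* alternate allele,
whose zygosity with respect to *j* is simply not interpretable as any of
the three classes. This mapping conserves alternate-allele dosage across
split records (a property test), phased and unphased separators are
equivalent (only zygosity matters downstream), and half-missing genotypes
(`./1`) become MISSING because zygosity is undeterminable.

The VCF `FILTER` column maps to a quality label (`PASS`, `.` →
`UNLABELED`, anything else → `FAIL`); filters consider only `PASS`
variants by default, with `UNLABELED` admissible via configuration.
Functional annotations are consumed, never computed: the standard
pipe-delimited ANN INFO sub-field is parsed into per-transcript entries
with ampersand-joined consequence terms split apart. HGVS strings are
preserved verbatim and never validated — published annotation sets
occasionally carry internally inconsistent genomic/cDNA notations, and a
screening tool must not silently "correct" them. Chromosome dialects
("16" vs "Chr16") are normalized by stripping the case-insensitive `chr`
prefix.

## Runs of homozygosity and F_ROH

ROH detection uses the consecutive-runs method: scanning each sample's
ordered marker track for maximal stretches of homozygous calls, tolerating
up to `max_opposite` heterozygous calls (default 1) and `max_missing`
missing calls (default 1) per run, with inter-marker gaps capped at
`max_gap` (default 1 Mb). Runs are trimmed to their first and last
homozygous markers and then filtered to `min_snp` homozygous markers
(default 20) and `min_length` bp (default 50 kb). These defaults sit near
the documented defaults of the consecutive-runs implementations commonly
used in livestock genetics; the sliding-window variant is deliberately not
implemented — one algorithm with an exact brute-force oracle is worth more
than two half-checked ones.

Scanning is left-greedy and emits pairwise-disjoint segments: a run starts
at the earliest eligible homozygous marker and extends as far right as the
tolerances allow, and the scan resumes after the violating marker. Two
consequences are worth knowing. First, valid windows can in principle
overlap (two stretches sharing their het budget); disjoint greedy
scanning resolves the ambiguity deterministically in favour of the
leftmost start. Second, every emitted segment is right-maximal, but a
segment may occasionally admit a valid left extension across territory
consumed by an earlier candidate window that the length filters
discarded; this is inherent to disjoint scanning and the property tests
assert exactly the guarantee that holds.

Intervals are held as 1-based closed `GRanges` — the native convention of
the Bioconductor interval stack used for the intersection arithmetic —
and converted to BED's 0-based half-open convention in a single function
(`grangesToBed()`) at export time, so no other call site performs
coordinate arithmetic.

Shared homozygous regions are the interval intersection of all cases' ROH
unions, filtered to `min_shared_length` (default 10 kb, "kb-sized"
regions). The genomic inbreeding coefficient is
F_ROH = Σ autosomal ROH length / Σ autosome length, with the denominator
taken from a user-supplied chromosome table for determinism and
cross-cohort comparability; "SNP-covered length" denominators are not
offered. A convenience table of the 29 cattle autosomes with lengths
rounded at the 0.1-Mb scale ships with the package
(`cattleAutosomesPath()`), clearly labelled approximate; real-data
analyses should supply their assembly's exact lengths.

## Population frequency tables

For a target variant, `genotypeCounts()` / `popFreqTable()` tabulate
HOM_ALT / HET / HOM_REF / MISSING per population and the allele frequency
(2·hom + het) / (2·genotyped). Missing genotypes are excluded from the
denominator rather than imputed — array and WGS sub-cohorts have very
different missingness. Percentages are rendered at two significant
figures, the convention that reproduces every verifiable published row
exactly; the unrounded fraction is always emitted alongside. A population
with no genotyped samples yields a flagged undefined frequency, never a
division by zero.

## Candidate classification

Published candidate interpretation in this setting is a narrative
application of the ACMG sequence-variant guidelines. The full 28-criterion
system is underdetermined by the available evidence, so the package
freezes the narrative into an explicit three-rule cascade ("ACMG-lite"):

* **R1** — no deleteriousness consensus (no tool calls the variant
  deleterious) or the gene is not a disorder candidate →
  `NOT_A_CANDIDATE`;
* **R2** — homozygous-alternate under a recessive model, deleterious
  consensus, candidate gene → `LIKELY_PATHOGENIC`;
* **R3** — heterozygous under the dominant model, deleterious consensus,
  candidate gene, and no segregation data → `UNCERTAIN_SIGNIFICANCE`
  (the heterozygous state without family data cannot support more).

The deleteriousness consensus is "at least one tool predicts
deleterious". The gene-candidacy flag is user-supplied with a free-text
evidence note (gene function, associated mammalian disorder, expression)
rather than computed from databases, to avoid dependence on database
versions. Residue conservation across an aligned protein panel
(`conservationFraction()`: the fraction of non-gap sequences matching the
reference residue) annotates the rationale when ≥ 0.9 (configurable) but
never changes the class — conservation is descriptive supporting
evidence, not a classification criterion here. The cascade is
deterministic, exhaustive, and monotone in predictions (adding a
deleterious call never downgrades), all property-tested.

## The simulator: what it emulates and what it does not

`simulateCohort()` generates a cohort VCF with three site kinds: a regular
marker grid (default 100 markers/Mb) carrying the homozygosity signal,
background polymorphism under Hardy–Weinberg genotype probabilities with
per-variant allele frequency uniform on [0.01, 0.5] (the minimal neutral
choice; no population-genetic structure is claimed), and planted
candidate variants stamped exactly as configured. Inside a sample's
planted homozygosity block every marker and background genotype of that
sample is forced homozygous, as in a true autozygous segment; carriers of
planted alleles are assigned deterministically to the first samples of
the designated populations. Output is byte-identical for a given seed,
and different seeds change only the background, never the plantings — the
truth table is therefore exact by construction.

The generator deliberately omits linkage disequilibrium, realistic site
frequency spectra, sequencing error, and genotyping noise. Passing tests
on simulated cohorts therefore demonstrate the correctness of the
*filtering logic and interval arithmetic*, not robustness to the error
modes of real pipelines.

`paperLikePreset()` bundles the study-shaped configuration used
throughout the tests: 7 cases, 120 tier-1 controls, 430 tier-2 genomes in
four populations; one recessive-individual planting for case 7 with
heterozygous tier-2 carriers in three populations (71, 6, 4); seven
dominant plantings across cases 1–6 with one digenic case (two plantings
in distinct genes); five homozygosity blocks shared by all seven cases
totalling 2.2 Mb plus two private blocks per case (planted autozygous
fraction ≈ 0.107 per case); two 50-Mb pseudo-autosomes. Control-cohort
sizes are deliberately desk-scale — cohort membership is always
manifest-driven input, never hard-coded, and published screens of this
kind report mutually inconsistent cohort sizes anyway. With these sizes
the expected number of *chance* background survivors of the designated
case's recessive funnel is ≈ 0.005 per run, so the preset's structural
results (0 shared-recessive candidates; exactly 1 recessive candidate for
the designated case; six dominant cases, one digenic; exactly five shared
regions of ≈ 2.2 Mb) are stable by construction across seeds.

Real-data quantities reported in the motivating study — per-case variant
totals in the millions, a cohort mean F_ROH of 0.15, the exact shared-ROH
coordinates — require the deposited sequencing data and unstated
detection parameters, and are consequently not reproduced here; the test
suite substitutes property-based checks (oracle equivalence of every
filter and of ROH detection, exact planted-variant recovery, funnel
monotonicity, F_ROH bounds and exactness on fully marker-covered blocks).

## Worked example

```{r example, eval = FALSE}
library(moiscan)

sim <- simulateCohort(paperLikePreset(), seed = 1, out_dir = "sim")
manifest <- readCohortManifest(sim$paths[["manifest"]])
genome <- readChromTable(sim$paths[["genome"]])
x <- readAnnotatedVcf(sim$paths[["vcf"]], manifest, names(genome))

# the designated case's recessive funnel
funnel <- candidateFunnel(x, manifest, "RECESSIVE_INDIVIDUAL", "case7")
vapply(funnel, nCandidates, integer(1))

# homozygosity mapping across all cases
cases <- caseIds(manifest)
roh <- lapply(setNames(cases, cases), function(cs)
  detectRohConsecutive(genotypeTrack(x, cs), rohParams(), sample_id = cs))
sharedHomozygousRegions(roh)
genomicInbreeding(roh, genome, group = cases)
```

## Numerical and degenerate-input choices

* Ordering and tie-breaking are deterministic everywhere:
  (chromosome per the supplied table order, position, ref, alt).
* An empty variant table filters to empty candidate sets and all-zero
  funnels; it is never an error.
* An unknown case id, a variant key absent from the table, a manifest
  sample missing from the VCF header, a ROH chromosome absent from the
  length table, and unsorted marker tracks are hard errors; malformed
  genotypes degrade to MISSING with a summary warning.
* Symbolic alternate alleles (`<DEL>` etc.) are outside scope and dropped
  with a warning; structural-variant screening is a non-goal.

## Known limitations

* The consecutive-runs method is the only ROH algorithm offered; no
  sliding-window variant, no association statistics on ROH.
* No statistical association testing, imputation, or haplotype analysis.
* The classifier implements the three-rule cascade only; it does not
  attempt full ACMG evidence combination.
* Deleteriousness predictions, gene candidacy and protein alignments are
  consumed as inputs; the package computes none of them.
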