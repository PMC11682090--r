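# moiscan

Candidate causal variant discovery for rare Mendelian disorders in
livestock cohorts: mode-of-inheritance (MOI) stratified private-variant
filtering of case genomes against tiered control cohorts, runs-of-
homozygosity (ROH) mapping with genomic inbreeding, per-population allele
frequency tables, and evidence-based candidate classification. The design
target is the typical veterinary rare-disease setting — a handful of
sequenced cases (for example cattle with spastic syndrome, an adult-onset
neuromuscular disorder), no parental samples, and large reference cohorts
of unaffected genomes.

## The screen

Each case/control cohort is screened under three genetic models, each a
four-stage filtering funnel
(`ALL → PRIVATE_TIER1 → PROTEIN_CHANGING → POST_TIER2`):

| Model | Case condition | Control condition (defaults) |
|---|---|---|
| Recessive, shared | every case `HOM_ALT` | controls `HOM_ALT` ≤ 0; het carriers unbounded |
| Recessive, individual | this case `HOM_ALT` | controls `HOM_ALT` ≤ 0; het carriers unbounded |
| Dominant, individual | this case carries the alt allele | total control alt-allele count ≤ 0 |

Heterozygous control carriers are allowed under the recessive models by
default because a recessive allele is expected to segregate in carriers —
the thresholds are configurable per tier via `filterConfig()`. The
protein-changing stage keeps variants with at least one annotation entry
(standard VCF `ANN` sub-field) whose consequence terms intersect a
configurable set (missense, stop/start changes, frameshift, inframe
indels, splice sites, protein-altering).

ROH are detected with the consecutive-runs method (tolerating by default
1 heterozygous and 1 missing call per run, gaps ≤ 1 Mb, runs ≥ 20
homozygous markers and ≥ 50 kb), intersected across cases into shared
homozygous regions, and summarized as the genomic inbreeding coefficient

```
F_ROH = Σ autosomal ROH length / Σ autosome length
```

Population tables report per-population genotype counts
(Var/Var, Ref/Var, Ref/Ref) and the allele frequency
`(2·n_VarVar + n_RefVar) / (2·n_genotyped)`, rendered at two significant
figures. Classification applies a deterministic three-rule cascade:
homozygous recessive + deleterious consensus + candidate gene →
*likely pathogenic*; heterozygous dominant + deleterious consensus +
candidate gene without segregation data → *uncertain significance*;
otherwise *not a candidate*.

A seeded simulator (`simulateCohort()`, preset `paperLikePreset()`)
generates annotated multi-sample VCF cohorts with planted MOI-consistent
variants, carrier structure, Hardy–Weinberg background polymorphism and
per-sample autozygosity blocks, together with a machine-readable truth
table — so the whole pipeline is testable without any external data.

## Worked example

```r
library(moiscan)

sim <- simulateCohort(paperLikePreset(), seed = 1, out_dir = "sim")
manifest <- readCohortManifest(sim$paths[["manifest"]])
genome   <- readChromTable(sim$paths[["genome"]])
x <- readAnnotatedVcf(sim$paths[["vcf"]], manifest, names(genome))

funnel <- candidateFunnel(x, manifest, "RECESSIVE_INDIVIDUAL", "case7")
funnelTable(buildFunnelReport(list(funnel)))
#>   case_id                  moi n_all n_private_tier1 n_protein_changing
#> 1   case7 RECESSIVE_INDIVIDUAL  1083               9                  1
#>   n_post_tier2 genes
#> 1            1 TOR3A
```

Of the 1083 quality-passing variants homozygous in case 7, nine are
private with respect to the tier-1 controls, one of those is
protein-changing, and it survives the tier-2 global cohort — the planted
recessive candidate, recovered despite its planted heterozygous carriers
in three tier-2 populations. Homozygosity mapping on the same cohort:

```r
cases <- caseIds(manifest)
roh <- lapply(setNames(cases, cases), function(cs)
  detectRohConsecutive(genotypeTrack(x, cs), rohParams(), sample_id = cs))
sharedHomozygousRegions(roh)$total_bp   # 2160005 over 5 shared regions
genomicInbreeding(roh, genome, group = cases)$mean  # 0.1127
```

and the allele-frequency arithmetic of a published-style occurrence row:

```r
alleleFrequency(data.frame(n_var_var = 0, n_ref_var = 71, n_ref_ref = 5785))
#> $fraction 0.006062158   $percent "0.61%"
```

A thin command-line interface over the same functions is installed at
`exec/moiscan` (`simulate`, `filter`, `roh`, `popfreq`, `classify`,
`run`, `config`).

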