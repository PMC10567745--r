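---
title: "Splice-disrupting variants in inherited heart disease: prioritisation, burden and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splice-disrupting variants in inherited heart disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceburden)
```

## Scope and model

`spliceburden` implements a computational workflow for putative
splice-disrupting variants in genes definitively associated with inherited
heart disease (hypertrophic, dilated and arrhythmogenic cardiomyopathy, long
QT and Brugada syndromes, CPVT, and sudden unexplained death screened
against the union panel). The pipeline has four analytical stages —
splice-region anatomy, candidate prioritisation, case-versus-population
burden testing, and ACMG/AMP classification — plus a seeded synthetic cohort
generator that provides study-shaped inputs so every stage runs and is
testable without clinical data.

Scores from the in silico splice predictors (MaxEntScan, dbscSNV ADA/RF,
SpliceAI) are consumed as input columns; the package never computes them.
Branchpoint, enhancer/silencer and UTR effects are out of scope, as is any
sequence-level validation of HGVS strings against a reference genome.

## Splice-region anatomy

Variants are located from their HGVS c. notation alone. The intronic offset
in `c.N+k` / `c.N-k` places a variant relative to the nearest exon/intron
junction:

* **donor site**: intronic +1..+6, plus the last three exonic nucleotides;
  the near-invariant GT occupies +1/+2;
* **acceptor site**: intronic −20..−1 (the polypyrimidine tract), plus the
  first three exonic nucleotides; the near-invariant AG occupies −2/−1;
* **deep intronic**: any intronic position outside both windows;
* **exonic (other)**: exonic positions away from exon edges.

Exonic variants can only be windowed when the distance to the nearest exon
boundary is known, so the variant table carries an optional
`exon_boundary_distance` column (signed: negative counts from the exon end).
Variants at the very first/last exonic nucleotide additionally get an
`exon_edge` flag; because published tallies sometimes report these
separately from the intronic donor/acceptor counts, the summary reports both
the combined and the flagged tallies. Ranged deletions are summarised at
their most splice-proximal affected nucleotide. AT/AC minor-spliceosome
introns are carried as an annotation flag only; no scoring rule consumes it,
since the prediction tools are trained on major-spliceosome sites.

Mechanism is inferred structurally: variants inside a donor/acceptor window
weaken an existing site (`site_loss`); deep intronic and exonic variants are
`site_gain` when a qualifying created-site signal exists (MaxEntScan above
the gain threshold with a greater-than-threshold increase over wild type, or
SpliceAI above its threshold), else `ambiguous`.

Frame arithmetic converts an observed splicing outcome into its coding
consequence: an affected length that is not a multiple of three is a
frameshift with a premature termination codon (PTC); a multiple of three is
an in-frame change of length/3 amino acids. Intron retention is treated as
PTC even when in frame unless the caller asserts the retained sequence is
stop-free — a retained intron essentially always contains an in-frame stop.

## Prioritisation thresholds

A variant observation is a candidate when every gate passes and at least one
tool flags it:

| Gate | Rule | Default |
|---|---|---|
| Phenotype | gene definitively associated with the carrier's disease (SUD: any panel gene) | ClinGen-style panels |
| Rarity | overall AF and each of five sub-population AFs below threshold; control allele count at most `max_ac` | AF < 1e-4, AC ≤ 15 |
| Region | burden mode: exonic or within 75 bp of an exon (exome target regions); discovery mode: all | 75 bp |
| Exclusion | not on the exclusion list | one known population-specific acceptor variant |
| Tools | MES site-loss drop > 4; site-gain score > 4 with increase > 4 (absent reference site counts 0); ADA > 0.6; RF > 0.6; SpliceAI > 0.5 | strict inequalities |

All threshold comparisons are strict, so boundary scores fail; a missing
score never flags. The rarity rule applies both the frequency and the
allele-count cut whenever both columns are present — they are near-equivalent
descriptions of the same cut in a ~125k-sample control set, and applying both
is the conservative reading. ADA and RF only evaluate canonical-splice-site
variants and are missing elsewhere, which is why the tool-concordance tally
is split: canonical-site variants over 1–4 concordant tools, non-canonical
variants over the MES-only / both / SpliceAI-only patterns.

## Burden testing

For each disease, every definitively associated gene is tested for an excess
of qualifying rare splice variants in cases over a gnomAD-like control
table. Qualifying case carriers are distinct participants (a participant
with two qualifying variants in a gene counts once) passing the burden-mode
gates; by default the same in silico thresholds are applied on the case side
as are assumed for the control counts, keeping the two arms symmetric — a
switch (`require_candidate = FALSE`) supports control tables built from
rarity and region alone. Each control allele is taken as a distinct carrier,
defensible at allele frequencies below 1e-4.

The control denominator is the *mean number of individuals sequenced for
that gene*, which adjusts for variable exome coverage; it is rounded to an
integer (with the rounded qualifying count) only for the exact test, while
frequencies and the case excess (`case_freq − control_freq`) use the
unrounded values. Significance uses the exact upper-tail hypergeometric
probability (one-sided Fisher, enrichment in cases), Bonferroni-corrected
per disease over that disease's panel size `m`, recorded in the output.

Post hoc power uses Cohen's arcsine effect size
`h = 2·asin(√p1) − 2·asin(√p2)` and the unequal-`n` one-sided normal
approximation `Φ(|h|·√(n1·n2/(n1+n2)) − z₁₋α)`. At `p1 = p2` this evaluates
to `α`, the test's size. The test suite checks the closed form against a
Monte-Carlo of the arcsine z-test at 10⁵ replicates in parameter regimes
where expected counts are moderate (tens of carriers or more); at very small
case counts the discreteness of the binomial makes any normal-approximation
power formula optimistic, which is a property of the formula, not of its
implementation.

## ACMG/AMP evidence engine

Evidence codes are assigned at the customised strengths used in this
application area:

* **PVS1 ladder** (loss-of-function consequence): very strong when LoF is an
  established disease mechanism or the ClinGen haploinsufficiency score is
  3; strong for score 2 and for titin; moderate for score 1; supporting for
  uncurated genes with gnomAD LoF o/e < 0.35 (strict). PVS1 is assigned from
  the *predicted* consequence (essential-dinucleotide site loss presumed
  LoF); observed RNA outcomes enter separately as PS3/PM4.
* **PS4**: ≥15 unrelated concordant-phenotype probands strong, ≥6 moderate,
  ≥2 supporting. The proband count is an input column, not mined.
* **PP1**: ≥7 informative meioses strong, ≥5 moderate, ≥3 supporting.
* **PS3 / PM4**: an RNA-confirmed out-of-frame outcome earns PS3; an
  in-frame insertion/deletion earns PM4.
* **PM2**: rarity filter passed and the variant essentially absent from
  controls (allele count ≤ 1 by default — the operational reading of
  "zero/near-zero", configurable).
* **PP3**: at least one concordant in silico tool, withheld whenever RNA
  evidence exists — observation supersedes prediction, so PP3 and PS3/PM4
  are mutually exclusive on a variant.

The combiner is point-based: supporting 1, moderate 2, strong 4, very
strong 8; VUS ≤ 5 points, likely pathogenic 6–9, pathogenic ≥ 10.
Benign-side criteria are not modelled. The classical categorical
rule-combination table is available behind `combiner = "categorical"`. The
point system was chosen because it reproduces eleven of the twelve
published functional-study classifications this package is tested against;
the single discrepancy (a pre-RNA code set of PS4_moderate + PM2 + PP1 +
PP3 printed as VUS, which sums to 6 points = likely pathogenic under either
combiner) is deliberately left in place and asserted as a discrepancy in
the test suite rather than patched around. RNA reclassification drops PP3,
adds the functional code, recombines, and labels the transition; the
pre-RNA class can be supplied externally (e.g. from a clinical report) when
it differs from the combiner's own result.

## The synthetic cohort generator

The generator emulates the study conditions: 1242 participants split 720
HCM, 203 SUD, 143 DCM, 66 BrS, 55 LQTS, 34 ACM, 21 CPVT; independent
binomial carrier draws per (disease, gene); and a gnomAD-style control
table with per-gene qualifying counts drawn at a control carrier rate of
1e-4 over a denominator of 1e5 sequenced individuals. Default carrier rates
concentrate the signal in the genes with known excess (MYBPC3 8.2% and MYH7
1.3% in HCM, TTN 2.8% and FLNC 2.7% in DCM, PKP2 5.9% in ACM, KCNQ1 3.6% in
LQTS, SCN5A 1.5% in BrS) with small background rates elsewhere chosen so
each group's overall carrier fraction sits near 10%.

Variant placement follows the observed location taxonomy (24:24:25:15 over
donor/acceptor/deep-intronic/exonic), with donor offsets clustered at the
essential GT and +5, acceptor offsets at the essential AG, and a
configurable share of exon-edge positions. Scores are generated by
*inverting* the thresholds for a planted tool subset drawn from the
observed concordance profiles (canonical 25:11:8:1 over 4/3/2/1 tools;
non-canonical 30:8:2 over MES-only/both/SpliceAI-only), with safety margins
of 0.05 probability units (0.5 MaxEntScan units) on both sides of every
threshold so that no test can be boundary-flaky. Carriers get distinct
variants unless a founder-recurrence probability is set. All randomness
flows from the single seed in the configuration; two runs with the same
configuration are identical.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: no nucleotide sequence or real splice-site motifs, so
scores are consistent-by-construction rather than computed from sequence;
no relatedness or pedigree structure beyond an informative-meioses count;
no ancestry stratification of frequencies; no correlation between a gene's
length and its variant count or control denominator; functional outcomes
are drawn from a mixture rather than caused by the variant's position.

Burden-calibration simulations (type-I error, planted-enrichment recovery)
use `deep_intronic_max = 75`, placing every variant inside exome-like
target regions so that the planted carrier rate *is* the burden-qualifying
rate; discovery-style cohorts allow depths to 300 nt, where the 75 bp
region rule removes roughly half the deep intronic variants, as it should.

## Numerical choices

* Exact hypergeometric tail via `phyper` (never a normal or chi-square
  approximation); validated in the tests by exhaustive comparison against a
  `choose()`-based enumeration over all 635,376 two-by-two tables with
  total ≤ 60 and against `fisher.test`.
* Printed percentages round half *up* at one decimal (0.10305 → "10.3"),
  matching clinical-report style, rather than R's round-half-to-even;
  p-values print in scientific notation.
* Strict threshold inequalities throughout; ties therefore fail filters and
  evidence cut-offs deterministically.
* Type-I error of the whole burden stage is checked on 2000 null cohorts
  (case rates equal control rates) at the full group sizes; planted
  enrichment recovery on 200 replicates of the 8.2%-in-720 HCM setting.
  These replicate counts give Monte-Carlo standard errors well under the
  asserted bounds while keeping the default test run to a few minutes.

## Limitations

Beyond the generator caveats above: the gene panels and gene-level metadata
(LoF mechanism, haploinsufficiency scores, o/e ratios) bundled with the
package are representative defaults for simulation and testing, not curated
ClinGen/gnomAD exports — real analyses should load their own tables via
`read_gene_meta()`. Proband counts and meiosis counts are inputs; the
package does no literature or database lookup. The benign side of the
ACMG/AMP framework is not modelled because the workflow only classifies
already-rare candidate variants.

## A minimal worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_cohort(cfg)
verdicts <- prioritise(annotate_anatomy(sim$variants), sim$gene_meta)
burden <- run_burden(
  prioritise(annotate_anatomy(sim$variants), sim$gene_meta, mode = "burden_75bp"),
  sim$controls, sim$gene_meta, "HCM", case_n = cfg$group_sizes[["HCM"]]
)
burden[burden$significant, c("gene", "excess", "p_one_sided", "power")]
classify_variants(verdicts, sim$gene_meta)
```

The numbered scripts under `analysis/` run the same stages over TSV files
in `results/`, and `scripts/acceptance.R` recomputes the headline
quantities from scratch.
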