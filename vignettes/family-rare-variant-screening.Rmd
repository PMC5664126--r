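---
title: "Family-based rare-variant screening: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based rare-variant screening: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscreen)
```

## The analysis problem

Task-specific focal dystonias such as musician's dystonia (MD) and
writer's dystonia (WD) show strong familial aggregation with apparently
autosomal-dominant transmission, but individual families are far too small
for linkage. The pragmatic discovery design, which this package
implements as a tested pipeline, is:

* sequence the affected members of a few small dominant families;
* within each family, reduce the variant list by a filter cascade —
  exonic/splicing, protein-changing, rare in a reference panel, shared by
  all definitely affected members;
* across families, hypothesize a shared disease gene: any gene hit by
  surviving variants of at least two families is a candidate;
* check segregation of candidate variants in all available relatives,
  tolerating the two failure modes dominant dystonia pedigrees actually
  show — phenocopies (affected non-carriers) and reduced penetrance
  (unaffected carriers);
* screen case and control cohorts for additional carriers and compare
  carrier counts with a two-tailed Fisher exact test.

## Data model and formats

Variants are biallelic records keyed `chrom:pos:ref:alt`; multi-allelic
VCF records are split per alternate allele with dosage-conserving
genotype recoding (a `1/2` genotype is heterozygous for both split
records). Keys use the minimal allele representation — shared suffix then
shared prefix trimmed with position adjustment — so the VCF and the
annotation sidecar agree on indel spelling. Full left-alignment would
require the reference sequence, which the IO layer deliberately does not
depend on; inputs whose indels differ by placement within a repeat tract
must be pre-normalized (e.g. with `bcftools norm`).

Annotation (gene, consequence class, panel allele frequency, external
predictor scores) lives in a TSV sidecar rather than in INFO/CSQ fields:
annotator dialects differ, and a flat table keeps provenance explicit.
Unknown consequence strings collapse to `other`, which the cascade treats
as non-exonic. Pedigrees are standard 6-column PED (affection 2 =
affected, 1 = unaffected, 0/−9 = unknown) with an optional seventh cohort
column; a separate cohort TSV overrides it when both are present.
Half-calls and non-diploid genotypes map to missing — the analysis is
autosomal and diploid only.

## The filter cascade

Stage order is fixed: consequence, rarity, sharing. Two stages of the
published recipe ("exonic or splicing" and "affects the amino acid
sequence") overlap almost completely, so they are fused into one
consequence filter; the stage ledger still reports an `exonic_splicing`
pre-count for transparency. Decisions that matter:

* **Strict `<` at the rarity threshold** (default 0.01): a variant at
  exactly 1% fails. The threshold is a `filter_config()` parameter.
* **Missing panel frequency keeps the variant** by default. A novel
  variant absent from dbSNP/GnomAD-like panels is certainly rare; dropping
  it would have discarded one of the motivating study's two discovery
  hits. `missing_af_policy = "drop"` is available for sensitivity
  analyses.
* **"Definitely affected" means affection status 2 only.** Unknown-status
  members never constrain sharing — the motivating pedigrees include an
  elderly carrier mother who could not be neurologically examined.
* **Sharing ignores zygosity class**: heterozygous and homozygous
  carriers both count, since real pedigrees can contain homozygous
  carriers of a dominant allele.
* **An affected member with a missing genotype fails the variant**
  (conservative default); `missing_genotype_policy = "ignore"` lets such
  members abstain instead, since vendor pipelines differ here.

The cross-family step maps each gene to the families whose final variants
hit it; `min_families_shared` (default 2) defines candidacy. Reports are
ordered lexicographically by gene so runs are byte-reproducible.

Segregation reports label members `+/+`, `+/-`, `-/-` or `?` and flag
affected non-carriers (phenocopy candidates) and unaffected or
unknown-status carriers (reduced-penetrance carriers); members with
missing calls are never flagged.

## Cohort screening and burden statistics

Per-variant, per-cohort tallies count genotyped individuals, carriers,
and alternate alleles, formatted as `"alt/total"` allele fractions
(`"3/482"` for 3 carrier alleles among 241 diploid genotypes).
Individual-level summaries count a person carrying two qualifying
variants once; an `is_index` flag and an exclusion list keep discovery
families and relatives out of burden denominators, mirroring how the
motivating study derived its 10/916 figure from 919 dystonia index
patients. Percentages are printed with half-up rounding (0.25% → 0.3%),
not banker's rounding, because that is how screening papers print them;
`round_half_up()` carries a 1e-9 tolerance for binary floating-point
representation of exact halves.

The Fisher test uses the probability-mass two-tailed convention: sum the
hypergeometric point probabilities of all same-margin tables whose mass
does not exceed the observed table's, with relative tolerance `1 + 1e-7`
for ties. Point masses are computed via `lchoose` in log space, exact for
the cohort sizes involved (thousands). This convention reproduces the
motivating study's printed p-values (0.005 for 10/916 vs 1/973; 0.0278
for the Caucasian-only 7/830 vs 1/973), and on all 2×2 tables with
margins ≤ 12 it agrees exactly with full enumeration (tested). The
Pearson chi-square for r×c category tables uses no continuity correction
and refuses tables with a zero expected cell, advising a category merge.

## The simulator: what it emulates, and what it does not

`simulation_config()` defaults are the motivating study's design:
screening cohorts of 241 MD, 74 WD, 604 other-dystonia, 512 Parkinson
and 461 control individuals; case/control causal-carrier frequencies
10/916 and 1/973; a causal missense variant with panel frequency 0
(novel). The background panel draws allele frequencies from a mixture —
point mass 0.2 at zero plus 0.5 · Beta(0.5, 5) on (0, 0.5] — giving a
low-frequency-skewed, exome-like spectrum with a realistic share of
panel-absent variants; 40% of background variants are protein-changing.
These are desk-scale stand-ins (hundreds of variants, not the ~25,000 of
a real exome), chosen so the full property suite runs in minutes; the
cascade's behaviour is scale-free, and its counts are checked against a
closed-form expectation rather than against the study's raw counts,
which depend on unavailable sequencing data.

Families are a founder couple plus `n_children` offspring. The published
pedigrees span two to three generations, but the cascade consumes only
affection status and genotypes, so deeper structures would add surface
without coverage. One founder (the father, by convention) is a
heterozygous causal carrier; transmission is Mendelian with probability
one half per allele; background genotypes are Hardy–Weinberg draws from
the panel frequency, unlinked (no LD) and autosomal. Affection is
sampled independently per member: penetrance for carriers (default 0.8),
phenocopy rate for non-carriers (default 0.05). The defaults acknowledge
that dominant dystonia penetrance is substantially reduced (the classic
TOR1A deletion penetrance is ~30%) while keeping simulated pedigrees
informative; planted-recovery guarantees are stated and tested at
penetrance 1, phenocopy 0, where they are deterministic consequences of
the sampling rules. Shared-environment effects (e.g. practice exposure in
musicians' families) are not modelled — affection is conditionally
independent given carrier status.

Randomness is reproducible by construction: every draw happens in a
sub-stream seeded by a rolling hash of the master seed and a
purpose/family/member key. Per-member (rather than per-variant) streams
keep the draws vectorizable while still guaranteeing that appending
variants never perturbs other members' existing genotypes; all outputs
are byte-identical across runs for a fixed seed.

`expected_background_survivors()` gives the closed-form expected number
of background variants surviving a family's cascade: consequence and
rarity probabilities come directly from the generative mixture, and the
sharing probability integrates, over the frequency spectrum (Gauss
quadrature via `integrate`), an exact enumeration of the founders'
Hardy–Weinberg genotypes with the affection process marginalized out.
Families with no affected member count as vacuous passes in the formula,
whereas the cascade itself refuses them, so closed-form/Monte-Carlo
comparisons are run at penetrance 1. Over 500 seeded replicates at 150
background variants the Monte-Carlo mean falls within the 99% confidence
interval of the closed form (tested).

What passing tests do and do not show: they validate the pipeline's
logic, determinism and statistical calibration under an idealized
generative model — unlinked variants, exact Hardy–Weinberg, no
genotyping error beyond explicit missingness, no population
stratification. They do not validate annotation quality, sequencing
artefacts, or relatedness within screening cohorts, all of which a real
application must handle upstream.

## Numerical and degenerate-input choices

* Fisher on a table with an empty row or column returns p = 1 (one
  admissible table).
* The chi-square refuses expected-zero cells rather than returning NaN.
* `carrier_percent()` refuses a zero denominator.
* Cascade on an empty variant list returns all-zero stage counts.
* A family with no affected member is an error naming the family, not a
  silent pass.
* PED parsing rejects unresolved parent references and cyclic parentage
  (topological elimination).
* Tallies treat roster individuals without a call row as genotyped
  reference by default (so sparse carrier-only call sets work) and
  explicitly missing calls as not genotyped; `absent = "missing"`
  switches to dense-call semantics.

## Problem sizes used by the test and acceptance runs

Unit and property tests run on panels of 10–400 variants, families of
4–8 members, cohorts up to 10,000 individuals (Hardy–Weinberg checks),
100 seeded two-family discovery replicates, 500 Monte-Carlo cascade
replicates, full Fisher-enumeration over all ~5,500 tables with margins
≤ 12, and 2,000 null burden replicates for the type-I error check.
`scripts/acceptance.R` reruns the study-count statistics exactly and 50
two-family synthetic discovery replicates.

## Known limitations

* Dominant sharing only: no recessive or compound-heterozygote models,
  no linkage or haplotype phasing.
* No LD, de novo mutation, or X-linked inheritance in the simulator.
* Annotation is pass-through: the package computes no consequences,
  frequencies or predictor scores.
* The burden test conditions on cohort sizes; it does not model
  relatedness or ancestry structure within cohorts (the motivating study
  handled ancestry by subsetting, which the tooling supports through
  explicit count-based runs).
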