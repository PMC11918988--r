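---
title: "Prioritizing rare variants in small trio/singleton cohorts"
author: "VariantCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare variants in small trio/singleton cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VariantCascade)
```

# The analysis

VariantCascade reimplements, as reusable and tested components, a strict
rare-variant prioritization analysis for small genome-sequencing cohorts in
which probands carry a candidate-Mendelian neurodevelopmental phenotype —
concretely, idiopathic speech delay — and the study design mixes
proband–parent trios with singleton probands. The pipeline has five stages:

1. **Genotype-level QC**: keep variants whose FILTER verdict is pass, that
   lie outside segmental duplications, and whose carried alleles each have
   at least four supporting reads in the proband (a heterozygote with three
   or fewer reads on either allele is discarded).
2. **Population-frequency ceiling**: keep variants whose allele frequency in
   *both* reference databases (gnomAD and Kaviar; their maximum is compared)
   lies strictly below the maximum credible population allele frequency.
3. **Design-specific routes**: trio probands go through a de novo route
   (present in the child, homozygous-reference parents with zero
   alt-supporting reads, then a damaging-and-intolerant evaluation);
   singleton probands go through a pLoF or a missense route combining gene
   constraint, regional tolerance, predicted impact and a parental-panel
   exclusion (absence from all parents of all trios in the cohort).
4. **Structural variants**: calls from a read-pair caller and a read-depth
   caller are kept when they concord (at most a twofold size difference and
   both breakpoints within 10 kb), are absent from the parents' read-pair
   calls, and the consensus interval overlaps an exon of a
   loss-of-function-intolerant gene.
5. **Five-tier interpretation**: surviving variants are classified into
   pathogenic / likely pathogenic / VUS / likely benign / benign from gene
   evidence (established gene–disease association, mechanism, causal
   clusters, phenotype similarity), variant context (inheritance, population
   novelty, ClinVar status, predicted nonsense-mediated decay, competing
   findings) and the cascade's own impact verdicts.

All elementary filters are *conjunctive* predicates, so the survivor set is
invariant to the order in which they are applied; the implementation records
a per-filter audit trail for every carried variant.

# The allele-frequency ceiling

For a monoallelic (heterozygous-carrier) disorder the highest frequency a
truly causal allele can plausibly reach in a population database is

$$AF_\max = \frac{\text{prevalence} \times \text{heterogeneity}}
{2 \times \text{penetrance}},$$

where *heterogeneity* is the maximum share of cases attributable to any one
variant and the factor 2 converts a carrier (genotype) frequency into an
allele frequency. With prevalence 2.9% (3.6% prevalence of speech delay in
4–8-year-olds, of which 82% have no motor speech disorder), heterogeneity
0.02 and penetrance 90%, the ceiling is

```{r}
prev <- derivePrevalence(0.036, 0.82)
prev
signif(maxCredibleAF(prev, 0.02, 0.90), 2)
```

Two numerical choices deserve note. First, the prevalence derivation
*truncates* toward zero at the requested significant figures rather than
rounding — 0.036 × 0.82 = 0.02952 is reported as 0.029, never 0.030 — so the
reported prevalence (and hence the ceiling) is conservative. Second, the
ceiling is displayed at two significant figures but the comparison in the
frequency filter uses the configured value as given; `filterConfig()`
defaults to the displayed 3.2 × 10⁻⁴, and all frequency comparisons are
strict inequalities, so a variant exactly at the ceiling fails. Only the
monoallelic model is offered: a biallelic mode would need a different
carrier-to-allele conversion, and every disorder this cascade targets is
dominant-model.

# Thresholds and their defaults

`filterConfig()` carries every numeric threshold, all strict inequalities:

| parameter | default | role |
|---|---|---|
| `mafCeiling` | 3.2e-4 | max(gnomAD, Kaviar) must lie below it |
| `minReadsPerAllele` | 4 reads | per carried allele, proband genotypes |
| `pliMin` | 0.9 | pLoF / SV gene intolerance (pLI) |
| `misZMin` | 2.5 | missense constraint Z |
| `gerpMin` | 2 | base-level conservation for missense impact |
| `revelMin` | 0.5 | ensemble deleteriousness for missense impact |
| `nmdEndWindowBp` | 50 bp | end-of-transcript window (coding bp) |
| `denovoRevelToleratedMax` | 0.25 | REVEL below this marks a de novo missense tolerated |
| `denovoMisZMin` | 3 | with a tolerant regional score, marks the gene missense-tolerant |

Missense gene intolerance requires both a constrained gene (missense Z above
threshold *or* pLI above threshold) and a residue whose regional
(Metadome-style) tolerance category lies on the intolerant side; "slightly
intolerant" counts as intolerant, "neutral" does not, which follows the
category ladder's midpoint.

Three behavioural switches exist because the underlying procedure is
ambiguous at the margins:

* `applyReadQcToParents` (default `FALSE`): the read-support rule is stated
  for the proband's alleles; whether it also gates parental genotypes is
  unspecified, so the default applies it to the proband only.
* `requireZeroParentAltReads` (default `TRUE`): a de novo call additionally
  requires zero alternate reads in both parents, guarding against
  under-called low-level transmission (a hom-ref genotype call alone can
  hide a mosaic or poorly covered allele).
* `toleranceNaBlocks` (default `TRUE`): an *unavailable* regional-tolerance
  score fails the missense gene filter, because unknown tolerance is not
  evidence of intolerance. The waiver (`FALSE`) lets gene-level constraint
  decide alone; it exists because the transcribed missense table retains one
  variant (in *CIC*) whose regional score is unavailable, so reproducing the
  printed eighteen survivors requires the waiver, while the stricter default
  yields seventeen. Relatedly, a missense variant whose SIFT, PolyPhen *and*
  REVEL are all unavailable cannot be scored by the impact filter at all;
  it is passed through flagged `predictors_unavailable` rather than failed —
  the same treatment inframe indels receive by construction — because a
  conjunction over entirely absent evidence would silently delete exactly
  the rows the original analysis kept.

# The de novo evaluation

De novo candidates that pass QC, frequency and brain expression are judged
damaging-and-intolerant as follows: a pLoF variant qualifies iff the gene's
pLI exceeds `pliMin`; a missense variant is *rejected* when it is predicted
tolerated by the protein (SIFT or PolyPhen benign, and/or REVEL <
`denovoRevelToleratedMax`) **or** lies in a (region of a) gene tolerant to
missense change (missense Z < `denovoMisZMin` **and** a tolerant-side
regional category). Note the asymmetry with the singleton route: the de novo
rule is an exclusion rule over unfiltered nonsynonymous de novos, not a
conjunction of inclusion filters, and its thresholds (REVEL 0.25, missense Z
3) differ from the singleton thresholds by design.

# Five-tier classification

The rule table encodes exactly the dispositions the reimplemented analysis
demonstrates — it is deliberately *not* a general ACMG/AMP engine:

* **R1, ClinVar override**: a benign/likely-benign ClinVar verdict becomes
  the tier; conflicting interpretations become VUS. The ClinVar-sourced
  alternative is preserved in the rationale codes and in the formatted cell
  ("Likely pathogenic/VUS", "VUS/likely benign" — a pathogenic-side
  alternative precedes the engine tier, a benign-side one follows it).
* **R2, pathogenic**: a truncating variant predicted to trigger
  nonsense-mediated decay (strictly more than 50 coding bp from the
  transcript end) in an established haploinsufficiency gene whose associated
  phenotype is not dissimilar.
* **R3, likely pathogenic**: a missense-class variant in an established
  missense-mechanism gene that is novel in both population databases, at a
  conserved residue, passed the impact filter, and falls inside a known
  causal cluster (or the gene is flagged domain-critical with no cluster
  defined and the variant hits a domain).
* **R4/R5, VUS otherwise**, with machine-readable codes naming the reason:
  gene not established, outside the causal cluster, dissimilar phenotype,
  NMD escape, inherited from an unaffected parent, or a competing (likely)
  pathogenic finding in the same proband. The competing-finding flag is
  computed in a second pass so it never depends on classification order.

Rule priority is fixed (R1 over R2 over R3 over R4): a variant with
conflicting ClinVar interpretations stays VUS even when it superficially
meets R3. Demotions (unaffected-parent inheritance, competing finding) gate
R2/R3 but never promote. Evidence is monotone: withdrawing a gene's
established status can only move a tier away from pathogenic.

The diagnostic yield is the percentage of probands with at least one
pathogenic or likely-pathogenic variant, rounded to the nearest integer
percent (3 of 23 probands gives 13%).

# SV concordance choices

"Maximum twofold size difference" is read as a size *ratio* ≤ 2 (twofold
denotes a ratio, not an absolute difference), and the 10 kb breakpoint
tolerance is enforced at *both* the start and the end: with only the size
constraint, a single-breakpoint rule would admit grossly discordant
intervals. Calls pair one-to-one greedily by the smallest combined
breakpoint distance (|Δstart| + |Δend|), ties broken by leftmost start; the
source procedure names no pairing scheme, and on realistic jitter the greedy
and the exhaustive pairing agree (this is property-tested against an
enumeration oracle). Parental exclusion consults only the read-pair caller's
parental output, following the letter of the described procedure.

# What the synthetic generator emulates — and what it does not

`generateCohort()` produces, deterministically from a seed, the full input
bundle: VCF-serializable genotypes for 10 trios and 13 singletons,
per-allele depths from a negative-binomial model with mean 33 (the study's
average depth), Mendelian transmission for background variants with
Poisson(1.2) background de novo events per trio proband, an annotation table
whose background rows are drawn from tolerant-gene/benign-score ranges
(pLI < 0.85, missense Z < 2, tolerant-side regional categories, REVEL <
0.45), planted variants whose fields deterministically satisfy or violate
each filter clause per template, and dual-caller SV call sets with uniform
breakpoint jitter (±2 kb) around each true event. The allele-frequency
spectrum is a four-class mixture (common 0.40 / low-frequency 0.30 / rare
0.20 / absent 0.10) chosen so that roughly a third of background variants
pass the frequency ceiling and the later clauses do the filtering work.

Realism is deliberately limited to what the cascade observes: annotation
fields are sampled from template-conditional ranges, not from real
databases; linkage, shared variants between families, genotyping error,
multi-allelic sites and mosaicism are not modelled; background variants
cannot survive by construction. Passing recovery tests therefore
demonstrates that the *decision logic* is faithful — which clause admits or
excludes which archetype — not that the pipeline is robust to real-data
noise. The per-proband background load (150 variants by default) is a
coding-scale stand-in that keeps the full suite comfortably fast; the
property tests run on cohorts of ≥ 3,000 variants and SV instances of 100
calls, sizes at which the brute-force oracles are still exact.

# Degenerate inputs and tie-breaks

* Absent numeric annotations are `NA`, never 0; each predicate documents its
  treatment (constraint filters fail on absent scores, the frequency filter
  treats absent frequencies as 0, the pLoF impact filter *errors* on a
  truncation without a transcript-end distance rather than guess).
* All threshold comparisons are strict, so boundary values (pLI 0.9, 4-read
  alleles are the exceptions as ≥ thresholds; REVEL 0.5, GERP 2, the 50 bp
  window, the frequency ceiling) behave deterministically and are covered by
  boundary tests.
* Genotype keys are `chrom:pos:ref:alt`; multi-allelic records must be split
  upstream, indels are assumed left-normalized by the producer, and no
  liftover is attempted (fixtures use GRCh37 coordinates).
* Within the fixture tables, a truncation's distance to the transcript end
  and its protein-domain overlap are synthetic augmentations (the printed
  tables do not carry them) chosen to be consistent with each variant's
  printed disposition; they are marked as such in the fixture documentation.

# Known limitations

The classifier reproduces one specific study's interpretive behaviour, so
transferring it to another cohort means re-curating the gene-evidence table.
Compound-heterozygous and X-linked models are out of scope, as is annotation
computation (SIFT/PolyPhen/REVEL/GERP/constraint scores are inputs, never
recomputed). The NMD rule is the stated 50-bp end-of-transcript window; the
canonical last-exon-junction rule differs for multi-exon transcripts near
the 3' end, and the two can disagree — the stated rule is implemented and
the discrepancy recorded here. The parental-panel filter depends on how many
trio parents the cohort happens to contain; with none it degrades (with a
warning) to a pass-through.
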