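Package: VariantCascade
Title: Rare-Variant Prioritization and Five-Tier Classification for
    Trio and Singleton Genome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements a strict rare-variant prioritization cascade for
    small genome-sequencing cohorts of probands with a Mendelian-candidate
    phenotype, as applied to idiopathic speech delay. Provides the maximum
    credible population allele frequency ceiling derived from disease
    prevalence, allelic heterogeneity and penetrance; conjunctive filters on
    gene constraint (pLI, missense Z, regional tolerance), predicted impact
    (GERP, REVEL, SIFT, PolyPhen, splice-site class, 50-bp end-of-transcript
    rule) and brain expression for singleton designs; a de novo route for
    trio designs; dual-caller structural-variant concordance; a five-tier
    pathogenicity classification engine with machine-readable rationale
    codes; and a seeded synthetic-cohort generator with planted variants for
    end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'afThreshold.R'
    'classification.R'
    'cohortIO.R'
    'pipeline.R'
    'prioritization.R'
    'svConcordance.R'
    'syntheticCohort.R'
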