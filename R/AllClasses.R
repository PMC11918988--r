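#' @import methods
#' @importFrom S4Vectors DataFrame SimpleList
NULL

## Controlled vocabularies used across the cascade. The consequence classes
## are the ones the filters distinguish; anything else is routed nowhere.
.CONSEQUENCES <- c("missense", "stop_gain", "frameshift", "splice",
                   "inframe_indel", "synonymous", "other")
.PLOF <- c("stop_gain", "frameshift", "splice")
.MISSENSE_LIKE <- c("missense", "inframe_indel")
.TOLERANCE_LEVELS <- c("highly_intolerant", "intolerant", "slightly_intolerant",
                       "neutral", "slightly_tolerant", "tolerant", "unavailable")
.TOLERANCE_INTOLERANT <- c("highly_intolerant", "intolerant", "slightly_intolerant")
.TOLERANCE_TOLERANT <- c("neutral", "slightly_tolerant", "tolerant")
.SIFT_LEVELS <- c("D", "T", "unavailable")
.POLYPHEN_LEVELS <- c("D", "P", "T", "unavailable")
.SPLICE_CLASSES <- c("main_donor_acceptor", "other", "not_splice")
.TIERS <- c("pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign")
.CLINVAR_LEVELS <- c("pathogenic", "likely_pathogenic", "conflicting",
                     "likely_benign", "benign", "absent")

## Columns a variant annotation table must carry (beyond the chrom/pos/ref/alt key).
.ANNOTATION_COLS <- c("gene", "transcript", "consequence", "cdna_change",
                      "protein_change", "gnomad_af", "kaviar_af", "pli", "mis_z",
                      "local_tolerance", "sift", "polyphen", "revel", "gerp",
                      "brain_expressed", "in_segdup", "dist_to_transcript_end",
                      "affects_protein_domain", "splice_site_class",
                      "protein_position")

#' Thresholds of the prioritization cascade
#'
#' Every numeric threshold of the filtering cascade, with the study's values
#' as defaults. The allele-frequency ceiling default is the maximum credible
#' population allele frequency computed by [maxCredibleAF()] from a disorder
#' prevalence of 2.9\%, allelic heterogeneity 0.02 and penetrance 90\%,
#' reported to two significant figures (3.2e-4).
#'
#' @slot mafCeiling numeric, strict upper bound on the larger of the two
#'   database allele frequencies.
#' @slot minReadsPerAllele integer, minimum reads supporting each allele
#'   carried by the proband ("three or fewer" supporting reads fail).
#' @slot pliMin numeric, strict lower bound on pLI for loss-of-function
#'   intolerance.
#' @slot misZMin numeric, strict lower bound on the missense constraint
#'   Z-score.
#' @slot gerpMin numeric, strict lower bound on GERP for missense impact.
#' @slot revelMin numeric, strict lower bound on REVEL for missense impact.
#' @slot nmdEndWindowBp integer, coding-bp window at the transcript end within
#'   which truncating variants are presumed to escape nonsense-mediated decay.
#' @slot denovoRevelToleratedMax numeric, REVEL below which a de novo missense
#'   variant counts as tolerated.
#' @slot denovoMisZMin numeric, missense-Z below which (together with a
#'   tolerant regional score) the gene counts as missense-tolerant for the
#'   de novo evaluation.
#' @slot applyReadQcToParents logical, whether the per-allele read-support
#'   rule is also applied to parental genotypes (default `FALSE`: proband
#'   only).
#' @slot requireZeroParentAltReads logical, whether a de novo call requires
#'   zero alt-supporting reads in both parents in addition to homozygous
#'   reference genotypes (default `TRUE`).
#' @slot toleranceNaBlocks logical, whether an unavailable regional-tolerance
#'   score fails the missense gene-intolerance filter (default `TRUE`; set
#'   `FALSE` to let gene-level constraint alone decide when the regional score
#'   is missing).
#' @seealso [filterConfig()]
#' @export
setClass("FilterConfig",
  representation(
    mafCeiling = "numeric",
    minReadsPerAllele = "integer",
    pliMin = "numeric",
    misZMin = "numeric",
    gerpMin = "numeric",
    revelMin = "numeric",
    nmdEndWindowBp = "integer",
    denovoRevelToleratedMax = "numeric",
    denovoMisZMin = "numeric",
    applyReadQcToParents = "logical",
    requireZeroParentAltReads = "logical",
    toleranceNaBlocks = "logical"
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character()
  fr <- c(mafCeiling = object@mafCeiling, revelMin = object@revelMin,
          denovoRevelToleratedMax = object@denovoRevelToleratedMax,
          pliMin = object@pliMin)
  bad <- fr < 0 | fr > 1
  if (any(bad))
    msg <- c(msg, paste0("fraction slots out of [0,1]: ",
                         paste(names(fr)[bad], collapse = ", ")))
  if (object@minReadsPerAllele < 0L || object@nmdEndWindowBp < 0L)
    msg <- c(msg, "read and window thresholds must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A cohort of annotated variants with per-sample genotypes
#'
#' The central container: one row per variant (keyed by chrom, pos, ref, alt)
#' carrying every annotation field the cascade consumes, aligned genotype and
#' allele-depth matrices (variants x samples), and the pedigree describing
#' which samples form trios and which probands are singletons.
#'
#' @slot variants a [S4Vectors::DataFrame] with the key columns `chrom`,
#'   `pos`, `ref`, `alt`, `filter_status` plus the annotation columns
#'   (gene, transcript, consequence, population frequencies, constraint and
#'   impact scores, brain expression, segmental-duplication flag, distance to
#'   transcript end, protein-domain flag, splice-site class, protein
#'   position).
#' @slot gt character matrix of genotype calls, values `"hom_ref"`, `"het"`,
#'   `"hom_alt"` or `"missing"`.
#' @slot adRef,adAlt integer matrices of reference / alternate supporting
#'   read counts (NA where missing).
#' @slot pedigree data.frame with columns `proband`, `father`, `mother`
#'   (`NA` for absent parents) and `design` (`"trio"` or `"singleton"`).
#' @seealso [readCohort()], [writeCohort()], [runCascade()]
#' @export
setClass("VariantCohort",
  representation(
    variants = "DataFrame",
    gt = "matrix",
    adRef = "matrix",
    adAlt = "matrix",
    pedigree = "data.frame"
  )
)

setValidity("VariantCohort", function(object) {
  v <- object@variants
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "filter_status", .ANNOTATION_COLS)
  miss <- setdiff(need, colnames(v))
  if (length(miss))
    return(paste0("variants lacks columns: ", paste(miss, collapse = ", ")))
  n <- nrow(v)
  dims <- vapply(list(object@gt, object@adRef, object@adAlt), nrow, 0L)
  if (any(dims != n))
    msg <- c(msg, "genotype/depth matrices must have one row per variant")
  if (!identical(colnames(object@gt), colnames(object@adRef)) ||
      !identical(colnames(object@gt), colnames(object@adAlt)))
    msg <- c(msg, "genotype and depth matrices must share sample columns")
  if (n > 0) {
    if (any(v$pos < 1L)) msg <- c(msg, "pos must be >= 1")
    if (any(v$ref == v$alt)) msg <- c(msg, "ref and alt must differ")
    for (col in c("gnomad_af", "kaviar_af", "pli", "revel")) {
      x <- v[[col]]
      if (any(!is.na(x) & (x < 0 | x > 1)))
        msg <- c(msg, paste0(col, " out of [0,1]"))
    }
    if (!all(v$consequence %in% .CONSEQUENCES))
      msg <- c(msg, "unknown consequence class")
    splice_ok <- (v$consequence == "splice") ==
      (v$splice_site_class != "not_splice")
    if (any(!splice_ok))
      msg <- c(msg, "consequence 'splice' must pair with a splice_site_class")
  }
  ped <- object@pedigree
  if (!all(c("proband", "father", "mother", "design") %in% colnames(ped)))
    msg <- c(msg, "pedigree needs proband/father/mother/design columns")
  else {
    trio <- ped$design == "trio"
    if (any(trio & (is.na(ped$father) | is.na(ped$mother))))
      msg <- c(msg, "trio design requires both parent ids")
    if (anyDuplicated(ped$proband))
      msg <- c(msg, "each proband must be listed once")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic-cohort generator
#'
#' Study conditions for simulated cohorts: family structure, background
#' variant load, de novo rate, allele-frequency spectrum, sequencing-depth
#' model, planted-variant specifications and the seed.
#'
#' @slot nTrios,nSingletons integer counts of trio / singleton probands.
#' @slot variantsPerProband integer, background variants carried per proband.
#' @slot denovoRate numeric, expected de novo background events per trio
#'   proband (Poisson).
#' @slot afWeights named numeric mixture weights over the frequency classes
#'   `common`, `low`, `rare`, `absent`; must sum to 1.
#' @slot depthMean,depthDispersion numeric, negative-binomial read-depth model.
#' @slot plants data.frame of planted variants (columns `template`,
#'   `proband`, `expected_survival`, `expected_tier`).
#' @slot seed integer random seed; identical seeds give identical bundles.
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nTrios = "integer",
    nSingletons = "integer",
    variantsPerProband = "integer",
    denovoRate = "numeric",
    afWeights = "numeric",
    depthMean = "numeric",
    depthDispersion = "numeric",
    plants = "data.frame",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nTrios < 0L || object@nSingletons < 0L ||
      object@variantsPerProband < 0L || object@denovoRate < 0)
    msg <- c(msg, "counts and rates must be non-negative")
  w <- object@afWeights
  if (!identical(sort(names(w)), sort(c("common", "low", "rare", "absent"))))
    msg <- c(msg, "afWeights needs names common/low/rare/absent")
  else if (abs(sum(w) - 1) > 1e-8 || any(w < 0))
    msg <- c(msg, "afWeights must be non-negative and sum to 1")
  if (length(msg)) msg else TRUE
})
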