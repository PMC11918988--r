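#' @include AllClasses.R
NULL

#' Accessors for VariantCohort objects
#'
#' `variantTable()` returns the per-variant annotation DataFrame,
#' `genotypeMatrix()` the variants-by-samples genotype call matrix,
#' `alleleDepths()` a list with integer matrices `ref` and `alt`,
#' `pedigree()` the family table, `cohortSamples()` the sample ids and
#' `variantKeys()` the `chrom:pos:ref:alt` key strings.
#'
#' @param x a [VariantCohort-class] object.
#' @return See each accessor's description.
#' @name cohort-accessors
#' @aliases variantTable genotypeMatrix alleleDepths pedigree cohortSamples
#'   variantKeys
#' @examples
#' b <- generateCohort(cohortConfig(nTrios = 1, nSingletons = 1,
#'                                  variantsPerProband = 5, seed = 7))
#' nrow(variantTable(b$cohort))
#' head(variantKeys(b$cohort))
NULL

#' @rdname cohort-accessors
#' @export
setGeneric("variantTable", function(x) standardGeneric("variantTable"))

#' @rdname cohort-accessors
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname cohort-accessors
#' @export
setGeneric("alleleDepths", function(x) standardGeneric("alleleDepths"))

#' @rdname cohort-accessors
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname cohort-accessors
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @rdname cohort-accessors
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))

#' @rdname cohort-accessors
setMethod("variantTable", "VariantCohort", function(x) x@variants)

#' @rdname cohort-accessors
setMethod("genotypeMatrix", "VariantCohort", function(x) x@gt)

#' @rdname cohort-accessors
setMethod("alleleDepths", "VariantCohort",
          function(x) list(ref = x@adRef, alt = x@adAlt))

#' @rdname cohort-accessors
setMethod("pedigree", "VariantCohort", function(x) x@pedigree)

#' @rdname cohort-accessors
setMethod("cohortSamples", "VariantCohort", function(x) colnames(x@gt))

#' @rdname cohort-accessors
setMethod("variantKeys", "VariantCohort", function(x) {
  v <- x@variants
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
})

setMethod("show", "VariantCohort", function(object) {
  ped <- object@pedigree
  cat("VariantCohort with", nrow(object@variants), "variants,",
      ncol(object@gt), "samples\n")
  cat("  probands:", sum(ped$design == "trio"), "trio,",
      sum(ped$design == "singleton"), "singleton\n")
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  MAF ceiling          < %g\n", object@mafCeiling))
  cat(sprintf("  reads per allele    >= %d\n", object@minReadsPerAllele))
  cat(sprintf("  pLI                  > %g ; MIS_Z > %g\n",
              object@pliMin, object@misZMin))
  cat(sprintf("  GERP                 > %g ; REVEL > %g\n",
              object@gerpMin, object@revelMin))
  cat(sprintf("  NMD end window         %d bp\n", object@nmdEndWindowBp))
  cat(sprintf("  de novo: REVEL tolerated < %g ; MIS_Z tolerant < %g\n",
              object@denovoRevelToleratedMax, object@denovoMisZMin))
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nTrios, "trios,", object@nSingletons,
      "singletons,", object@variantsPerProband, "background variants/proband,",
      nrow(object@plants), "plants, seed", object@seed, "\n")
})
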