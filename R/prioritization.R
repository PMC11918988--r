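## The filter cascade. All elementary filters are vectorized over the rows of
## a variant annotation table (DataFrame or data.frame) and return logical
## vectors; NA marks "not applicable" (wrong consequence class, or an
## explicitly non-blocking verdict). runCascade() assembles them into
## per-proband audit trails.

.naFalse <- function(x) { x[is.na(x)] <- FALSE; x }

#' Population allele-frequency filter
#'
#' Passes when the larger of the two database frequencies (gnomAD, Kaviar)
#' lies strictly below the ceiling; absent frequencies count as 0, so a
#' variant never seen in either database always passes.
#'
#' @param variants variant annotation table (rows of a
#'   [VariantCohort-class] `variantTable()`).
#' @param config a [FilterConfig-class].
#' @return Logical vector.
#' @export
mafFilter <- function(variants, config = filterConfig()) {
  g <- ifelse(is.na(variants$gnomad_af), 0, variants$gnomad_af)
  k <- ifelse(is.na(variants$kaviar_af), 0, variants$kaviar_af)
  pmax(g, k) < config@mafCeiling
}

#' Gene-intolerance filter for probable loss-of-function variants
#'
#' Applicable to stop-gain, frameshift and splice variants: passes when the
#' gene's pLI strictly exceeds the threshold (default 0.9). An absent pLI
#' fails: unknown constraint is not evidence of constraint.
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` where the consequence class is not pLoF.
#' @export
plofGeneFilter <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  i <- variants$consequence %in% .PLOF
  out[i] <- .naFalse(variants$pli[i] > config@pliMin)
  out
}

#' Gene- and region-intolerance filter for missense-class variants
#'
#' Applicable to missense and inframe-indel variants: the gene must be
#' constrained (missense Z above threshold, or pLI above threshold) AND the
#' residue's regional tolerance category must lie on the intolerant side
#' (highly intolerant, intolerant or slightly intolerant). When the regional
#' score is unavailable the filter fails by default; with
#' `config@toleranceNaBlocks = FALSE` the regional clause is waived and
#' gene-level constraint alone decides.
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` where the consequence class is not
#'   missense-like.
#' @export
missenseGeneFilter <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  i <- variants$consequence %in% .MISSENSE_LIKE
  geneOk <- .naFalse(variants$mis_z[i] > config@misZMin) |
    .naFalse(variants$pli[i] > config@pliMin)
  tol <- variants$local_tolerance[i]
  tolOk <- tol %in% .TOLERANCE_INTOLERANT
  if (!config@toleranceNaBlocks)
    tolOk <- tolOk | tol == "unavailable"
  out[i] <- geneOk & tolOk
  out
}

#' Impact filter for probable loss-of-function variants
#'
#' Splice variants pass only when they hit the main donor or acceptor site.
#' Stop-gain and frameshift variants pass when they lie more than
#' `nmdEndWindowBp` coding base pairs from the end of the transcript
#' (i.e. are expected to trigger nonsense-mediated decay), or — closer to the
#' end — when they disrupt a protein domain.
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` where not applicable. Stop-gain/frameshift
#'   rows with a missing distance-to-transcript-end raise an error.
#' @export
plofImpactFilter <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  sp <- variants$consequence == "splice"
  out[sp] <- variants$splice_site_class[sp] == "main_donor_acceptor"
  tr <- variants$consequence %in% c("stop_gain", "frameshift")
  if (any(tr & is.na(variants$dist_to_transcript_end)))
    stop("dist_to_transcript_end missing for a stop-gain/frameshift variant")
  out[tr] <- variants$dist_to_transcript_end[tr] > config@nmdEndWindowBp |
    variants$affects_protein_domain[tr]
  out
}

#' Impact filter for missense variants
#'
#' A missense variant has predicted high impact when GERP and REVEL both
#' exceed their thresholds and SIFT or PolyPhen flags it as (possibly)
#' damaging. An absent predictor fails its clause — except when SIFT,
#' PolyPhen and REVEL are all unavailable, in which case the filter is not
#' applicable (returns `NA`, non-blocking) and the verdict is flagged
#' "predictors unavailable"; inframe indels are always in that situation and
#' bypass this filter by construction.
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` where not applicable.
#' @export
missenseImpactFilter <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  i <- which(variants$consequence == "missense")
  noPred <- variants$sift[i] == "unavailable" &
    variants$polyphen[i] == "unavailable" & is.na(variants$revel[i])
  ok <- .naFalse(variants$gerp[i] > config@gerpMin) &
    .naFalse(variants$revel[i] > config@revelMin) &
    (variants$sift[i] == "D" | variants$polyphen[i] %in% c("D", "P"))
  ok[noPred] <- NA
  out[i] <- ok
  out
}

#' Brain-expression filter
#'
#' Passes variants whose transcript is expressed in the (developing) human
#' brain, as recorded in the `brain_expressed` annotation flag.
#'
#' @inheritParams mafFilter
#' @return Logical vector.
#' @export
brainExpressionFilter <- function(variants) {
  variants$brain_expressed
}

#' De novo status from trio genotypes
#'
#' A variant is de novo when the proband carries the alternate allele (het or
#' hom-alt) while both parents are homozygous reference; with
#' `requireZeroParentAltReads` (the default) both parents must additionally
#' show zero alternate-supporting reads, guarding against under-called
#' transmission.
#'
#' @param cohort a [VariantCohort-class].
#' @param proband,father,mother sample ids.
#' @param config a [FilterConfig-class].
#' @return Logical vector over variants; `NA` where any of the three
#'   genotypes is missing (the variant is then excluded from the de novo
#'   route).
#' @export
isDenovo <- function(cohort, proband, father, mother,
                     config = filterConfig()) {
  for (s in c(proband, father, mother))
    if (!s %in% colnames(cohort@gt))
      stop("sample '", s, "' absent from cohort genotypes")
  gp <- cohort@gt[, proband]
  gf <- cohort@gt[, father]
  gm <- cohort@gt[, mother]
  out <- gp %in% c("het", "hom_alt") & gf == "hom_ref" & gm == "hom_ref"
  if (config@requireZeroParentAltReads) {
    fa <- cohort@adAlt[, father]
    ma <- cohort@adAlt[, mother]
    out <- out & .naFalse(fa == 0L) & .naFalse(ma == 0L)
  }
  out[gp == "missing" | gf == "missing" | gm == "missing"] <- NA
  out
}

#' Parental-panel filter for singleton probands
#'
#' For probands sequenced without their parents, variants are required to be
#' absent from every parent of every trio in the cohort (the "panel"). An
#' empty panel passes everything, with a warning.
#'
#' @param cohort a [VariantCohort-class].
#' @param panel character vector of parental sample ids; defaults to all
#'   parents named in the cohort pedigree that have genotypes.
#' @return Logical vector over variants.
#' @export
parentalPanelFilter <- function(cohort, panel = NULL) {
  if (is.null(panel)) {
    ped <- cohort@pedigree
    panel <- stats::na.omit(c(ped$father, ped$mother))
    panel <- intersect(panel, colnames(cohort@gt))
  }
  if (length(panel) == 0L) {
    warning("empty parental panel: panel filter passes all variants")
    return(rep(TRUE, nrow(cohort@variants)))
  }
  carrier <- cohort@gt[, panel, drop = FALSE] %in% c("het", "hom_alt")
  dim(carrier) <- c(nrow(cohort@variants), length(panel))
  rowSums(carrier) == 0L
}

#' Damaging-and-intolerant evaluation for de novo candidates
#'
#' Applied to de novo variants that already passed the frequency and
#' brain-expression filters. A pLoF variant qualifies when the gene's pLI
#' exceeds the threshold. A missense-like variant qualifies unless it is
#' predicted tolerated by the protein (SIFT or PolyPhen benign, and/or REVEL
#' below the tolerated bound) or lies in a (region of a) gene tolerant to
#' missense change (missense Z below its bound AND a tolerant-side regional
#' category).
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` for consequence classes outside the rule.
#' @export
evaluateDenovo <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  p <- variants$consequence %in% .PLOF
  out[p] <- .naFalse(variants$pli[p] > config@pliMin)
  m <- variants$consequence %in% .MISSENSE_LIKE
  tolerated <- variants$sift[m] == "T" | variants$polyphen[m] == "T" |
    .naFalse(variants$revel[m] < config@denovoRevelToleratedMax)
  geneTolerant <- .naFalse(variants$mis_z[m] < config@denovoMisZMin) &
    variants$local_tolerance[m] %in% .TOLERANCE_TOLERANT
  out[m] <- !tolerated & !geneTolerant
  out
}

.routeFilters <- list(
  trio_denovo = c("qc", "denovo", "maf", "brain", "denovo_damaging"),
  singleton_plof = c("qc", "maf", "panel", "brain", "gene_intolerance",
                     "impact"),
  singleton_missense = c("qc", "maf", "panel", "brain", "gene_intolerance",
                         "impact"))

.VERDICT_FILTERS <- c("qc", "denovo", "maf", "panel", "brain",
                      "gene_intolerance", "impact", "denovo_damaging")

.outcome <- function(x) ifelse(is.na(x), "na", ifelse(x, "pass", "fail"))

#' Run the full prioritization cascade
#'
#' Routes every variant carried by each proband according to the study
#' design: trio probands go through the de novo route (QC, de novo status,
#' allele frequency, brain expression, damaging-and-intolerant evaluation);
#' singleton probands go through the pLoF or missense route by consequence
#' class (QC, allele frequency, parental panel, brain expression, gene
#' intolerance, impact). Synonymous and unclassifiable consequences receive a
#' not-applicable verdict and never survive. All filters are conjunctive, so
#' the survivor set does not depend on application order.
#'
#' @param cohort a [VariantCohort-class].
#' @param config a [FilterConfig-class].
#' @return data.frame with one row per (proband, carried variant): the
#'   variant key and gene, the route, one column per filter with values
#'   `"pass"`, `"fail"` or `"na"`, a `flags` column (e.g.
#'   `predictors_unavailable`), and the conjunction `survived`.
#' @examples
#' b <- generateCohort(cohortConfig(nTrios = 2, nSingletons = 2,
#'                                  variantsPerProband = 20, seed = 11))
#' vd <- runCascade(b$cohort)
#' table(vd$route, vd$survived)
#' @export
runCascade <- function(cohort, config = filterConfig()) {
  v <- cohort@variants
  ped <- cohort@pedigree
  key <- variantKeys(cohort)
  maf <- mafFilter(v, config)
  brain <- brainExpressionFilter(v)
  plofGene <- plofGeneFilter(v, config)
  misGene <- missenseGeneFilter(v, config)
  plofImp <- plofImpactFilter(v, config)
  misImp <- missenseImpactFilter(v, config)
  dnv <- evaluateDenovo(v, config)
  panelAll <- suppressWarnings(parentalPanelFilter(cohort))

  res <- list()
  for (r in seq_len(nrow(ped))) {
    pb <- ped$proband[r]
    carried <- which(cohort@gt[, pb] %in% c("het", "hom_alt"))
    if (!length(carried)) next
    qc <- qcPass(cohort, pb, config)[carried]
    if (ped$design[r] == "trio" && config@applyReadQcToParents)
      qc <- qc & qcPass(cohort, ped$father[r], config)[carried] &
        qcPass(cohort, ped$mother[r], config)[carried]
    cls <- v$consequence[carried]
    flags <- rep("", length(carried))
    out <- data.frame(proband = pb, key = key[carried],
                      gene = v$gene[carried], consequence = cls,
                      stringsAsFactors = FALSE)
    for (f in .VERDICT_FILTERS) out[[f]] <- "na"
    if (ped$design[r] == "trio") {
      out$route <- "trio_denovo"
      dn <- isDenovo(cohort, pb, ped$father[r], ped$mother[r], config)[carried]
      applicable <- cls %in% c(.PLOF, .MISSENSE_LIKE)
      out$qc <- .outcome(ifelse(applicable, qc, NA))
      out$denovo <- .outcome(ifelse(applicable, dn, NA))
      out$maf <- .outcome(ifelse(applicable, maf[carried], NA))
      out$brain <- .outcome(ifelse(applicable, brain[carried], NA))
      out$denovo_damaging <- .outcome(ifelse(applicable, dnv[carried], NA))
      out$survived <- applicable & .naFalse(qc) & .naFalse(dn) &
        maf[carried] & brain[carried] & .naFalse(dnv[carried])
      flags[!applicable] <- "route_not_applicable"
      flags[applicable & is.na(dn)] <- "genotype_missing"
    } else {
      isPlof <- cls %in% .PLOF
      isMis <- cls %in% .MISSENSE_LIKE
      out$route <- ifelse(isPlof, "singleton_plof",
                          ifelse(isMis, "singleton_missense", "none"))
      applicable <- isPlof | isMis
      gene <- ifelse(isPlof, plofGene[carried], misGene[carried])
      imp <- ifelse(isPlof, plofImp[carried], misImp[carried])
      out$qc <- .outcome(ifelse(applicable, qc, NA))
      out$maf <- .outcome(ifelse(applicable, maf[carried], NA))
      out$panel <- .outcome(ifelse(applicable, panelAll[carried], NA))
      out$brain <- .outcome(ifelse(applicable, brain[carried], NA))
      out$gene_intolerance <- .outcome(ifelse(applicable, gene, NA))
      out$impact <- .outcome(ifelse(applicable, imp, NA))
      ## an NA impact verdict (no predictors available) is non-blocking
      impOk <- ifelse(is.na(imp), TRUE, imp)
      out$survived <- applicable & .naFalse(qc) & maf[carried] &
        panelAll[carried] & brain[carried] & .naFalse(gene) & impOk
      flags[!applicable] <- "route_not_applicable"
      flags[applicable & isMis & is.na(imp)] <- "predictors_unavailable"
    }
    out$flags <- flags
    res[[length(res) + 1L]] <- out
  }
  if (!length(res)) {
    out <- data.frame(proband = character(), key = character(),
                      gene = character(), consequence = character(),
                      stringsAsFactors = FALSE)
    for (f in .VERDICT_FILTERS) out[[f]] <- character()
    out$route <- character(); out$survived <- logical()
    out$flags <- character()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("proband", "key", "gene", "consequence", "route",
          .VERDICT_FILTERS, "flags", "survived")]
}
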