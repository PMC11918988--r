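## Fixture replay and end-to-end orchestration.

#' Load the packaged singleton/trio variant-table fixtures as a cohort
#'
#' The package ships transcriptions of the study's three result tables (five
#' singleton pLoF variants, eighteen singleton missense-class variants, six
#' trio de novo variants) as TSV fixtures, together with a curated
#' gene-evidence table and the 23-proband pedigree. Fields the cascade needs
#' but the tables do not print (REF/ALT allele strings, the second database
#' frequency, distance to transcript end, protein-domain and splice-site
#' annotations, read depths) are synthetic augmentations chosen to be
#' consistent with the printed dispositions; genotypes are reconstructed as
#' heterozygous in the carrier proband (with homozygous-reference,
#' zero-alt-read parents for the trio rows).
#'
#' @return list with `cohort` ([VariantCohort-class]), `evidence`,
#'   `contexts` (inheritance/ClinVar context per variant), and `printed`
#'   (the transcribed classification cell per variant).
#' @export
studyCohortFixture <- function() {
  path <- function(f) system.file("extdata", f, package = "VariantCascade",
                                  mustWork = TRUE)
  rd <- function(f) read.delim(path(f), stringsAsFactors = FALSE,
                               na.strings = c("NA", "."),
                               colClasses = c(proband = "character",
                                              chrom = "character"))
  t1 <- rd("table_plof_singletons.tsv")
  t2 <- rd("table_missense_singletons.tsv")
  t3 <- rd("table_denovo_trios.tsv")
  tab <- rbind(cbind(t1, table = "plof"), cbind(t2, table = "missense"),
               cbind(t3, table = "denovo"))
  ann <- tab[, c("chrom", "pos", "ref", "alt", .ANNOTATION_COLS)]
  ann$filter_status <- "pass"
  ann <- .coerceAnnotation(ann)

  ped <- readPedigree(path("pedigree.tsv"))
  parents <- na.omit(c(ped$father, ped$mother))
  samples <- c(ped$proband, parents)
  n <- nrow(ann)
  gt <- matrix("hom_ref", n, length(samples),
               dimnames = list(NULL, samples))
  adRef <- matrix(30L, n, length(samples), dimnames = list(NULL, samples))
  adAlt <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  for (i in seq_len(n)) {
    pb <- tab$proband[i]
    gt[i, pb] <- "het"
    adRef[i, pb] <- 25L; adAlt[i, pb] <- 23L
  }
  cohort <- makeVariantCohort(ann, gt, adRef, adAlt, ped)
  key <- variantKeys(cohort)
  list(cohort = cohort,
       evidence = readGeneEvidence(path("gene_evidence.tsv")),
       contexts = data.frame(key = key, inheritance = tab$inheritance,
                             clinvar = tab$clinvar,
                             clinvar_alt = tab$clinvar_alt,
                             stringsAsFactors = FALSE),
       printed = data.frame(key = key, proband = tab$proband,
                            gene = tab$gene, table = tab$table,
                            printed = tab$printed_classification,
                            stringsAsFactors = FALSE))
}

#' Replay the packaged variant tables through the full pipeline
#'
#' Runs the prioritization cascade and the five-tier classifier over the
#' fixture cohort and compares, row by row, the computed classification cell
#' with the transcribed one, along with the headline counts: five singleton
#' pLoF survivors, eighteen singleton missense survivors (the regional-
#' tolerance waiver is on by default here, which is what retains the one
#' missense row whose regional score is unavailable), one damaging de novo
#' variant out of six, and a 13\% diagnostic yield over 23 probands.
#'
#' @param config a [FilterConfig-class]; defaults to the study thresholds
#'   with `toleranceNaBlocks = FALSE`.
#' @return list with `rows` (key, gene, printed vs computed cell, match),
#'   `counts` (named numeric vector), `yieldPct` and `ok` (all rows match
#'   and all headline counts are reproduced).
#' @examples
#' rep <- replayStudyFixtures()
#' rep$counts; rep$ok
#' @export
replayStudyFixtures <- function(config = filterConfig(
                                  toleranceNaBlocks = FALSE)) {
  fx <- studyCohortFixture()
  vd <- runCascade(fx$cohort, config)
  tiers <- classifyCohort(vd, fx$cohort, fx$evidence, fx$contexts, config)

  rows <- fx$printed
  m <- match(rows$key, tiers$key)
  rows$computed <- tiers$cell[m]
  ## de novo variants that reach the damaging evaluation but are predicted
  ## tolerated / in tolerant regions were reported as VUS
  dn <- match(rows$key, vd$key)
  notDamaging <- !is.na(dn) & vd$route[dn] == "trio_denovo" &
    vd$qc[dn] == "pass" & vd$denovo[dn] == "pass" & vd$maf[dn] == "pass" &
    vd$brain[dn] == "pass" & vd$denovo_damaging[dn] == "fail"
  rows$computed[is.na(rows$computed) & notDamaging] <- "VUS"
  rows$match <- !is.na(rows$computed) & rows$computed == rows$printed

  report <- cohortReport(tiers, pedigree(fx$cohort))
  counts <- c(
    plof_survivors = sum(vd$route == "singleton_plof" & vd$survived),
    missense_survivors = sum(vd$route == "singleton_missense" &
                               vd$survived),
    denovo_variants = sum(vd$route == "trio_denovo" & vd$denovo == "pass" &
                            vd$maf == "pass" & vd$brain == "pass"),
    denovo_damaging = sum(vd$route == "trio_denovo" & vd$survived),
    likely_pathogenic_missense = sum(tiers$tier == "likely_pathogenic" &
                                       tiers$route == "singleton_missense"),
    pathogenic = sum(tiers$tier == "pathogenic"))
  expected <- c(plof_survivors = 5, missense_survivors = 18,
                denovo_variants = 6, denovo_damaging = 1,
                likely_pathogenic_missense = 2, pathogenic = 1)
  list(rows = rows, counts = counts, yieldPct = report$yieldPct,
       verdicts = vd, tiers = tiers,
       ok = all(rows$match) && all(counts == expected) &&
         report$yieldPct == 13)
}

#' Run the complete synthetic pipeline
#'
#' Generates a cohort bundle, runs the prioritization cascade, the SV
#' consensus per trio proband, the classifier and the recovery summary, and
#' assembles a run manifest of per-stage record counts. With `outputDir`
#' set, every stage's table is written to TSV (and the cohort to
#' VCF/TSV/pedigree).
#'
#' @param config a [CohortConfig-class].
#' @param filter a [FilterConfig-class].
#' @param outputDir optional directory for stage outputs.
#' @return list with `bundle`, `verdicts`, `tiers`, `svCandidates`,
#'   `recovery`, `report` and `manifest` (data.frame of stage counts plus
#'   the seed).
#' @examples
#' res <- runPipeline(cohortConfig(nTrios = 2, nSingletons = 2,
#'                                 variantsPerProband = 25, seed = 5))
#' res$manifest
#' @export
runPipeline <- function(config = cohortConfig(), filter = filterConfig(),
                        outputDir = NULL) {
  bundle <- generateCohort(config)
  verdicts <- runCascade(bundle$cohort, filter)
  tiers <- classifyCohort(verdicts, bundle$cohort, bundle$geneEvidence,
                          bundle$contexts, filter)
  ped <- pedigree(bundle$cohort)
  svc <- list()
  for (r in which(ped$design == "trio")) {
    pb <- ped$proband[r]
    calls <- bundle$svCalls[bundle$svCalls$sample == pb, , drop = FALSE]
    if (!nrow(calls)) next
    par <- bundle$svParental[bundle$svParental$sample %in%
                               c(ped$father[r], ped$mother[r]), ,
                             drop = FALSE]
    svc[[pb]] <- svConsensus(calls, par, bundle$exons, filter)
  }
  svCandidates <- if (length(svc)) do.call(rbind, svc) else
    data.frame()
  recovery <- recoverTruth(bundle, verdicts, tiers)
  report <- cohortReport(tiers, ped)
  manifest <- data.frame(
    stage = c("seed", "probands", "variants", "carried_verdicts",
              "survivors", "classified", "sv_calls", "sv_candidates",
              "solved_probands"),
    count = c(config@seed, nrow(ped), nrow(variantTable(bundle$cohort)),
              nrow(verdicts), sum(verdicts$survived), nrow(tiers),
              nrow(bundle$svCalls), nrow(svCandidates), report$solved))
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeCohortBundle(bundle, outputDir)
    wt <- function(x, f) write.table(x, file.path(outputDir, f),
                                     sep = "\t", quote = FALSE,
                                     row.names = FALSE, na = "NA")
    wt(verdicts, "verdicts.tsv")
    wt(tiers, "tiers.tsv")
    if (nrow(svCandidates)) wt(svCandidates, "sv_candidates.tsv")
    wt(report$perProband, "per_proband.tsv")
    wt(manifest, "manifest.tsv")
  }
  list(bundle = bundle, verdicts = verdicts, tiers = tiers,
       svCandidates = svCandidates, recovery = recovery, report = report,
       manifest = manifest)
}
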