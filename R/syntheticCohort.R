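## Seeded generator of trio/singleton cohorts with planted variants. The
## defaults mirror the study conditions: 10 trios + 13 singletons, mean
## sequencing depth 33, roughly one de novo coding candidate per proband.
## Background annotation is drawn from tolerant-gene / benign-score ranges,
## so background variants cannot survive the cascade by construction; planted
## variants satisfy or violate each filter clause per template.

#' @importFrom stats rbinom rnbinom rpois runif na.omit setNames
NULL

.PLANT_TEMPLATES <- c("pathogenic_plof", "likely_pathogenic_missense",
                      "vus_plof", "vus_missense", "benign_common",
                      "nmd_escape_plof", "denovo_damaging",
                      "inherited_unaffected")

#' Default planted-variant specification
#'
#' One plant per template: a pathogenic NMD-triggering truncation, a
#' likely-pathogenic clustered missense change, surviving pLoF/missense
#' variants in unestablished genes, a common benign variant (filtered out),
#' an NMD-escaping truncation, a damaging de novo stop-gain in a trio, and a
#' truncation inherited from an unaffected parent.
#'
#' @param trioProbands,singletonProbands sample ids to plant into.
#' @return data.frame with columns `template`, `proband`,
#'   `expected_survival`, `expected_tier`.
#' @export
defaultPlants <- function(trioProbands = sprintf("T%02d", 1:10),
                          singletonProbands = sprintf("S%02d", 1:13)) {
  data.frame(
    template = .PLANT_TEMPLATES,
    proband = c(singletonProbands[1:6], trioProbands[1],
                singletonProbands[7]),
    expected_survival = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    expected_tier = c("pathogenic", "likely_pathogenic", "vus", "vus", NA,
                      "vus", "vus", "vus"),
    stringsAsFactors = FALSE)
}

#' Build a synthetic-cohort configuration
#'
#' @param nTrios,nSingletons number of trio / singleton probands.
#' @param variantsPerProband background variants carried per proband.
#' @param denovoRate expected background de novo events per trio proband.
#' @param afWeights named mixture weights over allele-frequency classes
#'   `common` (1--30\%), `low` (ceiling--1\%), `rare` (below the ceiling) and
#'   `absent` (never observed).
#' @param depthMean,depthDispersion negative-binomial read-depth model
#'   (mean 33, matching the study's average depth).
#' @param plants planted-variant table (see [defaultPlants()]); probands
#'   referenced must exist under the chosen design sizes.
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @return A validated [CohortConfig-class].
#' @export
cohortConfig <- function(nTrios = 10L, nSingletons = 13L,
                         variantsPerProband = 150L, denovoRate = 1.2,
                         afWeights = c(common = 0.40, low = 0.30,
                                       rare = 0.20, absent = 0.10),
                         depthMean = 33, depthDispersion = 8,
                         plants = NULL, seed = 1L) {
  trioP <- sprintf("T%02d", seq_len(nTrios))
  singP <- sprintf("S%02d", seq_len(nSingletons))
  if (is.null(plants)) {
    plants <- defaultPlants(trioP, singP)
    plants <- plants[plants$proband %in% c(trioP, singP), , drop = FALSE]
  }
  bad <- setdiff(plants$proband, c(trioP, singP))
  if (length(bad))
    stop("plants reference unknown probands: ", paste(bad, collapse = ", "))
  if (!all(plants$template %in% .PLANT_TEMPLATES))
    stop("unknown plant template")
  new("CohortConfig", nTrios = as.integer(nTrios),
      nSingletons = as.integer(nSingletons),
      variantsPerProband = as.integer(variantsPerProband),
      denovoRate = denovoRate, afWeights = afWeights,
      depthMean = depthMean, depthDispersion = depthDispersion,
      plants = plants, seed = as.integer(seed))
}

.emptyAnnotation <- function(n) {
  data.frame(chrom = character(n), pos = integer(n), ref = character(n),
             alt = character(n), gene = character(n),
             transcript = character(n), consequence = character(n),
             cdna_change = NA_character_, protein_change = NA_character_,
             gnomad_af = NA_real_, kaviar_af = NA_real_, pli = NA_real_,
             mis_z = NA_real_, local_tolerance = "unavailable",
             sift = "unavailable", polyphen = "unavailable",
             revel = NA_real_, gerp = NA_real_, brain_expressed = TRUE,
             in_segdup = FALSE, dist_to_transcript_end = NA_integer_,
             affects_protein_domain = FALSE, splice_site_class = "not_splice",
             protein_position = NA_integer_, filter_status = "pass",
             stringsAsFactors = FALSE)
}

## Template-conditional annotation for one planted variant. Values are fixed
## (not sampled): a plant deterministically satisfies or violates each clause.
.plantAnnotation <- function(template) {
  a <- .emptyAnnotation(1L)
  a$gnomad_af <- 0; a$kaviar_af <- 0
  a$brain_expressed <- TRUE
  set <- function(...) { v <- list(...); for (n in names(v)) a[[n]] <<- v[[n]]; }
  switch(template,
    pathogenic_plof = set(consequence = "frameshift", pli = 0.99,
      dist_to_transcript_end = 600L, affects_protein_domain = TRUE,
      protein_position = 400L),
    likely_pathogenic_missense = set(consequence = "missense", pli = 0.95,
      mis_z = 3.6, local_tolerance = "intolerant", sift = "D",
      polyphen = "D", revel = 0.9, gerp = 5.2, protein_position = 150L),
    vus_plof = set(consequence = "stop_gain", pli = 0.97,
      dist_to_transcript_end = 800L, protein_position = 210L),
    vus_missense = set(consequence = "missense", pli = 0.5, mis_z = 3.1,
      local_tolerance = "intolerant", sift = "D", polyphen = "D",
      revel = 0.8, gerp = 4.5, protein_position = 95L),
    benign_common = set(consequence = "missense", gnomad_af = 0.05,
      kaviar_af = 0.04, pli = 0.95, mis_z = 3.2,
      local_tolerance = "intolerant", sift = "D", polyphen = "D",
      revel = 0.8, gerp = 4.8, protein_position = 60L),
    nmd_escape_plof = set(consequence = "frameshift", pli = 0.95,
      dist_to_transcript_end = 20L, affects_protein_domain = TRUE,
      protein_position = 500L),
    denovo_damaging = set(consequence = "stop_gain", pli = 1.0,
      dist_to_transcript_end = 500L, protein_position = 275L),
    inherited_unaffected = set(consequence = "frameshift", pli = 0.98,
      dist_to_transcript_end = 700L, protein_position = 320L),
    stop("unknown template: ", template))
  a
}

.plantEvidence <- function(template, gene) {
  est <- template %in% c("pathogenic_plof", "likely_pathogenic_missense",
                         "nmd_escape_plof", "inherited_unaffected")
  data.frame(gene = gene, established_ndd_gene = est,
             lof_mechanism = est && template != "likely_pathogenic_missense",
             missense_mechanism = template == "likely_pathogenic_missense",
             causal_clusters = if (template == "likely_pathogenic_missense")
               "120-180" else "",
             domain_critical = FALSE,
             phenotype_similarity = if (est) "overlapping" else "unknown",
             notes = paste0("synthetic plant: ", template),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort bundle
#'
#' Produces, deterministically from the seed, a complete in-memory cohort:
#' genotypes obeying Mendelian transmission (background de novo events are
#' Poisson per trio proband), allele depths from a negative-binomial model,
#' a background annotation table drawn from tolerant-gene/benign-score
#' ranges, planted variants per the configured templates, dual-caller SV
#' call sets with breakpoint jitter, an exon table, gene evidence and
#' variant contexts for the plants, and a ground-truth manifest.
#'
#' @param config a [CohortConfig-class].
#' @return list with elements `cohort` ([VariantCohort-class]), `truth`,
#'   `geneEvidence`, `contexts`, `svCalls`, `svParental`, `exons` and
#'   `config`.
#' @seealso [writeCohortBundle()], [recoverTruth()]
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(is(config, "CohortConfig"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(config@seed)

  trioP <- sprintf("T%02d", seq_len(config@nTrios))
  singP <- sprintf("S%02d", seq_len(config@nSingletons))
  fathers <- sprintf("%s_F", trioP); mothers <- sprintf("%s_M", trioP)
  samples <- c(trioP, fathers, mothers, singP)
  ped <- data.frame(
    proband = c(trioP, singP),
    father = c(fathers, rep(NA_character_, length(singP))),
    mother = c(mothers, rep(NA_character_, length(singP))),
    design = c(rep("trio", length(trioP)), rep("singleton", length(singP))),
    stringsAsFactors = FALSE)

  probands <- c(trioP, singP)
  nBg <- config@variantsPerProband * length(probands)
  nDn <- if (config@nTrios > 0)
    rpois(config@nTrios, config@denovoRate) else integer()
  plants <- config@plants
  nAll <- nBg + sum(nDn) + nrow(plants)

  ## unique keys by construction: global position counter
  chrom <- as.character(sample(1:22, nAll, replace = TRUE))
  pos <- 100000L + seq_len(nAll) * 151L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nAll, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")

  ann <- .emptyAnnotation(nAll)
  ann$chrom <- chrom; ann$pos <- pos; ann$ref <- ref; ann$alt <- unname(alt)
  ann$gene <- sprintf("BG%05d", seq_len(nAll))
  ann$transcript <- sprintf("NM_%06d", seq_len(nAll))

  owner <- character(nAll)       # proband carrying the variant
  origin <- character(nAll)      # transmitted / denovo / plant template

  ## --- background transmitted variants
  iBg <- seq_len(nBg)
  owner[iBg] <- rep(probands, each = config@variantsPerProband)
  origin[iBg] <- "transmitted"
  afClass <- sample(names(config@afWeights), nBg, replace = TRUE,
                    prob = config@afWeights)
  ceiling <- signif(maxCredibleAF(derivePrevalence(0.036, 0.82), 0.02, 0.9),
                    2L)
  af <- numeric(nBg)
  af[afClass == "common"] <- runif(sum(afClass == "common"), 0.01, 0.30)
  af[afClass == "low"] <- runif(sum(afClass == "low"), ceiling, 0.01)
  af[afClass == "rare"] <- runif(sum(afClass == "rare"), 1e-6,
                                 ceiling * 0.999)
  ann$gnomad_af[iBg] <- af
  ann$kaviar_af[iBg] <- af * runif(nBg, 0.5, 1)
  cons <- sample(c("missense", "synonymous", "other", "stop_gain",
                   "frameshift"), nBg, replace = TRUE,
                 prob = c(0.45, 0.30, 0.10, 0.075, 0.075))
  ann$consequence[iBg] <- cons
  ann$pli[iBg] <- runif(nBg, 0, 0.85)
  ann$mis_z[iBg] <- runif(nBg, -2, 2)
  ann$local_tolerance[iBg] <- sample(.TOLERANCE_TOLERANT, nBg, replace = TRUE)
  ann$sift[iBg] <- sample(c("T", "D"), nBg, replace = TRUE, c(0.8, 0.2))
  ann$polyphen[iBg] <- sample(c("T", "D", "P"), nBg, replace = TRUE,
                              c(0.8, 0.1, 0.1))
  ann$revel[iBg] <- runif(nBg, 0, 0.45)
  ann$gerp[iBg] <- runif(nBg, -2, 6)
  ann$brain_expressed[iBg] <- runif(nBg) < 0.85
  ann$in_segdup[iBg] <- runif(nBg) < 0.03
  ann$protein_position[iBg] <- sample(1:500, nBg, replace = TRUE)
  tr <- iBg[cons %in% c("stop_gain", "frameshift")]
  ann$dist_to_transcript_end[tr] <- sample(0:3000, length(tr),
                                           replace = TRUE)

  ## --- background de novo events (same benign annotation ranges)
  iDn <- integer()
  if (sum(nDn) > 0) {
    iDn <- nBg + seq_len(sum(nDn))
    owner[iDn] <- rep(trioP, nDn)
    origin[iDn] <- "denovo_background"
    ann$gnomad_af[iDn] <- 0; ann$kaviar_af[iDn] <- 0
    ann$consequence[iDn] <- "missense"
    ann$pli[iDn] <- runif(length(iDn), 0, 0.85)
    ann$mis_z[iDn] <- runif(length(iDn), -2, 2)
    ann$local_tolerance[iDn] <- sample(.TOLERANCE_TOLERANT, length(iDn),
                                       replace = TRUE)
    ann$sift[iDn] <- "T"; ann$polyphen[iDn] <- "T"
    ann$revel[iDn] <- runif(length(iDn), 0, 0.2)
    ann$gerp[iDn] <- runif(length(iDn), -2, 6)
    ann$protein_position[iDn] <- sample(1:500, length(iDn), replace = TRUE)
  }

  ## --- planted variants
  iPl <- nBg + sum(nDn) + seq_len(nrow(plants))
  evid <- list(); ctx <- list()
  for (k in seq_len(nrow(plants))) {
    i <- iPl[k]
    tpl <- plants$template[k]
    pa <- .plantAnnotation(tpl)
    gene <- paste0("PLANT_", toupper(tpl))
    for (col in setdiff(colnames(pa), c("chrom", "pos", "ref", "alt",
                                        "gene", "transcript")))
      ann[[col]][i] <- pa[[col]]
    ann$gene[i] <- gene
    owner[i] <- plants$proband[k]
    origin[i] <- tpl
    evid[[k]] <- .plantEvidence(tpl, gene)
    ctx[[k]] <- data.frame(
      key = .keyOf(ann$chrom[i], ann$pos[i], ann$ref[i], ann$alt[i]),
      inheritance = switch(tpl, denovo_damaging = "de_novo",
                           inherited_unaffected = "inherited_unaffected_parent",
                           "unknown"),
      clinvar = "absent", clinvar_alt = NA_character_,
      stringsAsFactors = FALSE)
  }
  geneEvidence <- unique(do.call(rbind, evid))
  contexts <- do.call(rbind, ctx)
  if (is.null(contexts))
    contexts <- data.frame(key = character(), inheritance = character(),
                           clinvar = character(), clinvar_alt = character())

  ## --- genotypes and depths
  nS <- length(samples)
  dp <- matrix(rnbinom(nAll * nS, mu = config@depthMean,
                       size = config@depthDispersion) + 1L,
               nrow = nAll, dimnames = list(NULL, samples))
  gt <- matrix("hom_ref", nAll, nS, dimnames = list(NULL, samples))
  adAlt <- matrix(0L, nAll, nS, dimnames = list(NULL, samples))
  fatherOf <- setNames(ped$father, ped$proband)
  motherOf <- setNames(ped$mother, ped$proband)
  for (i in seq_len(nAll)) {
    pb <- owner[i]
    gt[i, pb] <- "het"
    if (origin[i] == "transmitted" && !is.na(fatherOf[pb])) {
      carrier <- if (runif(1) < 0.5) fatherOf[pb] else motherOf[pb]
      gt[i, carrier] <- "het"
    }
  }
  het <- gt == "het"
  adAlt[het] <- rbinom(sum(het), dp[het], 0.5)
  adRef <- dp - adAlt
  ## planted genotypes get fixed, QC-proof depths
  for (i in iPl) {
    adRef[i, owner[i]] <- 25L; adAlt[i, owner[i]] <- 23L
    pb <- owner[i]
    if (!is.na(fatherOf[pb]) && origin[i] == "denovo_damaging") {
      adAlt[i, c(fatherOf[pb], motherOf[pb])] <- 0L
      adRef[i, c(fatherOf[pb], motherOf[pb])] <- 30L
    }
  }
  ## background de novos: parents carry zero alt reads
  for (i in iDn) {
    pb <- owner[i]
    adAlt[i, c(fatherOf[pb], motherOf[pb])] <- 0L
  }

  variants <- S4Vectors::DataFrame(ann)
  cohort <- makeVariantCohort(variants, gt, adRef, adAlt, ped)

  truth <- data.frame(
    key = variantKeys(cohort)[iPl],
    template = plants$template, proband = plants$proband,
    expected_survival = plants$expected_survival,
    expected_tier = plants$expected_tier, stringsAsFactors = FALSE)

  sv <- .generateSv(trioP, fathers, mothers)

  list(cohort = cohort, truth = truth, geneEvidence = geneEvidence,
       contexts = contexts, svCalls = sv$calls, svParental = sv$parental,
       exons = sv$exons,
       origin = data.frame(key = variantKeys(cohort), owner = owner,
                           origin = origin, stringsAsFactors = FALSE),
       config = config)
}

## Dual-caller SV call sets with breakpoint jitter. Each trio proband gets
## one inherited and one de novo deletion; both callers see every true event
## through independent uniform breakpoint noise. Exons are placed away from
## the simulated events, mirroring a cohort in which no consensus SV hits an
## intolerant exon.
.generateSv <- function(trioP, fathers, mothers, jitter = 2000L) {
  calls <- list(); parental <- list()
  for (k in seq_along(trioP)) {
    for (type in c("inherited", "denovo")) {
      start <- 1000000L + as.integer(runif(1, 0, 500000))
      size <- as.integer(runif(1, 5000, 50000))
      chrom <- as.character(sample(1:22, 1L))
      jit <- function() as.integer(runif(2, -jitter, jitter))
      jA <- jit(); jB <- jit()
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chrom,
        start = c(start + jA[1L], start + jB[1L]),
        end = c(start + size + jA[2L], start + size + jB[2L]),
        sv_type = "deletion", caller = c("pair_based", "depth_based"),
        sample = trioP[k], stringsAsFactors = FALSE)
      if (type == "inherited") {
        jP <- jit()
        parental[[length(parental) + 1L]] <- data.frame(
          chrom = chrom, start = start + jP[1L], end = start + size + jP[2L],
          sv_type = "deletion", caller = "pair_based",
          sample = if (runif(1) < 0.5) fathers[k] else mothers[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    .checkSvCalls(data.frame(chrom = character(), start = integer(),
                             end = integer(), sv_type = character(),
                             caller = character(), sample = character()))
  parental <- if (length(parental)) do.call(rbind, parental) else
    calls[integer(), ]
  exons <- data.frame(
    chrom = as.character(sample(1:22, 30L, replace = TRUE)),
    start = 3000000L + seq_len(30L) * 10000L,
    gene = sprintf("EXG%03d", seq_len(30L)),
    pli = runif(30L), stringsAsFactors = FALSE)
  exons$end <- exons$start + 200L
  exons <- exons[, c("chrom", "start", "end", "gene", "pli")]
  list(calls = calls, parental = parental, exons = exons)
}

#' Write a generated bundle to files
#'
#' Serializes every component of a [generateCohort()] bundle in the formats
#' the loaders expect: VCF + annotation TSV + pedigree TSV for the cohort,
#' and TSVs for SV calls, parental SV calls, exons, gene evidence, variant
#' contexts and the truth manifest. Identical configurations produce
#' identical files.
#'
#' @param bundle output of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
writeCohortBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  writeCohort(bundle$cohort, p("cohort.vcf"), p("annotation.tsv"),
              p("pedigree.tsv"))
  wt <- function(x, f) write.table(x, p(f), sep = "\t", quote = FALSE,
                                   row.names = FALSE, na = "NA")
  wt(bundle$svCalls, "sv_calls.tsv")
  wt(bundle$svParental, "sv_parental.tsv")
  wt(bundle$exons, "exons.tsv")
  wt(bundle$geneEvidence, "gene_evidence.tsv")
  wt(bundle$contexts, "contexts.tsv")
  wt(bundle$truth, "truth.tsv")
  out <- c(vcf = p("cohort.vcf"), annotation = p("annotation.tsv"),
           pedigree = p("pedigree.tsv"), sv_calls = p("sv_calls.tsv"),
           sv_parental = p("sv_parental.tsv"), exons = p("exons.tsv"),
           gene_evidence = p("gene_evidence.tsv"),
           contexts = p("contexts.tsv"), truth = p("truth.tsv"))
  invisible(out)
}

#' Compare pipeline output against the planted truth
#'
#' Joins cascade verdicts and assigned tiers to the truth manifest and
#' summarizes recovery: survival sensitivity (planted expected survivors
#' recovered), survival specificity (planted non-survivors correctly
#' excluded) and tier accuracy among recovered survivors.
#'
#' @param bundle output of [generateCohort()].
#' @param verdicts output of [runCascade()] on the bundle's cohort.
#' @param tiers output of [classifyCohort()], or `NULL` to skip tier
#'   accuracy.
#' @return list with `perPlant` (truth table with observed columns),
#'   `sensitivity`, `specificity` and `tierAccuracy`.
#' @export
recoverTruth <- function(bundle, verdicts, tiers = NULL) {
  truth <- bundle$truth
  sv <- verdicts[verdicts$survived, , drop = FALSE]
  hit <- paste(sv$proband, sv$key) ; want <- paste(truth$proband, truth$key)
  if (!all(truth$key %in% verdicts$key))
    stop("truth manifest key absent from verdicts: ",
         truth$key[!truth$key %in% verdicts$key][1L])
  truth$observed_survival <- want %in% hit
  truth$observed_tier <- NA_character_
  if (!is.null(tiers) && nrow(tiers)) {
    m <- match(truth$key, tiers$key)
    truth$observed_tier <- tiers$tier[m]
  }
  pos <- truth$expected_survival
  sens <- if (any(pos)) mean(truth$observed_survival[pos]) else NA_real_
  spec <- if (any(!pos)) mean(!truth$observed_survival[!pos]) else NA_real_
  tierOk <- !is.na(truth$expected_tier) & truth$observed_survival
  acc <- if (any(tierOk))
    mean(truth$observed_tier[tierOk] == truth$expected_tier[tierOk],
         na.rm = FALSE) else NA_real_
  list(perPlant = truth, sensitivity = sens, specificity = spec,
       tierAccuracy = acc)
}
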