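cfg <- filterConfig()

test_that("allele-frequency filter compares the stricter database maximum", {
  expect_true(mafFilter(annRow(gnomad_af = 2.2e-5), cfg))
  expect_true(mafFilter(annRow(gnomad_af = 0, kaviar_af = 0), cfg))
  expect_false(mafFilter(annRow(gnomad_af = 3.22001e-4), cfg))
  expect_false(mafFilter(annRow(gnomad_af = 0, kaviar_af = 0.01), cfg))
  # absent frequencies count as zero
  expect_true(mafFilter(annRow(gnomad_af = NA, kaviar_af = NA), cfg))
  # strict inequality at the ceiling itself
  expect_false(mafFilter(annRow(gnomad_af = cfg@mafCeiling), cfg))
})

test_that("pLoF gene filter requires pLI strictly above threshold", {
  expect_true(plofGeneFilter(annRow(consequence = "stop_gain", pli = 0.95),
                             cfg))
  expect_false(plofGeneFilter(annRow(consequence = "stop_gain", pli = 0.90),
                              cfg))
  expect_false(plofGeneFilter(annRow(consequence = "frameshift",
                                     pli = NA), cfg))
  expect_true(is.na(plofGeneFilter(annRow(consequence = "missense",
                                          pli = 1), cfg)))
})

test_that("missense gene filter combines constraint with regional tolerance", {
  # constrained via pLI despite low missense Z
  expect_true(missenseGeneFilter(
    annRow(mis_z = 1.14, pli = 1.00, local_tolerance = "intolerant"), cfg))
  # constrained via missense Z despite low pLI
  expect_true(missenseGeneFilter(
    annRow(mis_z = 3.01, pli = 0.62, local_tolerance = "highly_intolerant"),
    cfg))
  expect_false(missenseGeneFilter(
    annRow(mis_z = 2.0, pli = 0.5, local_tolerance = "intolerant"), cfg))
  expect_true(missenseGeneFilter(
    annRow(mis_z = 3.0, pli = 0.95,
           local_tolerance = "slightly_intolerant"), cfg))
  expect_false(missenseGeneFilter(
    annRow(mis_z = 3.0, pli = 0.95, local_tolerance = "neutral"), cfg))
  # unavailable regional score blocks by default, waived by the switch
  naRow <- annRow(mis_z = 1.53, pli = 1.00, local_tolerance = "unavailable")
  expect_false(missenseGeneFilter(naRow, cfg))
  expect_true(missenseGeneFilter(naRow,
                                 filterConfig(toleranceNaBlocks = FALSE)))
  expect_true(is.na(missenseGeneFilter(annRow(consequence = "stop_gain"),
                                       cfg)))
})

test_that("pLoF impact filter applies splice-site and transcript-end rules", {
  fs <- function(dist, domain) annRow(consequence = "frameshift",
                                      dist_to_transcript_end = dist,
                                      affects_protein_domain = domain)
  expect_false(plofImpactFilter(fs(30L, FALSE), cfg))
  expect_true(plofImpactFilter(fs(30L, TRUE), cfg))
  expect_true(plofImpactFilter(fs(51L, FALSE), cfg))
  expect_false(plofImpactFilter(fs(50L, FALSE), cfg))  # strict boundary
  expect_true(plofImpactFilter(
    annRow(consequence = "splice", splice_site_class = "main_donor_acceptor"),
    cfg))
  expect_false(plofImpactFilter(
    annRow(consequence = "splice", splice_site_class = "other"), cfg))
  expect_error(plofImpactFilter(fs(NA_integer_, FALSE), cfg), "missing")
})

test_that("missense impact filter needs GERP, REVEL and a damaging call", {
  hit <- annRow(gerp = 5.6, revel = 0.86, sift = "D", polyphen = "D")
  expect_true(missenseImpactFilter(hit, cfg))
  expect_true(missenseImpactFilter(
    annRow(gerp = 5.7, revel = 0.95, sift = "D", polyphen = "D"), cfg))
  expect_true(missenseImpactFilter(
    annRow(gerp = 2.91, revel = 0.669, sift = "T", polyphen = "P"), cfg))
  expect_false(missenseImpactFilter(transform(hit, revel = 0.3), cfg))
  expect_false(missenseImpactFilter(transform(hit, gerp = 1.9), cfg))
  expect_false(missenseImpactFilter(
    transform(hit, sift = "T", polyphen = "T"), cfg))
  # a single absent predictor fails its clause ...
  expect_false(missenseImpactFilter(transform(hit, revel = NA_real_), cfg))
  # ... but all three absent makes the filter not applicable
  expect_true(is.na(missenseImpactFilter(
    annRow(gerp = 4.7, sift = "unavailable", polyphen = "unavailable",
           revel = NA_real_), cfg)))
})

test_that("de novo detection requires hom-ref parents with zero alt reads", {
  ann <- annRow()
  co <- trioCohort(ann, "het", "hom_ref", "hom_ref")
  expect_true(isDenovo(co, "P1", "F1", "M1", cfg))
  co2 <- trioCohort(ann, "het", "het", "hom_ref")
  expect_false(isDenovo(co2, "P1", "F1", "M1", cfg))
  # hom-ref father with residual alt reads blocks the call by default
  co3 <- trioCohort(ann, "het", "hom_ref", "hom_ref", adF = c(28L, 2L))
  expect_false(isDenovo(co3, "P1", "F1", "M1", cfg))
  expect_true(isDenovo(co3, "P1", "F1", "M1",
                       filterConfig(requireZeroParentAltReads = FALSE)))
  co4 <- trioCohort(ann, "het", "missing", "hom_ref")
  expect_true(is.na(isDenovo(co4, "P1", "F1", "M1", cfg)))
})

test_that("planted de novo events are recovered exactly from a large trio", {
  set.seed(91)
  n <- 10000L; nDn <- 5L
  ann <- do.call(rbind, lapply(seq_len(n + nDn), function(i)
    annRow(pos = 1000L + i * 7L)))
  samples <- c("P1", "F1", "M1")
  gt <- matrix("hom_ref", n + nDn, 3, dimnames = list(NULL, samples))
  adAlt <- matrix(0L, n + nDn, 3, dimnames = list(NULL, samples))
  adRef <- matrix(30L, n + nDn, 3, dimnames = list(NULL, samples))
  gt[, "P1"] <- "het"; adAlt[, "P1"] <- 15L
  carrier <- sample(c("F1", "M1"), n, replace = TRUE)
  for (i in seq_len(n)) {   # transmitted: one carrier parent
    gt[i, carrier[i]] <- "het"; adAlt[i, carrier[i]] <- 14L
  }
  ped <- data.frame(proband = "P1", father = "F1", mother = "M1",
                    design = "trio")
  co <- makeVariantCohort(ann, gt, adRef, adAlt, ped)
  dn <- isDenovo(co, "P1", "F1", "M1", cfg)
  expect_identical(which(dn), seq.int(n + 1L, n + nDn))
})

test_that("parental panel filter equals the brute-force any-carrier check", {
  set.seed(14)
  nPanel <- 20L; nVar <- 60L
  samples <- c("S01", paste0("PAR", seq_len(nPanel)))
  ann <- do.call(rbind, lapply(seq_len(nVar), function(i)
    annRow(pos = 500L + i * 3L)))
  gt <- matrix(sample(c("hom_ref", "het", "hom_alt"), nVar * (nPanel + 1),
                      replace = TRUE, prob = c(0.9, 0.08, 0.02)),
               nVar, nPanel + 1, dimnames = list(NULL, samples))
  ad0 <- matrix(20L, nVar, nPanel + 1, dimnames = list(NULL, samples))
  ped <- data.frame(proband = "S01", father = NA_character_,
                    mother = NA_character_, design = "singleton")
  co <- makeVariantCohort(ann, gt, ad0, ad0, ped)
  got <- parentalPanelFilter(co, panel = samples[-1])
  oracle <- vapply(seq_len(nVar), function(i)
    !any(gt[i, -1] %in% c("het", "hom_alt")), TRUE)
  expect_identical(got, oracle)
  # presence in a single panel parent excludes
  gt2 <- gt; gt2[, -1] <- "hom_ref"; gt2[1, 2] <- "het"
  co2 <- makeVariantCohort(ann, gt2, ad0, ad0, ped)
  expect_false(parentalPanelFilter(co2, panel = samples[-1])[1])
  expect_warning(res <- parentalPanelFilter(co2, panel = character()),
                 "empty")
  expect_true(all(res))
})

test_that("de novo evaluation reproduces the tolerated/intolerant rule", {
  # stop-gain in a pLoF-intolerant gene is damaging
  expect_true(evaluateDenovo(annRow(consequence = "stop_gain", pli = 1.00),
                             cfg))
  expect_false(evaluateDenovo(annRow(consequence = "stop_gain", pli = 0.5),
                              cfg))
  # benign SIFT/PolyPhen calls make a missense variant tolerated
  expect_false(evaluateDenovo(
    annRow(sift = "T", polyphen = "T", revel = 0.77, mis_z = 1.6,
           local_tolerance = "intolerant"), cfg))
  # damaging calls but a missense-tolerant gene region
  expect_false(evaluateDenovo(
    annRow(sift = "D", polyphen = "P", revel = 0.44, mis_z = 1.1,
           local_tolerance = "slightly_tolerant"), cfg))
  # low REVEL alone marks the protein effect tolerated
  expect_false(evaluateDenovo(
    annRow(sift = "D", polyphen = "D", revel = 0.17, mis_z = 0.9,
           local_tolerance = "slightly_tolerant"), cfg))
  # damaging predictions in an intolerant region survive
  expect_true(evaluateDenovo(
    annRow(sift = "D", polyphen = "D", revel = 0.6, mis_z = 3.5,
           local_tolerance = "intolerant"), cfg))
})

test_that("cascade equals the brute-force conjunction oracle", {
  for (seed in c(2, 17)) {
    b <- generateCohort(cohortConfig(nTrios = 3, nSingletons = 3,
                                     variantsPerProband = 60, seed = seed))
    vd <- runCascade(b$cohort, cfg)
    got <- sort(paste(vd$proband[vd$survived], vd$key[vd$survived]))
    expect_identical(got, oracleSurvivorKeys(b$cohort, cfg))
  }
})

test_that("tightening any threshold never adds a survivor", {
  b <- generateCohort(cohortConfig(nTrios = 3, nSingletons = 4,
                                   variantsPerProband = 80, seed = 27))
  base <- runCascade(b$cohort, cfg)
  baseKeys <- paste(base$proband[base$survived], base$key[base$survived])
  stricter <- list(
    filterConfig(mafCeiling = cfg@mafCeiling / 10),
    filterConfig(pliMin = 0.99),
    filterConfig(misZMin = 3.5),
    filterConfig(gerpMin = 4),
    filterConfig(revelMin = 0.85),
    filterConfig(minReadsPerAllele = 10))
  for (s in stricter) {
    vd <- runCascade(b$cohort, s)
    expect_true(all(paste(vd$proband[vd$survived],
                          vd$key[vd$survived]) %in% baseKeys))
  }
})

test_that("routes are exclusive and verdicts audit every filter", {
  b <- generateCohort(cohortConfig(nTrios = 2, nSingletons = 2,
                                   variantsPerProband = 40, seed = 3))
  vd <- runCascade(b$cohort, cfg)
  ped <- pedigree(b$cohort)
  trioPb <- ped$proband[ped$design == "trio"]
  expect_true(all(vd$route[vd$proband %in% trioPb] == "trio_denovo"))
  expect_false(any(vd$route[!vd$proband %in% trioPb] == "trio_denovo"))
  # survived implies every applicable filter passed
  surv <- vd[vd$survived, ]
  filterCols <- c("qc", "denovo", "maf", "panel", "brain",
                  "gene_intolerance", "impact", "denovo_damaging")
  expect_false(any(surv[, filterCols] == "fail"))
})
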