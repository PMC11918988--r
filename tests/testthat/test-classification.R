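cfg <- filterConfig()

test_that("NMD prediction applies the strict end-of-transcript window", {
  fs <- function(d) annRow(consequence = "frameshift",
                           dist_to_transcript_end = d)
  expect_true(nmdPredicted(fs(1182L), cfg))
  expect_false(nmdPredicted(fs(10L), cfg))
  expect_false(nmdPredicted(fs(50L), cfg))  # boundary: within the window
  expect_true(is.na(nmdPredicted(annRow(consequence = "missense"), cfg)))
})

test_that("causal-cluster membership uses inclusive interval bounds", {
  expect_true(inCausalCluster(230, "173-284"))
  expect_false(inCausalCluster(540, "450-484"))
  expect_true(inCausalCluster(450, "450-484"))
  expect_true(inCausalCluster(484, "450-484"))
  expect_true(inCausalCluster(75, "10-20;70-85"))
  expect_false(inCausalCluster(75, ""))
  expect_false(inCausalCluster(NA, "10-20"))
})

# Minimal single-variant classification harness: builds a one-proband
# singleton cohort, runs the cascade, classifies the survivor.
classifyOneVariant <- function(ann, evidence, inheritance = "unknown",
                               clinvar = "absent",
                               clinvar_alt = NA_character_, config = cfg) {
  one <- function(x) matrix(x, nrow(ann), 1, dimnames = list(NULL, "P1"))
  ped <- data.frame(proband = "P1", father = NA_character_,
                    mother = NA_character_, design = "singleton",
                    stringsAsFactors = FALSE)
  co <- makeVariantCohort(ann, one("het"), one(25L), one(23L), ped)
  vd <- runCascade(co, config)
  stopifnot(all(vd$survived))
  ctx <- data.frame(key = vd$key, inheritance = inheritance,
                    clinvar = clinvar, clinvar_alt = clinvar_alt,
                    stringsAsFactors = FALSE)
  classifyCohort(vd, co, evidence, ctx, config)
}

ev <- function(gene = "G1", established = FALSE, lof = FALSE,
               missense = FALSE, clusters = "", domainCritical = FALSE,
               phenotype = "unknown")
  data.frame(gene = gene, established_ndd_gene = established,
             lof_mechanism = lof, missense_mechanism = missense,
             causal_clusters = clusters, domain_critical = domainCritical,
             phenotype_similarity = phenotype, notes = "",
             stringsAsFactors = FALSE)

nmdLof <- annRow(consequence = "frameshift", pli = 0.99,
                 dist_to_transcript_end = 900L, protein_position = 400L)
clusterMissense <- annRow(pli = 0.95, mis_z = 3.8,
                          local_tolerance = "intolerant", sift = "D",
                          polyphen = "D", revel = 0.86, gerp = 5.6,
                          protein_position = 230L)

test_that("NMD-triggering truncations in established LoF genes are pathogenic", {
  t <- classifyOneVariant(nmdLof, ev(established = TRUE, lof = TRUE,
                                     phenotype = "overlapping"),
                          inheritance = "inherited_affected_parent")
  expect_equal(t$tier, "pathogenic")
  expect_match(t$rationale, "R2")
  # inheritance from an unaffected parent demotes to VUS
  t2 <- classifyOneVariant(nmdLof, ev(established = TRUE, lof = TRUE,
                                      phenotype = "overlapping"),
                           inheritance = "inherited_unaffected_parent")
  expect_equal(t2$tier, "vus")
  expect_match(t2$rationale, "inherited-unaffected")
  # NMD escape blocks the pathogenic rule
  esc <- transform(nmdLof, dist_to_transcript_end = 20L,
                   affects_protein_domain = TRUE)
  t3 <- classifyOneVariant(esc, ev(established = TRUE, lof = TRUE,
                                   phenotype = "overlapping"))
  expect_equal(t3$tier, "vus")
  expect_match(t3$rationale, "nmd-escape")
})

test_that("novel clustered high-impact missense variants are likely pathogenic", {
  evRow <- ev(established = TRUE, missense = TRUE, clusters = "173-284",
              phenotype = "overlapping")
  t <- classifyOneVariant(clusterMissense, evRow)
  expect_equal(t$tier, "likely_pathogenic")
  # outside the cluster: VUS
  t2 <- classifyOneVariant(transform(clusterMissense,
                                     protein_position = 540L), evRow)
  expect_equal(t2$tier, "vus")
  expect_match(t2$rationale, "outside-causal-cluster")
  # non-novel population frequency blocks the rule
  t3 <- classifyOneVariant(transform(clusterMissense, gnomad_af = 7.1e-6),
                           evRow)
  expect_equal(t3$tier, "vus")
  # dissimilar gene-disease phenotype blocks it
  t4 <- classifyOneVariant(clusterMissense,
                           ev(established = TRUE, missense = TRUE,
                              clusters = "173-284",
                              phenotype = "dissimilar"))
  expect_equal(t4$tier, "vus")
  expect_match(t4$rationale, "dissimilar")
})

test_that("ClinVar verdicts override and dual cells are formatted", {
  evRow <- ev(established = TRUE, missense = TRUE)
  lb <- classifyOneVariant(clusterMissense, evRow, clinvar = "likely_benign")
  expect_equal(lb$tier, "likely_benign")
  expect_equal(lb$cell, "Likely benign")
  cfl <- classifyOneVariant(clusterMissense, evRow, clinvar = "conflicting",
                            clinvar_alt = "likely_pathogenic")
  expect_equal(cfl$tier, "vus")
  expect_equal(cfl$cell, "Likely pathogenic/VUS")
  cfb <- classifyOneVariant(clusterMissense, evRow, clinvar = "conflicting",
                            clinvar_alt = "likely_benign")
  expect_equal(cfb$cell, "VUS/likely benign")
})

test_that("genes without an evidence row classify as VUS with a code", {
  t <- classifyOneVariant(clusterMissense,
                          ev(gene = "OTHER", established = TRUE,
                             missense = TRUE, clusters = "173-284"))
  expect_equal(t$tier, "vus")
  expect_match(t$rationale, "no-evidence")
})

test_that("a competing likely-pathogenic finding demotes co-occurring variants", {
  fx <- studyCohortFixture()
  config <- filterConfig(toleranceNaBlocks = FALSE)
  vd <- runCascade(fx$cohort, config)
  tiers <- classifyCohort(vd, fx$cohort, fx$evidence, fx$contexts, config)
  tcerg1 <- tiers[tiers$gene == "TCERG1", ]
  expect_equal(tcerg1$tier, "vus")
  expect_match(tcerg1$rationale, "competing")
  # its proband also carries the likely pathogenic SPTBN1 missense variant
  expect_equal(tiers$tier[tiers$gene == "SPTBN1"], "likely_pathogenic")
  expect_equal(unique(tiers$proband[tiers$gene %in% c("TCERG1", "SPTBN1")]),
               "04")
})

test_that("withdrawing gene-level evidence never raises a tier", {
  rank <- c(pathogenic = 1, likely_pathogenic = 2, vus = 3,
            likely_benign = 4, benign = 5)
  cases <- list(
    list(ann = nmdLof, ev = ev(established = TRUE, lof = TRUE,
                               phenotype = "overlapping")),
    list(ann = clusterMissense, ev = ev(established = TRUE, missense = TRUE,
                                        clusters = "173-284",
                                        phenotype = "overlapping")),
    list(ann = clusterMissense, ev = ev(established = TRUE, missense = TRUE,
                                        phenotype = "dissimilar")))
  for (cs in cases) {
    withEv <- classifyOneVariant(cs$ann, cs$ev)
    noEv <- classifyOneVariant(cs$ann,
                               transform(cs$ev,
                                         established_ndd_gene = FALSE))
    expect_gte(rank[noEv$tier], rank[withEv$tier])
  }
})

test_that("classification is total over the evidence/context enumeration", {
  grid <- expand.grid(
    established = c(TRUE, FALSE), lof = c(TRUE, FALSE),
    missense = c(TRUE, FALSE),
    phenotype = c("overlapping", "dissimilar", "unknown"),
    inheritance = c("de_novo", "inherited_affected_parent",
                    "inherited_unaffected_parent", "unknown"),
    clinvar = c("conflicting", "likely_benign", "benign", "absent"),
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    t <- classifyOneVariant(clusterMissense,
                            ev(established = g$established, lof = g$lof,
                               missense = g$missense, clusters = "173-284",
                               phenotype = g$phenotype),
                            inheritance = g$inheritance,
                            clinvar = g$clinvar)
    expect_length(t$tier, 1)
    expect_true(t$tier %in% c("pathogenic", "likely_pathogenic", "vus",
                              "likely_benign", "benign"))
  }
})

test_that("cohort report computes the diagnostic yield over all probands", {
  ped <- data.frame(proband = sprintf("%02d", 1:23))
  tiers <- data.frame(proband = c("01", "04", "04", "05"),
                      gene = c("A", "B", "C", "D"),
                      tier = c("pathogenic", "vus", "likely_pathogenic",
                               "likely_pathogenic"))
  rep <- cohortReport(tiers, ped)
  expect_equal(rep$yieldPct, 13)
  expect_equal(rep$solved, 3)
  expect_equal(rep$perProband$best_tier[rep$perProband$proband == "04"],
               "likely_pathogenic")
  expect_equal(cohortReport(tiers[0, ], ped)$yieldPct, 0)
  all23 <- data.frame(proband = ped$proband, gene = "G",
                      tier = "pathogenic")
  expect_equal(cohortReport(all23, ped)$yieldPct, 100)
})
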