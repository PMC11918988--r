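# Builders for small in-code fixtures, plus independent brute-force oracles
# the implementation-level tests compare against.

# One annotation row per call; defaults describe a clean, rare, brain-expressed
# missense variant that fails the gene-intolerance clauses.
annRow <- function(chrom = "1", pos = 1000L, ref = "A", alt = "T",
                   gene = "G1", transcript = "NM_000001",
                   consequence = "missense", cdna_change = NA_character_,
                   protein_change = NA_character_, gnomad_af = 0,
                   kaviar_af = 0, pli = NA_real_, mis_z = NA_real_,
                   local_tolerance = "unavailable", sift = "unavailable",
                   polyphen = "unavailable", revel = NA_real_,
                   gerp = NA_real_, brain_expressed = TRUE,
                   in_segdup = FALSE, dist_to_transcript_end = NA_integer_,
                   affects_protein_domain = FALSE,
                   splice_site_class = "not_splice",
                   protein_position = NA_integer_,
                   filter_status = "pass") {
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             gene = gene, transcript = transcript,
             consequence = consequence, cdna_change = cdna_change,
             protein_change = protein_change, gnomad_af = gnomad_af,
             kaviar_af = kaviar_af, pli = pli, mis_z = mis_z,
             local_tolerance = local_tolerance, sift = sift,
             polyphen = polyphen, revel = revel, gerp = gerp,
             brain_expressed = brain_expressed, in_segdup = in_segdup,
             dist_to_transcript_end = as.integer(dist_to_transcript_end),
             affects_protein_domain = affects_protein_domain,
             splice_site_class = splice_site_class,
             protein_position = as.integer(protein_position),
             filter_status = filter_status, stringsAsFactors = FALSE)
}

# Cohort from an annotation table plus explicit genotype/depth matrices.
tinyCohort <- function(ann, gt, adRef, adAlt, ped) {
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(ann),
                                     dimnames = list(NULL, names(gt)))
  makeVariantCohort(ann, gt, adRef, adAlt, ped)
}

# A single-variant trio cohort with the given genotypes/depths.
trioCohort <- function(ann, gtP, gtF, gtM, adP = c(20L, 18L),
                       adF = c(30L, 0L), adM = c(30L, 0L)) {
  samples <- c("P1", "F1", "M1")
  n <- nrow(ann)
  gt <- matrix(rep(c(gtP, gtF, gtM), each = n), n,
               dimnames = list(NULL, samples))
  adRef <- matrix(rep(c(adP[1], adF[1], adM[1]), each = n), n,
                  dimnames = list(NULL, samples))
  adAlt <- matrix(rep(c(adP[2], adF[2], adM[2]), each = n), n,
                  dimnames = list(NULL, samples))
  ped <- data.frame(proband = "P1", father = "F1", mother = "M1",
                    design = "trio", stringsAsFactors = FALSE)
  makeVariantCohort(ann, gt, adRef, adAlt, ped)
}

# Independent scalar re-evaluation of the singleton/trio predicates; used as
# the brute-force oracle for runCascade on small cohorts.
oracleSurvivorKeys <- function(cohort, config) {
  v <- as.data.frame(variantTable(cohort))
  ped <- pedigree(cohort)
  gt <- genotypeMatrix(cohort)
  ad <- alleleDepths(cohort)
  panel <- intersect(stats::na.omit(c(ped$father, ped$mother)),
                     colnames(gt))
  keys <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  plof <- c("stop_gain", "frameshift", "splice")
  mis <- c("missense", "inframe_indel")
  intol <- c("highly_intolerant", "intolerant", "slightly_intolerant")
  tol <- c("neutral", "slightly_tolerant", "tolerant")
  nn <- function(x, d = FALSE) ifelse(is.na(x), d, x)
  out <- character()
  for (r in seq_len(nrow(ped))) {
    pb <- ped$proband[r]
    for (i in seq_len(nrow(v))) {
      if (!gt[i, pb] %in% c("het", "hom_alt")) next
      qc <- v$filter_status[i] == "pass" && !v$in_segdup[i] &&
        (if (gt[i, pb] == "het")
           ad$ref[i, pb] >= config@minReadsPerAllele &&
           ad$alt[i, pb] >= config@minReadsPerAllele
         else ad$alt[i, pb] >= config@minReadsPerAllele)
      maf <- max(nn(v$gnomad_af[i], 0), nn(v$kaviar_af[i], 0)) <
        config@mafCeiling
      brain <- v$brain_expressed[i]
      cls <- v$consequence[i]
      ok <- FALSE
      if (ped$design[r] == "trio") {
        if (!cls %in% c(plof, mis)) next
        f <- ped$father[r]; m <- ped$mother[r]
        dn <- gt[i, f] == "hom_ref" && gt[i, m] == "hom_ref" &&
          ad$alt[i, f] == 0 && ad$alt[i, m] == 0
        if (cls %in% plof) dmg <- nn(v$pli[i] > config@pliMin)
        else {
          tolerated <- v$sift[i] == "T" || v$polyphen[i] == "T" ||
            nn(v$revel[i] < config@denovoRevelToleratedMax)
          gtol <- nn(v$mis_z[i] < config@denovoMisZMin) &&
            v$local_tolerance[i] %in% tol
          dmg <- !tolerated && !gtol
        }
        ok <- qc && dn && maf && brain && dmg
      } else {
        if (!cls %in% c(plof, mis)) next
        pan <- length(panel) == 0 ||
          !any(gt[i, panel] %in% c("het", "hom_alt"))
        if (cls %in% plof) {
          gene <- nn(v$pli[i] > config@pliMin)
          imp <- if (cls == "splice")
            v$splice_site_class[i] == "main_donor_acceptor"
          else v$dist_to_transcript_end[i] > config@nmdEndWindowBp ||
            v$affects_protein_domain[i]
        } else {
          gene <- (nn(v$mis_z[i] > config@misZMin) ||
                     nn(v$pli[i] > config@pliMin)) &&
            (v$local_tolerance[i] %in% intol ||
               (!config@toleranceNaBlocks &&
                  v$local_tolerance[i] == "unavailable"))
          noPred <- v$sift[i] == "unavailable" &&
            v$polyphen[i] == "unavailable" && is.na(v$revel[i])
          imp <- if (cls == "inframe_indel" || noPred) TRUE
          else nn(v$gerp[i] > config@gerpMin) &&
            nn(v$revel[i] > config@revelMin) &&
            (v$sift[i] == "D" || v$polyphen[i] %in% c("D", "P"))
        }
        ok <- qc && maf && pan && brain && gene && imp
      }
      if (ok) out <- c(out, paste(pb, keys[i]))
    }
  }
  sort(out)
}

# Exhaustive enumeration + greedy selection oracle for the SV matcher.
oracleMatch <- function(a, b, maxSizeRatio = 2, maxBreakpointDist = 10000) {
  cand <- data.frame(i = integer(), j = integer(), dist = numeric())
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j] || a$sv_type[i] != b$sv_type[j]) next
    sa <- a$end[i] - a$start[i] + 1; sb <- b$end[j] - b$start[j] + 1
    if (max(sa, sb) / min(sa, sb) > maxSizeRatio) next
    ds <- abs(a$start[i] - b$start[j]); de <- abs(a$end[i] - b$end[j])
    if (ds > maxBreakpointDist || de > maxBreakpointDist) next
    cand <- rbind(cand, data.frame(i = i, j = j, dist = ds + de))
  }
  cand <- cand[order(cand$dist, a$start[cand$i], b$start[cand$j]), ]
  usedA <- logical(nrow(a)); usedB <- logical(nrow(b))
  pairs <- list()
  for (r in seq_len(nrow(cand))) {
    if (usedA[cand$i[r]] || usedB[cand$j[r]]) next
    usedA[cand$i[r]] <- TRUE; usedB[cand$j[r]] <- TRUE
    pairs[[length(pairs) + 1L]] <- c(cand$i[r], cand$j[r])
  }
  if (!length(pairs)) return(matrix(integer(), ncol = 2))
  do.call(rbind, pairs)
}
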