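#' @importFrom utils read.delim write.table
#' @importFrom VariantAnnotation readVcf writeVcf VCF VCFHeader geno geno<-
#'   meta meta<- ref alt
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment rowRanges
NULL

.keyOf <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

.GT_FROM_VCF <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
                  "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
                  "1/1" = "hom_alt", "1|1" = "hom_alt",
                  "./." = "missing", "." = "missing", ".|." = "missing")
.GT_TO_VCF <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                missing = "./.")

## Coerce an annotation data.frame read from TSV to the typed columns the
## cohort container expects; "." and "NA" already arrive as NA via na.strings.
.coerceAnnotation <- function(ann, file = "<annotation>") {
  need <- c("chrom", "pos", "ref", "alt", .ANNOTATION_COLS)
  miss <- setdiff(need, colnames(ann))
  if (length(miss))
    stop("annotation table ", file, " lacks columns: ",
         paste(miss, collapse = ", "))
  ann$chrom <- as.character(ann$chrom)
  ann$pos <- as.integer(ann$pos)
  for (col in c("ref", "alt", "gene", "transcript", "cdna_change",
                "protein_change"))
    ann[[col]] <- as.character(ann[[col]])
  for (col in c("gnomad_af", "kaviar_af", "pli", "mis_z", "revel", "gerp"))
    ann[[col]] <- as.numeric(ann[[col]])
  ann$dist_to_transcript_end <- as.integer(ann$dist_to_transcript_end)
  ann$protein_position <- as.integer(ann$protein_position)
  for (col in c("brain_expressed", "in_segdup", "affects_protein_domain"))
    ann[[col]] <- as.logical(ann[[col]])
  ann$local_tolerance[is.na(ann$local_tolerance)] <- "unavailable"
  ann$sift[is.na(ann$sift)] <- "unavailable"
  ann$polyphen[is.na(ann$polyphen)] <- "unavailable"
  chk <- function(col, levels) {
    bad <- !ann[[col]] %in% levels
    if (any(bad))
      stop("annotation table ", file, ": invalid ", col, " value '",
           ann[[col]][which(bad)[1L]], "' at row ", which(bad)[1L])
  }
  chk("consequence", .CONSEQUENCES)
  chk("local_tolerance", .TOLERANCE_LEVELS)
  chk("sift", .SIFT_LEVELS)
  chk("polyphen", .POLYPHEN_LEVELS)
  chk("splice_site_class", .SPLICE_CLASSES)
  key <- .keyOf(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key))
    stop("duplicate (chrom,pos,ref,alt) in annotation table ", file, ": ",
         key[duplicated(key)][1L])
  ann
}

#' Read a pedigree table
#'
#' Three-column TSV (`proband`, `father`, `mother`; `"."` for an absent
#' parent). The design is derived: probands with both parents present are
#' trios, the rest singletons.
#'
#' @param path path to the pedigree TSV.
#' @return data.frame with columns `proband`, `father`, `mother`, `design`.
#' @export
readPedigree <- function(path) {
  ped <- read.delim(path, stringsAsFactors = FALSE,
                    na.strings = c("NA", "."), colClasses = "character")
  if (!all(c("proband", "father", "mother") %in% colnames(ped)))
    stop("pedigree ", path, " needs columns proband, father, mother")
  if (anyDuplicated(ped$proband))
    stop("pedigree ", path, " lists a proband more than once")
  ped$design <- ifelse(!is.na(ped$father) & !is.na(ped$mother),
                       "trio", "singleton")
  ped
}

#' Construct a VariantCohort from in-memory pieces
#'
#' Lower-level constructor used by [readCohort()] and the synthetic-cohort
#' generator; validates dimensions and field domains.
#'
#' @param variants DataFrame or data.frame with the key and annotation
#'   columns (see [VariantCohort-class]).
#' @param gt character matrix (variants x samples) of genotype calls.
#' @param adRef,adAlt integer matrices of per-allele supporting reads.
#' @param pedigree data.frame as returned by [readPedigree()].
#' @return A [VariantCohort-class] object.
#' @export
makeVariantCohort <- function(variants, gt, adRef, adAlt, pedigree) {
  if (is.data.frame(variants)) variants <- DataFrame(variants)
  storage.mode(adRef) <- "integer"
  storage.mode(adAlt) <- "integer"
  if (!"design" %in% colnames(pedigree))
    pedigree$design <- ifelse(!is.na(pedigree$father) &
                                !is.na(pedigree$mother), "trio", "singleton")
  new("VariantCohort", variants = variants, gt = gt,
      adRef = adRef, adAlt = adAlt, pedigree = pedigree)
}

#' Read a cohort from VCF + annotation TSV + pedigree
#'
#' Joins VCF records (GT and AD FORMAT fields required) to annotation rows by
#' the `(chrom, pos, ref, alt)` key. VCF records without an annotation row
#' are dropped with a warning (and counted); annotation rows without a VCF
#' record are likewise reported. Every sample named in the pedigree must be
#' present in the VCF.
#'
#' @param vcfPath path to a VCF 4.x file (plain or bgzipped).
#' @param annotationPath path to the annotation TSV; required columns are the
#'   key plus the fields listed in [VariantCohort-class].
#' @param pedigreePath path to the pedigree TSV (see [readPedigree()]).
#' @param genome genome build label attached on read (default `"GRCh37"`).
#' @return A [VariantCohort-class] object.
#' @export
readCohort <- function(vcfPath, annotationPath, pedigreePath,
                       genome = "GRCh37") {
  ped <- readPedigree(pedigreePath)
  vcf <- VariantAnnotation::readVcf(vcfPath, genome = genome)
  rr <- SummarizedExperiment::rowRanges(vcf)
  altList <- VariantAnnotation::alt(vcf)
  if (any(lengths(altList) != 1L))
    stop("multi-allelic records are not supported; split before loading")
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refA <- as.character(VariantAnnotation::ref(vcf))
  altA <- as.character(unlist(altList))
  filt <- rr$FILTER
  gtRaw <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gtRaw)) stop("VCF ", vcfPath, " lacks the GT FORMAT field")
  adRaw <- VariantAnnotation::geno(vcf)$AD
  if (is.null(adRaw)) stop("VCF ", vcfPath, " lacks the AD FORMAT field")
  samples <- colnames(gtRaw)
  gt <- matrix(.GT_FROM_VCF[gtRaw], nrow = nrow(gtRaw),
               dimnames = list(NULL, samples))
  gt[is.na(gt)] <- "missing"
  if (length(dim(adRaw)) == 3L) {
    adRef <- adRaw[, , 1L, drop = TRUE]
    adAlt <- adRaw[, , 2L, drop = TRUE]
    if (is.null(dim(adRef))) {  # single record and/or single sample
      adRef <- matrix(adRef, nrow = nrow(gtRaw))
      adAlt <- matrix(adAlt, nrow = nrow(gtRaw))
    }
  } else {  # list-matrix layout: one integer pair per cell
    pick <- function(i) matrix(vapply(adRaw, function(x)
      if (length(x) >= i) as.integer(x[[i]]) else NA_integer_, 0L),
      nrow = nrow(adRaw))
    adRef <- pick(1L); adAlt <- pick(2L)
  }
  dimnames(adRef) <- dimnames(adAlt) <- list(NULL, samples)

  ann <- read.delim(annotationPath, stringsAsFactors = FALSE,
                    na.strings = c("NA", "."))
  ann <- .coerceAnnotation(ann, annotationPath)

  vcfKey <- .keyOf(chrom, pos, refA, altA)
  annKey <- .keyOf(ann$chrom, ann$pos, ann$ref, ann$alt)
  hit <- match(vcfKey, annKey)
  if (anyNA(hit))
    warning(sum(is.na(hit)), " VCF record(s) without an annotation row ",
            "dropped: ", paste(utils::head(vcfKey[is.na(hit)], 3L),
                               collapse = ", "))
  orphan <- setdiff(annKey, vcfKey)
  if (length(orphan))
    warning(length(orphan), " annotation row(s) without a VCF record ",
            "ignored")
  keep <- which(!is.na(hit))
  variants <- DataFrame(ann[hit[keep], , drop = FALSE])
  rownames(variants) <- NULL
  variants$filter_status <- ifelse(filt[keep] %in% c("PASS", "pass", "."),
                                   "pass", "fail")

  pedSamples <- stats::na.omit(unlist(ped[c("proband", "father", "mother")]))
  absent <- setdiff(pedSamples, samples)
  if (length(absent))
    stop("pedigree sample(s) absent from VCF: ",
         paste(absent, collapse = ", "))

  makeVariantCohort(variants, gt[keep, , drop = FALSE],
                    adRef[keep, , drop = FALSE],
                    adAlt[keep, , drop = FALSE], ped)
}

#' Write a cohort back to VCF + annotation TSV + pedigree TSV
#'
#' Inverse of [readCohort()]: re-reading the three files yields an equal
#' cohort. Genotypes are written as `GT` (`0/0`, `0/1`, `1/1`, `./.`) and
#' per-allele depths as `AD`.
#'
#' @param cohort a [VariantCohort-class].
#' @param vcfPath,annotationPath,pedigreePath output paths.
#' @return Invisibly, the three paths.
#' @export
writeCohort <- function(cohort, vcfPath, annotationPath, pedigreePath) {
  v <- cohort@variants
  samples <- colnames(cohort@gt)
  n <- nrow(v)
  rr <- GRanges(v$chrom, IRanges(v$pos, width = nchar(v$ref)))
  hdr <- VCFHeader(samples = samples)
  meta(hdr) <- IRanges::DataFrameList(
    fileformat = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  geno(hdr) <- DataFrame(
    Number = c("1", "R"), Type = c("String", "Integer"),
    Description = c("Genotype", "Allelic depths (ref,alt)"),
    row.names = c("GT", "AD"))
  gtOut <- matrix(.GT_TO_VCF[cohort@gt], nrow = n,
                  dimnames = list(NULL, samples))
  ad <- array(NA_integer_, dim = c(n, length(samples), 2L))
  ad[, , 1L] <- cohort@adRef
  ad[, , 2L] <- cohort@adAlt
  vcf <- VCF(rowRanges = rr,
             fixed = DataFrame(REF = DNAStringSet(v$ref),
                               ALT = Biostrings::DNAStringSetList(
                                 as.list(v$alt)),
                               QUAL = rep(NA_real_, n),
                               FILTER = ifelse(v$filter_status == "pass",
                                               "PASS", "FAIL")),
             geno = S4Vectors::SimpleList(GT = gtOut, AD = ad),
             colData = DataFrame(row.names = samples),
             exptData = list(header = hdr))
  VariantAnnotation::writeVcf(vcf, vcfPath)

  annOut <- as.data.frame(v[, c("chrom", "pos", "ref", "alt",
                                .ANNOTATION_COLS)])
  write.table(annOut, annotationPath, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  pedOut <- cohort@pedigree[, c("proband", "father", "mother")]
  pedOut[is.na(pedOut)] <- "."
  write.table(pedOut, pedigreePath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(vcf = vcfPath, annotation = annotationPath,
              pedigree = pedigreePath))
}

#' Genotype-level quality control
#'
#' A variant passes QC for a given sample when its FILTER verdict is pass,
#' it does not lie in a segmental duplication, and every allele the sample
#' carries is supported by at least `minReadsPerAllele` reads (so a
#' heterozygote with three or fewer reads on either allele fails; a
#' homozygote needs only the carried allele covered).
#'
#' @param cohort a [VariantCohort-class].
#' @param sample sample id (column of the genotype matrix).
#' @param config a [FilterConfig-class].
#' @return Logical vector over variants; an error is raised if the sample is
#'   absent, and `NA` is returned for variants whose genotype is missing.
#' @examples
#' b <- generateCohort(cohortConfig(nTrios = 1, nSingletons = 0,
#'                                  variantsPerProband = 10, seed = 3))
#' table(qcPass(b$cohort, pedigree(b$cohort)$proband[1], filterConfig()))
#' @export
qcPass <- function(cohort, sample, config = filterConfig()) {
  if (!sample %in% colnames(cohort@gt))
    stop("sample '", sample, "' absent from cohort genotypes")
  v <- cohort@variants
  gt <- cohort@gt[, sample]
  aR <- cohort@adRef[, sample]
  aA <- cohort@adAlt[, sample]
  m <- config@minReadsPerAllele
  depthOk <- rep(NA, nrow(v))
  depthOk[gt == "hom_ref"] <- aR[gt == "hom_ref"] >= m
  depthOk[gt == "hom_alt"] <- aA[gt == "hom_alt"] >= m
  depthOk[gt == "het"] <- aR[gt == "het"] >= m & aA[gt == "het"] >= m
  (v$filter_status == "pass") & !v$in_segdup & depthOk
}
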