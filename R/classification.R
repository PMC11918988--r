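## Five-tier interpretation engine. The rule table encodes the dispositions
## demonstrated in the study it reimplements, not the full published clinical
## criteria catalogue: a ClinVar override, a pathogenic rule for
## NMD-triggering truncations in established haploinsufficiency genes, a
## likely-pathogenic rule for novel, conserved, high-impact missense changes
## inside a causal cluster of an established gene, and a VUS default.

#' Read a gene-evidence table
#'
#' TSV with one row per gene: `gene`, `established_ndd_gene`,
#' `lof_mechanism`, `missense_mechanism` (logicals), `causal_clusters`
#' (semicolon-separated `start-end` amino-acid intervals, empty for none),
#' `domain_critical` (logical: no cluster defined but any domain hit counts),
#' `phenotype_similarity` (`overlapping`, `dissimilar`, `unknown`) and free
#' `notes`.
#'
#' @param path path to the TSV.
#' @return data.frame of gene evidence.
#' @export
readGeneEvidence <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  need <- c("gene", "established_ndd_gene", "lof_mechanism",
            "missense_mechanism", "causal_clusters", "domain_critical",
            "phenotype_similarity")
  miss <- setdiff(need, colnames(ev))
  if (length(miss))
    stop("gene-evidence table ", path, " lacks columns: ",
         paste(miss, collapse = ", "))
  for (col in c("established_ndd_gene", "lof_mechanism",
                "missense_mechanism", "domain_critical"))
    ev[[col]] <- as.logical(ev[[col]])
  ev$causal_clusters[is.na(ev$causal_clusters)] <- ""
  ev$phenotype_similarity[is.na(ev$phenotype_similarity)] <- "unknown"
  ev
}

.parseClusters <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) return(matrix(numeric(), ncol = 2L))
  parts <- strsplit(strsplit(spec, ";", fixed = TRUE)[[1L]], "-", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) as.numeric(p[1:2])))
}

#' Is a protein position inside a known causal cluster?
#'
#' Causal clusters are intervals of amino-acid positions where previously
#' reported pathogenic variants concentrate (for instance a calponin
#' homology or switch domain). Bounds are inclusive; an empty cluster list
#' returns `FALSE`.
#'
#' @param position amino-acid index (1-based), or `NA`.
#' @param clusters cluster specification string (`"a-b;c-d"`), or the
#'   `causal_clusters` field of a gene-evidence row.
#' @return Logical scalar.
#' @examples
#' inCausalCluster(230, "173-284")   # TRUE
#' inCausalCluster(540, "450-484")   # FALSE
#' @export
inCausalCluster <- function(position, clusters) {
  if (is.na(position)) return(FALSE)
  iv <- .parseClusters(clusters)
  if (!nrow(iv)) return(FALSE)
  any(position >= iv[, 1L] & position <= iv[, 2L])
}

#' Predicted nonsense-mediated decay
#'
#' A stop-gain or frameshift variant is predicted to trigger
#' nonsense-mediated decay of the transcript (and hence haploinsufficiency)
#' when it lies strictly more than `nmdEndWindowBp` coding base pairs from
#' the end of the transcript; truncations within the window are presumed to
#' escape.
#'
#' @inheritParams mafFilter
#' @return Logical vector, `NA` for other consequence classes.
#' @export
nmdPredicted <- function(variants, config = filterConfig()) {
  out <- rep(NA, nrow(variants))
  i <- variants$consequence %in% c("stop_gain", "frameshift")
  out[i] <- .naFalse(variants$dist_to_transcript_end[i] >
                       config@nmdEndWindowBp)
  out
}

.TIER_RANK <- stats::setNames(seq_along(.TIERS), .TIERS)

## Classify one surviving variant. `variant` is a one-row slice of the
## annotation table; `evidence` a one-row gene-evidence slice or NULL;
## `context` a list/one-row frame with inheritance, clinvar, clinvar_alt,
## competing_lp_or_p, and optionally precomputed novelty/conservation/NMD.
.classifyOne <- function(variant, evidence, context, impactPassed, config) {
  codes <- character()
  tier <- NA_character_
  clin <- context$clinvar %||% "absent"
  if (is.na(clin)) clin <- "absent"
  alt <- context$clinvar_alt %||% NA_character_

  novel <- .naFalse(ifelse(is.na(variant$gnomad_af), 0, variant$gnomad_af) == 0 &
                      ifelse(is.na(variant$kaviar_af), 0, variant$kaviar_af) == 0)
  conserved <- .naFalse(variant$gerp > config@gerpMin)
  inh <- context$inheritance %||% "unknown"
  if (is.na(inh)) inh <- "unknown"
  competing <- isTRUE(context$competing_lp_or_p)

  if (clin %in% c("benign", "likely_benign")) {
    tier <- clin
    codes <- c(codes, "R1-clinvar-override")
  } else if (clin == "conflicting") {
    tier <- "vus"
    codes <- c(codes, "R1-clinvar-conflicting")
    if (!is.na(alt)) codes <- c(codes, paste0("clinvar-alt:", alt))
  } else if (is.null(evidence) || !nrow(evidence)) {
    tier <- "vus"
    codes <- c(codes, "no-evidence")
  } else {
    plof <- variant$consequence %in% .PLOF
    mis <- variant$consequence %in% .MISSENSE_LIKE
    nmd <- isTRUE(nmdPredicted(variant, config))
    demoted <- inh == "inherited_unaffected_parent" || competing
    if (demoted)
      codes <- c(codes, if (inh == "inherited_unaffected_parent")
        "R4-inherited-unaffected" else "R4-competing-finding")
    clusterHit <- inCausalCluster(variant$protein_position,
                                  evidence$causal_clusters)
    clusterOk <- clusterHit ||
      (!nzchar(evidence$causal_clusters) && isTRUE(evidence$domain_critical) &&
         isTRUE(variant$affects_protein_domain))
    if (!demoted && plof && nmd && isTRUE(evidence$established_ndd_gene) &&
        isTRUE(evidence$lof_mechanism) &&
        evidence$phenotype_similarity != "dissimilar") {
      tier <- "pathogenic"
      codes <- c(codes, "R2-plof-haploinsufficiency")
    } else if (!demoted && mis && isTRUE(evidence$established_ndd_gene) &&
               isTRUE(evidence$missense_mechanism) && novel && conserved &&
               isTRUE(impactPassed) && clusterOk &&
               evidence$phenotype_similarity != "dissimilar") {
      tier <- "likely_pathogenic"
      codes <- c(codes, "R3-missense-cluster")
    } else {
      tier <- "vus"
      if (!isTRUE(evidence$established_ndd_gene))
        codes <- c(codes, "R4-gene-not-established")
      else {
        if (evidence$phenotype_similarity == "dissimilar")
          codes <- c(codes, "R4-dissimilar-phenotype")
        if (mis && !clusterOk)
          codes <- c(codes, "R4-outside-causal-cluster")
        if (plof && !nmd)
          codes <- c(codes, "R4-nmd-escape")
      }
      if (length(codes) == 0L) codes <- "R5-default"
    }
  }
  list(tier = tier, codes = codes, clinvar = clin, clinvar_alt = alt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Printed-cell formatting: a pathogenic-side ClinVar alternative precedes
## the engine tier, a benign-side one follows it.
.TIER_LABEL <- c(pathogenic = "Pathogenic",
                 likely_pathogenic = "Likely pathogenic", vus = "VUS",
                 likely_benign = "Likely benign", benign = "Benign")

.cellLabel <- function(tier, clinvar, clinvar_alt) {
  if (clinvar %in% c("benign", "likely_benign"))
    return(.TIER_LABEL[[tier]])
  if (clinvar == "conflicting" && !is.na(clinvar_alt)) {
    if (clinvar_alt %in% c("pathogenic", "likely_pathogenic"))
      return(paste0(.TIER_LABEL[[clinvar_alt]], "/", .TIER_LABEL[[tier]]))
    return(paste0(.TIER_LABEL[[tier]], "/",
                  tolower(.TIER_LABEL[[clinvar_alt]])))
  }
  .TIER_LABEL[[tier]]
}

#' Classify surviving variants into the five tiers
#'
#' Applies the rule table (ClinVar override; pathogenic for NMD-triggering
#' truncations in established loss-of-function genes; likely pathogenic for
#' novel, conserved, high-impact missense variants in a causal cluster of an
#' established gene; VUS otherwise) to every cascade survivor. Demotion to
#' VUS applies when the variant was inherited from an unaffected parent or
#' when the proband carries a competing likely-pathogenic/pathogenic
#' finding; the competing flag is computed automatically in a second pass.
#'
#' @param verdicts output of [runCascade()].
#' @param cohort the [VariantCohort-class] the verdicts came from.
#' @param evidence gene-evidence table (see [readGeneEvidence()]).
#' @param contexts optional data.frame keyed by `key` with columns
#'   `inheritance` (`de_novo`, `inherited_affected_parent`,
#'   `inherited_unaffected_parent`, `unknown`), `clinvar` (ClinVar status)
#'   and `clinvar_alt` (the alternative interpretation shown alongside a
#'   conflicting status). Missing rows default to unknown/absent; trio-route
#'   survivors default to `de_novo`.
#' @param config a [FilterConfig-class].
#' @return data.frame with one row per surviving variant: proband, key,
#'   gene, `tier`, `cell` (formatted label including any ClinVar-sourced
#'   alternative) and semicolon-joined `rationale` codes.
#' @export
classifyCohort <- function(verdicts, cohort, evidence, contexts = NULL,
                           config = filterConfig()) {
  surv <- verdicts[verdicts$survived, , drop = FALSE]
  v <- cohort@variants
  key <- variantKeys(cohort)
  getCtx <- function(k, route) {
    ctx <- list(inheritance = if (route == "trio_denovo") "de_novo"
                else "unknown",
                clinvar = "absent", clinvar_alt = NA_character_,
                competing_lp_or_p = FALSE)
    if (!is.null(contexts) && k %in% contexts$key) {
      row <- contexts[contexts$key == k, , drop = FALSE][1L, ]
      for (f in c("inheritance", "clinvar", "clinvar_alt"))
        if (f %in% colnames(row) && !is.na(row[[f]])) ctx[[f]] <- row[[f]]
    }
    ctx
  }
  classifyPass <- function(competingProbands) {
    res <- vector("list", nrow(surv))
    for (r in seq_len(nrow(surv))) {
      idx <- match(surv$key[r], key)
      variant <- v[idx, , drop = FALSE]
      ev <- evidence[evidence$gene == surv$gene[r], , drop = FALSE]
      ctx <- getCtx(surv$key[r], surv$route[r])
      ctx$competing_lp_or_p <- surv$proband[r] %in% competingProbands$proband &&
        !surv$key[r] %in% competingProbands$key
      impactPassed <- surv$impact[r] == "pass" ||
        (surv$route[r] == "trio_denovo" && surv$denovo_damaging[r] == "pass")
      res[[r]] <- .classifyOne(variant, if (nrow(ev)) ev[1L, , drop = FALSE]
                               else NULL, ctx, impactPassed, config)
    }
    res
  }
  first <- classifyPass(data.frame(proband = character(), key = character()))
  lp <- vapply(first, function(x)
    x$tier %in% c("pathogenic", "likely_pathogenic"), TRUE)
  competing <- data.frame(proband = surv$proband[lp], key = surv$key[lp])
  res <- classifyPass(competing)
  out <- data.frame(
    proband = surv$proband, key = surv$key, gene = surv$gene,
    route = surv$route,
    tier = vapply(res, `[[`, "", "tier"),
    cell = vapply(res, function(x)
      .cellLabel(x$tier, x$clinvar, x$clinvar_alt), ""),
    rationale = vapply(res, function(x) paste(x$codes, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-proband summary and diagnostic yield
#'
#' Reports each proband's best (most pathogenic) finding and the cohort
#' diagnostic yield: the percentage of probands carrying at least one
#' pathogenic or likely-pathogenic variant, rounded to the nearest integer.
#'
#' @param tiers output of [classifyCohort()].
#' @param ped pedigree data.frame (all probands, including those with no
#'   surviving variant).
#' @return list with `perProband` (proband, best tier or `"none"`, gene) and
#'   `yieldPct`.
#' @examples
#' ped <- data.frame(proband = sprintf("P%02d", 1:23))
#' tiers <- data.frame(proband = c("P01", "P04", "P05"),
#'                     gene = c("A", "B", "C"),
#'                     tier = c("pathogenic", rep("likely_pathogenic", 2)))
#' cohortReport(tiers, ped)$yieldPct  # 13
#' @export
cohortReport <- function(tiers, ped) {
  best <- lapply(ped$proband, function(p) {
    rows <- tiers[tiers$proband == p, , drop = FALSE]
    if (!nrow(rows))
      return(data.frame(proband = p, best_tier = "none",
                        gene = NA_character_))
    i <- which.min(.TIER_RANK[rows$tier])
    data.frame(proband = p, best_tier = rows$tier[i], gene = rows$gene[i])
  })
  best <- do.call(rbind, best)
  solved <- best$best_tier %in% c("pathogenic", "likely_pathogenic")
  list(perProband = best,
       solved = sum(solved),
       yieldPct = round(100 * sum(solved) / nrow(ped)))
}
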