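## Structural-variant consensus: calls from a read-pair caller and a
## read-depth caller are matched one-to-one, parental calls are subtracted,
## and the survivors are intersected with exons of loss-of-function
## intolerant genes.

#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

.checkSvCalls <- function(calls, what = "SV calls") {
  need <- c("chrom", "start", "end", "sv_type", "caller", "sample")
  miss <- setdiff(need, colnames(calls))
  if (length(miss))
    stop(what, " lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(calls) && any(calls$start > calls$end))
    stop(what, ": start must be <= end")
  calls
}

#' Read a BED-like SV call table
#'
#' TSV with columns `chrom`, `start`, `end` (1-based inclusive), `sv_type`
#' (`deletion`, `duplication`, `other`), `caller` (`pair_based`,
#' `depth_based`) and `sample`.
#'
#' @param path path to the TSV.
#' @return data.frame of calls.
#' @export
readSVCalls <- function(path) {
  calls <- read.delim(path, stringsAsFactors = FALSE)
  calls$start <- as.integer(calls$start)
  calls$end <- as.integer(calls$end)
  .checkSvCalls(calls, path)
}

## Candidate pairs between two call sets under the concordance criteria;
## returns a data.frame of (i, j, dist) or an empty frame.
.svCandidates <- function(a, b, maxSizeRatio, maxBreakpointDist) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  idx <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)),
                     KEEP.OUT.ATTRS = FALSE)
  sa <- a$end[idx$i] - a$start[idx$i] + 1
  sb <- b$end[idx$j] - b$start[idx$j] + 1
  ds <- abs(a$start[idx$i] - b$start[idx$j])
  de <- abs(a$end[idx$i] - b$end[idx$j])
  ok <- a$chrom[idx$i] == b$chrom[idx$j] &
    a$sv_type[idx$i] == b$sv_type[idx$j] &
    pmax(sa, sb) / pmin(sa, sb) <= maxSizeRatio &
    ds <= maxBreakpointDist & de <= maxBreakpointDist
  data.frame(i = idx$i[ok], j = idx$j[ok], dist = (ds + de)[ok])
}

#' Match calls between the two structural-variant callers
#'
#' Two calls concord when they come from the same chromosome and SV type,
#' their sizes differ by at most `maxSizeRatio`-fold (a ratio, not an
#' absolute difference), and both the start and the end breakpoints lie
#' within `maxBreakpointDist` of each other. Each call participates in at
#' most one pair; pairs are resolved greedily by smallest combined
#' breakpoint distance, ties broken by the leftmost start.
#'
#' @param callsA,callsB data.frames of calls (see [readSVCalls()]) from the
#'   same sample.
#' @param maxSizeRatio maximum fold size difference (default 2).
#' @param maxBreakpointDist maximum distance in bp between corresponding
#'   breakpoints (default 10000).
#' @return data.frame with one row per matched pair: the indices `idxA`,
#'   `idxB`, both callers' coordinates, the consensus (union) interval and
#'   the combined breakpoint distance.
#' @examples
#' a <- data.frame(chrom = "1", start = 1000L, end = 6000L,
#'                 sv_type = "deletion", caller = "pair_based", sample = "P1")
#' b <- transform(a, caller = "depth_based", start = 1200L, end = 6300L)
#' matchCalls(a, b)
#' @export
matchCalls <- function(callsA, callsB, maxSizeRatio = 2,
                       maxBreakpointDist = 10000) {
  .checkSvCalls(callsA, "callsA"); .checkSvCalls(callsB, "callsB")
  samp <- unique(c(callsA$sample, callsB$sample))
  if (length(samp) > 1L)
    stop("matchCalls expects calls from a single sample, got: ",
         paste(samp, collapse = ", "))
  cand <- .svCandidates(callsA, callsB, maxSizeRatio, maxBreakpointDist)
  cand <- cand[order(cand$dist, callsA$start[cand$i], callsB$start[cand$j]), ,
               drop = FALSE]
  usedA <- logical(nrow(callsA)); usedB <- logical(nrow(callsB))
  keep <- integer()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!usedA[i] && !usedB[j]) {
      usedA[i] <- TRUE; usedB[j] <- TRUE
      keep <- c(keep, r)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- data.frame(
    idxA = cand$i, idxB = cand$j,
    sample = if (nrow(cand)) callsA$sample[cand$i] else character(),
    chrom = callsA$chrom[cand$i], sv_type = callsA$sv_type[cand$i],
    startA = callsA$start[cand$i], endA = callsA$end[cand$i],
    startB = callsB$start[cand$j], endB = callsB$end[cand$j],
    dist = cand$dist, stringsAsFactors = FALSE)
  out$start <- pmin(out$startA, out$startB)
  out$end <- pmax(out$endA, out$endB)
  rownames(out) <- NULL
  out
}

#' Remove matched pairs present in the parents
#'
#' Drops any matched pair whose pair-based-caller member concords (same
#' criteria as [matchCalls()]) with a parental call from the pair-based
#' caller; only that caller's parental output is consulted.
#'
#' @param matched output of [matchCalls()].
#' @param parentalCalls data.frame of parental pair-based calls.
#' @param maxSizeRatio,maxBreakpointDist concordance criteria.
#' @return The matched pairs not seen in a parent.
#' @export
parentalExclusion <- function(matched, parentalCalls, maxSizeRatio = 2,
                              maxBreakpointDist = 10000) {
  if (!nrow(matched) || !nrow(parentalCalls)) return(matched)
  .checkSvCalls(parentalCalls, "parentalCalls")
  child <- data.frame(chrom = matched$chrom, start = matched$startA,
                      end = matched$endA, sv_type = matched$sv_type)
  cand <- .svCandidates(child, parentalCalls, maxSizeRatio,
                        maxBreakpointDist)
  matched[!seq_len(nrow(matched)) %in% cand$i, , drop = FALSE]
}

#' Keep consensus SVs hitting exons of intolerant genes
#'
#' Retains matched pairs whose consensus interval (union of the two callers'
#' intervals) overlaps at least one base of at least one exon of a gene with
#' pLI strictly above `pliMin`, and reports the overlapped genes.
#'
#' @param matched output of [matchCalls()] (possibly after
#'   [parentalExclusion()]).
#' @param exons data.frame with columns `chrom`, `start`, `end`, `gene`,
#'   `pli`.
#' @param pliMin pLI threshold (default 0.9, strict).
#' @return data.frame of candidate SVs with a `genes` column
#'   (comma-separated overlapped intolerant genes).
#' @export
exonOverlapFilter <- function(matched, exons, pliMin = 0.9) {
  if (!nrow(matched)) {
    matched$genes <- character(0)
    return(matched)
  }
  ex <- exons[!is.na(exons$pli) & exons$pli > pliMin, , drop = FALSE]
  if (!nrow(ex)) return(matched[integer(), , drop = FALSE])
  lev <- unique(c(matched$chrom, ex$chrom))
  gSv <- GRanges(factor(matched$chrom, lev), IRanges(matched$start,
                                                     matched$end))
  gEx <- GRanges(factor(ex$chrom, lev), IRanges(ex$start, ex$end))
  hits <- findOverlaps(gSv, gEx, minoverlap = 1L)
  if (!length(hits)) {
    out <- matched[integer(), , drop = FALSE]
    out$genes <- character(0)
    return(out)
  }
  genes <- vapply(split(ex$gene[subjectHits(hits)], queryHits(hits)),
                  function(g) paste(sort(unique(g)), collapse = ","), "")
  keep <- as.integer(names(genes))
  out <- matched[keep, , drop = FALSE]
  out$genes <- unname(genes)
  rownames(out) <- NULL
  out
}

#' Dual-caller SV consensus for one proband
#'
#' Convenience wrapper: splits a call table by caller, matches the two
#' callers' calls, removes calls concordant with parental pair-based calls,
#' and keeps consensus intervals hitting exons of intolerant genes.
#'
#' @param calls data.frame of one proband's calls from both callers.
#' @param parentalCalls data.frame of pair-based parental calls (may be
#'   empty).
#' @param exons exon table (see [exonOverlapFilter()]).
#' @param config a [FilterConfig-class] (supplies `pliMin`).
#' @param maxSizeRatio,maxBreakpointDist concordance criteria.
#' @return data.frame of candidate SVs.
#' @export
svConsensus <- function(calls, parentalCalls, exons,
                        config = filterConfig(), maxSizeRatio = 2,
                        maxBreakpointDist = 10000) {
  .checkSvCalls(calls)
  a <- calls[calls$caller == "pair_based", , drop = FALSE]
  b <- calls[calls$caller == "depth_based", , drop = FALSE]
  m <- matchCalls(a, b, maxSizeRatio, maxBreakpointDist)
  m <- parentalExclusion(m, parentalCalls, maxSizeRatio, maxBreakpointDist)
  exonOverlapFilter(m, exons, pliMin = config@pliMin)
}
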