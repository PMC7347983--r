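#' Assign peaks to the nearest TSS
#'
#' Each peak is assigned to the gene whose transcription start site lies
#' nearest its midpoint, provided the distance does not exceed
#' \code{windowBp}; ties are broken toward the lexicographically smaller
#' gene id. Distances are signed in gene orientation (negative upstream of
#' the TSS).
#'
#' @param peaks \code{GRanges} of peaks.
#' @param genes \code{GRanges} with \code{gene_id} and \code{tss} metadata.
#' @param windowBp maximum midpoint-to-TSS distance (default 100 kb).
#' @return list with \code{assigned} (data.frame: peak index, name, gene_id,
#'   distance) and \code{unassigned} (peak indices).
#' @export
assignPeaksToGenes <- function(peaks, genes, windowBp = 1e5) {
  if (windowBp <= 0) stop("windowBp must be positive")
  if (length(genes) == 0L) stop("no genes to assign to")
  mid <- floor((start(peaks) + end(peaks)) / 2)
  midGr <- GRanges(seqnames(peaks), IRanges(mid, mid))
  tssGr <- GRanges(seqnames(genes),
                   IRanges(mcols(genes)$tss, mcols(genes)$tss))
  hits <- findOverlaps(midGr, tssGr, maxgap = windowBp)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (length(qh)) {
    d <- abs(mid[qh] - mcols(genes)$tss[sh])
    gid <- mcols(genes)$gene_id[sh]
    o <- order(qh, d, gid)
    qh <- qh[o]; sh <- sh[o]; d <- d[o]; gid <- gid[o]
    keep <- !duplicated(qh)
    qh <- qh[keep]; sh <- sh[keep]; gid <- gid[keep]
    gstr <- as.character(strand(genes))[sh]
    signed <- mid[qh] - mcols(genes)$tss[sh]
    signed[gstr == "-"] <- -signed[gstr == "-"]
    assigned <- data.frame(
      peak = qh,
      peak_name = if (!is.null(mcols(peaks)$name)) mcols(peaks)$name[qh]
                  else as.character(qh),
      gene_id = gid,
      distance = signed,
      stringsAsFactors = FALSE)
  } else {
    assigned <- data.frame(peak = integer(0), peak_name = character(0),
                           gene_id = character(0), distance = numeric(0),
                           stringsAsFactors = FALSE)
  }
  list(assigned = assigned,
       unassigned = setdiff(seq_along(peaks), assigned$peak))
}

#' Two-set peak Venn partition
#'
#' A peak is shared iff it overlaps any peak of the other set by at least
#' one base pair. Because the two sets' peak widths differ, shared counts
#' are reported from each side: \code{a_only + shared_a = |A|} and
#' \code{b_only + shared_b = |B|}; the headline \code{shared} count is the
#' A-side count.
#'
#' @param a,b \code{GRanges} peak sets on the same assembly.
#' @return list with \code{counts} (a_only, shared, b_only, shared_b) and
#'   \code{regions} (the corresponding \code{GRanges} subsets).
#' @examples
#' p <- generateVennPeaks(3, 2, 1)
#' vennPartition(p$a, p$b)$counts
#' @export
vennPartition <- function(a, b) {
  sharedA <- countOverlaps(a, b, minoverlap = 1L) > 0
  sharedB <- countOverlaps(b, a, minoverlap = 1L) > 0
  list(counts = c(a_only = sum(!sharedA),
                  shared = sum(sharedA),
                  b_only = sum(!sharedB),
                  shared_b = sum(sharedB)),
       regions = list(a_only = a[!sharedA], shared = a[sharedA],
                      b_only = b[!sharedB], shared_b = b[sharedB]))
}

#' Consensus of two peak callers' outputs
#'
#' Retains caller 1's intervals (with their coordinates) iff they overlap a
#' caller 2 interval by at least one base pair.
#'
#' @param caller1,caller2 \code{GRanges} peak sets.
#' @return \code{GRanges} subset of \code{caller1}.
#' @export
consensusPeaks <- function(caller1, caller2) {
  caller1[countOverlaps(caller1, caller2, minoverlap = 1L) > 0]
}

#' Classify direct maternal Wnt target genes
#'
#' Integrates rescue-gated regulation calls at stages 8 and 9, surge
#' classification, and stage-7/stage-10 peak assignments into per-gene
#' target classes: \code{class1} (regulated at stage 8, stage-7 binding
#' only), \code{class2} (regulated at stage 9 but not class1, binding at
#' both stages), \code{direct_other} (regulated with stage-7 binding but
#' neither persistence pattern), \code{indirect} (regulated without stage-7
#' binding) and \code{not_regulated}. Stage-8-regulated genes are expected
#' to be a subset of stage-9-regulated genes; violations are returned in
#' attribute \code{"venn_violations"}.
#'
#' @param regulatedSt8,regulatedSt9 data.frames from
#'   \code{\link{callRegulatedGenes}}.
#' @param surgeCalls data.frame from \code{\link{classifySurge}} (optional;
#'   genes missing from it get surge \code{none} with a warning).
#' @param assignmentsSt7,assignmentsSt10 results of
#'   \code{\link{assignPeaksToGenes}} for the stage-7 and stage-10
#'   beta-catenin peak sets.
#' @return data.frame: gene_id, surge, bound_st7, bound_st10, regulated_st8,
#'   regulated_st9, target_class.
#' @export
classifyDirectTargets <- function(regulatedSt8, regulatedSt9, surgeCalls,
                                  assignmentsSt7, assignmentsSt10) {
  ids <- regulatedSt9$gene_id
  r8 <- regulatedSt8$regulated[match(ids, regulatedSt8$gene_id)]
  r8[is.na(r8)] <- FALSE
  r9 <- regulatedSt9$regulated
  b7 <- ids %in% assignmentsSt7$assigned$gene_id
  b10 <- ids %in% assignmentsSt10$assigned$gene_id
  surge <- surgeCalls$surge[match(ids, surgeCalls$gene_id)]
  if (anyNA(surge) && any(r8 | r9)) {
    missing <- is.na(surge) & (r8 | r9)
    if (any(missing))
      warning(sum(missing), " regulated gene(s) absent from surge calls")
  }
  surge[is.na(surge)] <- "none"
  reg <- r8 | r9
  cls <- rep("not_regulated", length(ids))
  cls[reg & !b7] <- "indirect"
  cls[reg & b7] <- "direct_other"
  cls[r8 & b7 & !b10] <- "class1"
  cls[r9 & !(r8 & b7 & !b10) & b7 & b10] <- "class2"
  out <- data.frame(gene_id = ids, surge = surge,
                    bound_st7 = b7, bound_st10 = b10,
                    regulated_st8 = r8, regulated_st9 = r9,
                    target_class = cls, stringsAsFactors = FALSE)
  attr(out, "venn_violations") <- ids[r8 & !r9]
  out
}
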