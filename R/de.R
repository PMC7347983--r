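#' Median-of-ratios library size factors
#'
#' For each sample, the median across genes of the ratio between its count
#' and the per-gene geometric mean over samples, restricted to genes with no
#' zero count. If no zero-free gene exists the function falls back to
#' total-count scaling (factors proportional to column sums, normalized to
#' geometric mean 1) with a warning.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @examples
#' k <- matrix(rpois(300, 100), 50, 6)
#' sizeFactorsMedianRatio(k)
#' @export
sizeFactorsMedianRatio <- function(counts) {
  counts <- as.matrix(counts)
  ok <- rowSums(counts == 0) == 0
  if (!any(ok)) {
    warning("no zero-free gene; falling back to total-count scaling")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  logk <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(logk)
  exp(apply(sweep(logk, 1, ref), 2, stats::median))
}

#' Per-gene negative-binomial Wald contrast
#'
#' Counts are scaled by size factors; within each contrast group the mean of
#' the normalized counts estimates the group expression. Dispersion is
#' estimated per gene by the method of moments on normalized counts, pooled
#' across the two groups, then moderated by shrinking halfway toward the
#' mean moment dispersion over all genes (information sharing across genes,
#' as is standard for small replicate numbers) and floored at 1e-8. The Wald
#' statistic for the log ratio of group means is referred to a t
#' distribution with \code{n1 + n2 - 2 + priorDf} degrees of freedom,
#' crediting the shrinkage target with \code{priorDf} effective degrees of
#' freedom. A half-count pseudo-mean regularizes the log fold change. Genes
#' with all zero counts in both groups return lfc 0, p 1.
#'
#' @param counts gene x sample count matrix.
#' @param group1,group2 column indices (or logical masks) of the two groups;
#'   the reported fold change is group2 over group1.
#' @param sizeFactors optional; computed by
#'   \code{\link{sizeFactorsMedianRatio}} on the involved columns when
#'   missing.
#' @param priorWeight weight of the across-gene mean dispersion in the
#'   shrunken estimate.
#' @param priorDf effective degrees of freedom credited to the shrinkage
#'   target.
#' @return data.frame: gene_id, lfc (log2), p.
#' @export
testContrast <- function(counts, group1, group2, sizeFactors = NULL,
                         priorWeight = 0.5, priorDf = 8) {
  counts <- as.matrix(counts)
  k1 <- counts[, group1, drop = FALSE]
  k2 <- counts[, group2, drop = FALSE]
  n1 <- ncol(k1); n2 <- ncol(k2)
  if (n1 < 2L || n2 < 2L) stop("each contrast group needs >= 2 replicates")
  if (is.null(sizeFactors)) {
    sf <- sizeFactorsMedianRatio(cbind(k1, k2))
    sf1 <- sf[seq_len(n1)]; sf2 <- sf[n1 + seq_len(n2)]
  } else {
    sf1 <- sizeFactors[group1]; sf2 <- sizeFactors[group2]
  }
  q1 <- sweep(k1, 2, sf1, "/"); q2 <- sweep(k2, 2, sf2, "/")
  m1 <- rowMeans(q1); m2 <- rowMeans(q2)
  v1 <- apply(q1, 1, stats::var); v2 <- apply(q2, 1, stats::var)
  mom <- function(m, v) ifelse(m > 0, (v - m) / m^2, 0)
  aGene <- (mom(m1, v1) + mom(m2, v2)) / 2
  prior <- mean(pmax(aGene, 0), na.rm = TRUE)
  alpha <- pmax((1 - priorWeight) * aGene + priorWeight * prior, 1e-8)
  vlog <- (1 / n1) * (1 / pmax(m1, 1e-8) + alpha) +
          (1 / n2) * (1 / pmax(m2, 1e-8) + alpha)
  w <- (log(m2 + 0.5) - log(m1 + 0.5)) / sqrt(vlog)
  p <- 2 * stats::pt(-abs(w), df = n1 + n2 - 2 + priorDf)
  lfc <- (log2(m2 + 0.5) - log2(m1 + 0.5))
  zero <- m1 == 0 & m2 == 0
  lfc[zero] <- 0; p[zero] <- 1
  data.frame(gene_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             lfc = lfc, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rescue-gated regulated-gene calls
#'
#' At one stage, tests the knockdown contrast (MO vs control) and the rescue
#' contrast (MO_rescue vs MO) gene-wise, adjusts each contrast's p-values by
#' Benjamini-Hochberg across all tested genes, and calls a gene regulated
#' iff it is significantly down in the knockdown AND significantly up in
#' the rescue (both FDR < alpha). The two-contrast AND gate mirrors the
#' knockdown-then-rescue experimental logic.
#'
#' @param experiment a \linkS4class{CountExperiment} containing conditions
#'   control, MO and MO_rescue (or the sia_-prefixed equivalents) at
#'   \code{stage}.
#' @param stage numeric stage code to test at.
#' @param alpha FDR threshold.
#' @return data.frame of per-gene calls: fold changes, p and BH q per
#'   contrast and the \code{regulated} flag.
#' @export
callRegulatedGenes <- function(experiment, stage, alpha = 0.05) {
  cd <- colData(experiment)
  cond <- sub("^sia_", "", cd$condition)
  atStage <- cd$stage == stage
  need <- c("control", "MO", "MO_rescue")
  if (!all(need %in% cond[atStage]))
    stop("missing condition at stage ", stage, ": ",
         paste(setdiff(need, cond[atStage]), collapse = ", "))
  k <- assay(experiment, "counts")
  sf <- sizeFactorsMedianRatio(k[, atStage, drop = FALSE])
  sfAll <- numeric(ncol(k)); sfAll[atStage] <- sf
  gC <- which(atStage & cond == "control")
  gM <- which(atStage & cond == "MO")
  gR <- which(atStage & cond == "MO_rescue")
  mo <- testContrast(k, gC, gM, sizeFactors = sfAll)
  re <- testContrast(k, gM, gR, sizeFactors = sfAll)
  qMO <- stats::p.adjust(mo$p, method = "BH")
  qRe <- stats::p.adjust(re$p, method = "BH")
  data.frame(gene_id = mo$gene_id,
             stage = stage,
             lfc_MO_vs_control = mo$lfc,
             lfc_rescue_vs_MO = re$lfc,
             p_MO = mo$p, p_rescue = re$p,
             q_MO = qMO, q_rescue = qRe,
             regulated = qMO < alpha & mo$lfc < 0 &
                         qRe < alpha & re$lfc > 0,
             stringsAsFactors = FALSE)
}
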