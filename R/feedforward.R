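#' Classify a regulatory triad into the feedforward-loop taxonomy
#'
#' For a triad with regulator W, intermediate A and target B, the loop is
#' coherent iff the direct sign W->B equals the product of the indirect path
#' signs (W->A times A->B). The type index follows the standard taxonomy
#' ordering on the (W->A, A->B) sign pattern: type 1 = (+,+) (all-activator
#' coherent loop), type 2 = (-,+), type 3 = (+,-), type 4 = (-,-).
#'
#' @param signWA,signWB,signAB signs of the three edges, \code{"+"} or
#'   \code{"-"}.
#' @return character label, e.g. \code{"coherent_type1"}.
#' @examples
#' fflClassify("+", "+", "+")
#' @export
fflClassify <- function(signWA, signWB, signAB) {
  sgn <- function(s) {
    if (is.na(s) || !s %in% c("+", "-")) stop("signs must be '+' or '-'")
    if (s == "+") 1L else -1L
  }
  wa <- sgn(signWA); wb <- sgn(signWB); ab <- sgn(signAB)
  coherent <- wb == wa * ab
  type <- if (wa == 1L && ab == 1L) 1L
          else if (wa == -1L && ab == 1L) 2L
          else if (wa == 1L && ab == -1L) 3L
          else 4L
  paste0(if (coherent) "coherent_type" else "incoherent_type", type)
}

#' Epistasis calls from an intermediate-factor knockdown
#'
#' Runs the same rescue-gated contrast machinery as the primary knockdown
#' analysis on a knockdown of a first-class gene product (e.g., sia):
#' first-class genes are expected unaffected at stage 8 (the knockdown acts
#' downstream of them), second-class genes reduced at stage 9 and restored
#' by rescue. A second-class gene is feedforward-consistent when it is
#' affected at stage 9, rescued, and no first-class gene in the experiment
#' is affected at stage 8. "Unaffected" means q >= alpha (absence of
#' evidence); \code{tost = TRUE} replaces it with a two-one-sided-test
#' equivalence criterion on the log2 fold change.
#'
#' @param experiment a \linkS4class{CountExperiment} with conditions
#'   control, sia_MO, sia_MO_rescue at stages 8 and 9.
#' @param classLabels data.frame with columns gene_id and target_class (or
#'   true_class), as from \code{\link{classifyDirectTargets}}.
#' @param alpha FDR threshold.
#' @param tost use a TOST equivalence test for "unaffected".
#' @param tostBound equivalence bound on |log2 fold change|.
#' @return data.frame: gene_id, class_label, affected_at_st8,
#'   affected_at_st9, rescued, ffl_consistent; attribute
#'   \code{"class1_affected_at_st8"} lists first-class violations.
#' @export
knockdownEpistasisCall <- function(experiment, classLabels, alpha = 0.05,
                                   tost = FALSE, tostBound = 1) {
  clCol <- if ("target_class" %in% colnames(classLabels)) "target_class"
           else "true_class"
  cd <- colData(experiment)
  cond <- sub("^sia_", "", cd$condition)
  for (st in c(8, 9))
    if (!all(c("control", "MO", "MO_rescue") %in% cond[cd$stage == st]))
      stop("missing condition at stage ", st)
  k <- assay(experiment, "counts")
  callsAt <- function(st) {
    atStage <- cd$stage == st
    sf <- numeric(ncol(k))
    sf[atStage] <- sizeFactorsMedianRatio(k[, atStage, drop = FALSE])
    mo <- testContrast(k, which(atStage & cond == "control"),
                       which(atStage & cond == "MO"), sizeFactors = sf)
    re <- testContrast(k, which(atStage & cond == "MO"),
                       which(atStage & cond == "MO_rescue"), sizeFactors = sf)
    list(mo = mo, re = re,
         qMO = stats::p.adjust(mo$p, "BH"),
         qRe = stats::p.adjust(re$p, "BH"))
  }
  s8 <- callsAt(8); s9 <- callsAt(9)
  ids <- s9$mo$gene_id
  cls <- classLabels[[clCol]][match(ids, classLabels$gene_id)]
  aff8 <- s8$qMO < alpha & s8$mo$lfc < 0
  aff9 <- s9$qMO < alpha & s9$mo$lfc < 0
  resc <- s9$qRe < alpha & s9$re$lfc > 0
  unaffected8 <- if (tost) abs(s8$mo$lfc) < tostBound & s8$qMO >= alpha
                 else !aff8
  class1Hit <- ids[cls == "class1" & aff8]
  noClass1Effect <- length(class1Hit) == 0L
  out <- data.frame(gene_id = ids,
                    class_label = cls,
                    affected_at_st8 = aff8,
                    affected_at_st9 = aff9,
                    rescued = resc,
                    ffl_consistent = cls == "class2" & aff9 & resc &
                      noClass1Effect,
                    stringsAsFactors = FALSE)
  attr(out, "class1_affected_at_st8") <- class1Hit
  attr(out, "class1_unaffected_at_st8") <-
    all(unaffected8[cls == "class1"], na.rm = TRUE)
  out
}
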