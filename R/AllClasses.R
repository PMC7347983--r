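#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' Position weight matrix
#'
#' A probability matrix over the DNA alphabet, one column per motif position.
#' Columns are stochastic (sum to 1); the pseudocount applied when the matrix
#' was built from counts is retained so that log-odds scanning can reproduce
#' the same regularization.
#'
#' @slot matrix 4 x width numeric matrix, rows named A, C, G, T; each column
#'   sums to 1.
#' @slot pseudocount nonnegative number added to each count cell before
#'   normalization.
#' @slot name motif identifier.
#'
#' @examples
#' pwm <- consensusPWM("CTTTGWW")
#' motifWidth(pwm)
#' @export
setClass("PWM", representation(
  matrix = "matrix",
  pseudocount = "numeric",
  name = "character"
))

setValidity("PWM", function(object) {
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != 4L)
    return("matrix must be numeric with 4 rows (A, C, G, T)")
  if (!identical(rownames(m), c("A", "C", "G", "T")))
    return("matrix rows must be named A, C, G, T in that order")
  if (ncol(m) < 1L)
    return("matrix must have at least one column")
  if (any(m < 0))
    return("probabilities must be nonnegative")
  if (any(abs(colSums(m) - 1) > 1e-9))
    return("every column must sum to 1 (tolerance 1e-9)")
  if (length(object@pseudocount) != 1L || object@pseudocount < 0)
    return("pseudocount must be a single nonnegative number")
  TRUE
})

#' @describeIn PWM display a compact consensus summary
#' @param object a \code{PWM}
#' @export
setMethod("show", "PWM", function(object) {
  cat("PWM", sQuote(object@name), "width", ncol(object@matrix),
      "consensus", pwmConsensus(object), "\n")
})

#' Knockdown/rescue count experiment
#'
#' A \linkS4class{SummarizedExperiment} holding an integer gene x sample count
#' matrix in assay \code{"counts"} with a design in \code{colData}: a
#' \code{condition} column (\code{control}, \code{MO}, \code{MO_rescue} for
#' the beta-catenin design, or \code{control}, \code{sia_MO},
#' \code{sia_MO_rescue} for the intermediate-factor epistasis design) and a
#' numeric developmental \code{stage} column.
#'
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
  if (!"counts" %in% names(assays(object)))
    return("assay 'counts' is required")
  k <- assay(object, "counts")
  if (any(k < 0) || any(k != round(k)))
    return("counts must be nonnegative integers")
  cd <- colData(object)
  if (!all(c("condition", "stage") %in% colnames(cd)))
    return("colData must contain 'condition' and 'stage'")
  if (!is.numeric(cd$stage))
    return("stage must be numeric (developmental stage code)")
  TRUE
})

#' Staged expression time courses
#'
#' A \linkS4class{SummarizedExperiment} whose single assay \code{"tpe"} holds
#' transcripts-per-embryo values, one row per gene and one column per sampled
#' developmental stage. Column data carry the numeric stage codes, strictly
#' increasing, all members of \code{\link{stageVocabulary}}.
#'
#' @export
setClass("StageSeriesSet", contains = "SummarizedExperiment")

setValidity("StageSeriesSet", function(object) {
  if (!"tpe" %in% names(assays(object)))
    return("assay 'tpe' is required")
  if (any(assay(object, "tpe") < 0))
    return("transcripts-per-embryo values must be nonnegative")
  st <- colData(object)$stage
  if (is.null(st) || !is.numeric(st))
    return("colData must contain numeric 'stage'")
  if (is.unsorted(st, strictly = TRUE))
    return("stages must be strictly increasing")
  if (!all(st %in% stageVocabulary()))
    return("all stages must belong to stageVocabulary()")
  TRUE
})

#' @describeIn StageSeriesSet compact display
#' @param object a \code{StageSeriesSet}
#' @export
setMethod("show", "StageSeriesSet", function(object) {
  st <- colData(object)$stage
  cat("StageSeriesSet with", nrow(object), "genes over stages",
      st[1L], "-", st[length(st)], sprintf("(%d points)\n", length(st)))
})

#' Constructor for CountExperiment
#'
#' @param counts integer gene x sample matrix (rownames are gene ids).
#' @param condition character/factor per-sample condition labels.
#' @param stage numeric per-sample stage codes.
#' @return a validated \linkS4class{CountExperiment}.
#' @examples
#' k <- matrix(rpois(12, 50), 2, 6,
#'             dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
#' ce <- CountExperiment(k, rep(c("control", "MO", "MO_rescue"), 2),
#'                       rep(c(8, 9), each = 3))
#' @export
CountExperiment <- function(counts, condition, stage) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    colData = DataFrame(condition = as.character(condition),
                        stage = as.numeric(stage),
                        row.names = colnames(counts)))
  new("CountExperiment", se)
}

#' Constructor for StageSeriesSet
#'
#' @param tpe numeric gene x stage matrix of transcripts per embryo.
#' @param stage numeric stage codes, one per column.
#' @return a validated \linkS4class{StageSeriesSet}.
#' @export
StageSeriesSet <- function(tpe, stage) {
  tpe <- as.matrix(tpe)
  colnames(tpe) <- as.character(stage)
  se <- SummarizedExperiment(
    assays = list(tpe = tpe),
    colData = DataFrame(stage = as.numeric(stage),
                        row.names = colnames(tpe)))
  new("StageSeriesSet", se)
}
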