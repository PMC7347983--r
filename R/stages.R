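#' Nieuwkoop-Faber stage vocabulary
#'
#' The ordered set of developmental stage codes used throughout the package:
#' cleavage/blastula stages from stage 4 through early gastrula stage 10.25.
#' Stage labels are exact decimal codes; all comparisons between stages go
#' through the index in this vocabulary, never through floating-point
#' arithmetic on derived values.
#'
#' @return numeric vector of strictly increasing stage codes.
#' @examples
#' stageVocabulary()
#' @export
stageVocabulary <- function() {
  c(4, 5, 6, 6.5, 7, 7.5, 8, 8.5, 9, 9.5, 10, 10.25)
}

#' Index of a stage code in the vocabulary
#'
#' @param stage numeric stage code(s).
#' @return integer index into \code{stageVocabulary()}; error if absent.
#' @keywords internal
stageIndex <- function(stage) {
  idx <- match(stage, stageVocabulary())
  if (anyNA(idx))
    stop("stage code(s) not in vocabulary: ",
         paste(stage[is.na(idx)], collapse = ", "))
  idx
}
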