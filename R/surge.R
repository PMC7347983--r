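#' Surge-classification thresholds
#'
#' Thresholds and stage windows for classifying staged expression profiles
#' into the two surges of zygotic target-gene expression: induction is
#' defined by crossing 20,000 transcripts per embryo; profiles qualify only
#' if maternally quiet (below 10,000 before stage 6) and strongly induced
#' (above 100,000 by stage 10). The first-surge window is the closed stage
#' interval [7, 7.5]; the second-surge window is the half-open interval
#' (8, 9.5], so an onset exactly at stage 8 falls in the gap between the
#' windows and is annotated rather than classified.
#'
#' @param expressionThreshold transcripts/embryo defining induction onset.
#' @param baselineMaxBeforeSt6 maternal-contamination ceiling before stage 6.
#' @param plateauMinBySt10 induction floor to be reached by stage 10.
#' @param firstWindow closed stage interval of the first surge.
#' @param secondWindow half-open stage interval (open left) of the second.
#' @return validated list of class \code{SurgeConfig}.
#' @export
surgeConfig <- function(expressionThreshold = 20000,
                        baselineMaxBeforeSt6 = 10000,
                        plateauMinBySt10 = 1e5,
                        firstWindow = c(7, 7.5),
                        secondWindow = c(8, 9.5)) {
  if (!(baselineMaxBeforeSt6 < expressionThreshold &&
        expressionThreshold < plateauMinBySt10))
    stop("need baselineMax < expressionThreshold < plateauMin")
  if (firstWindow[2] > secondWindow[1])
    stop("surge windows must be disjoint and ordered")
  structure(as.list(environment()), class = "SurgeConfig")
}

#' Onset stage of an expression profile
#'
#' The earliest sampled stage (in vocabulary order) at which the profile
#' reaches the threshold; the crossing is inclusive (value >= threshold
#' counts). No interpolation between sampled stages is performed: onset
#' resolution equals sampling resolution.
#'
#' @param values named numeric vector of transcripts per embryo, names are
#'   stage codes, or a single-row slice of a \linkS4class{StageSeriesSet}.
#' @param threshold positive transcripts-per-embryo threshold.
#' @return numeric stage code, or \code{NA} if the threshold is never
#'   reached.
#' @examples
#' onsetStage(c("6" = 1000, "7" = 5000, "7.5" = 60000, "8" = 2e5), 20000)
#' @export
onsetStage <- function(values, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  if (length(values) == 0L) stop("empty series")
  st <- as.numeric(names(values))
  o <- order(stageIndex(st))
  st <- st[o]; values <- values[o]
  hit <- which(values >= threshold)
  if (length(hit) == 0L) NA_real_ else st[hit[1L]]
}

#' Inclusion filter for surge classification
#'
#' @param values named numeric stage profile (names are stage codes).
#' @param config a \code{\link{surgeConfig}}.
#' @return \code{TRUE} iff the profile is below the maternal ceiling at all
#'   stages before 6 and exceeds the induction floor by stage 10.
#' @export
passesInclusion <- function(values, config = surgeConfig()) {
  st <- as.numeric(names(values))
  early <- st < 6
  late <- st >= 10
  if (!any(early))
    stop("series lacks coverage of stages before 6")
  if (!any(late))
    stop("series lacks coverage of stage 10 or later")
  upTo10 <- st <= 10
  max(values[early]) < config$baselineMaxBeforeSt6 &&
    max(values[upTo10]) > config$plateauMinBySt10
}

#' Classify genes into expression surges
#'
#' Applies the inclusion filter and onset definition to every gene of a
#' \linkS4class{StageSeriesSet} and assigns \code{first} (onset within the
#' closed first window), \code{second} (onset within the half-open second
#' window) or \code{none}. Onsets falling strictly between the windows are
#' annotated \code{"gap"} in the \code{note} column; this mirrors treating
#' boundary genes as a remark, not a third class.
#'
#' @param series a \linkS4class{StageSeriesSet}.
#' @param config a \code{\link{surgeConfig}}.
#' @return data.frame: gene_id, onset_stage, surge, passed_inclusion, note.
#' @export
classifySurge <- function(series, config = surgeConfig()) {
  tpe <- assay(series, "tpe")
  st <- colData(series)$stage
  colnames(tpe) <- as.character(st)
  vI <- function(s) if (is.na(s)) NA_integer_ else stageIndex(s)
  iF1 <- stageIndex(config$firstWindow[1]); iF2 <- stageIndex(config$firstWindow[2])
  iS1 <- stageIndex(config$secondWindow[1]); iS2 <- stageIndex(config$secondWindow[2])
  res <- lapply(seq_len(nrow(tpe)), function(i) {
    v <- tpe[i, ]
    ok <- passesInclusion(v, config)
    onset <- onsetStage(v, config$expressionThreshold)
    surge <- "none"; note <- ""
    if (ok && !is.na(onset)) {
      io <- vI(onset)
      if (io >= iF1 && io <= iF2) surge <- "first"
      else if (io > iS1 && io <= iS2) surge <- "second"
      else if (io > iF2 && io <= iS1) note <- "gap"
    }
    data.frame(gene_id = rownames(tpe)[i],
               onset_stage = onset,
               surge = surge,
               passed_inclusion = ok,
               note = note,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
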