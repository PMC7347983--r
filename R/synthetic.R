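#' Configuration of the synthetic maternal-Wnt study
#'
#' Bundles every parameter of the synthetic-study generator. Defaults encode
#' the study design this package models: ten first-class (first-surge) genes
#' against a larger second-class cohort, triplicate knockdown/rescue count
#' samples at stages 8 and 9, stage-7-only versus persistent (stage 7 and 10)
#' beta-catenin peaks, Foxh1 co-binding enriched at target loci, and TCF/LEF-
#' plus Foxh1-like motifs planted in peak sequences.
#'
#' @param nGenes total genes in the synthetic annotation.
#' @param nClass1,nClass2 numbers of first-class and second-class target
#'   genes (remaining genes are Wnt-independent).
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param geneWidth gene-body width (bp).
#' @param peakWidth ChIP peak width (bp).
#' @param placementWindow peaks are centred within this distance of the
#'   target TSS (bp).
#' @param decoyPeakCount decoy beta-catenin peaks per stage set, placed near
#'   Wnt-independent genes (widespread non-functional binding).
#' @param foxh1RateClass1,foxh1RateClass2,foxh1RateBackground probability
#'   that a target-class (or decoy) beta-catenin peak is Foxh1 co-bound.
#' @param baselineTPE,ceilingTPE baseline and plateau expression of the
#'   time-course ramps, transcripts per embryo.
#' @param class1Window,class2Window stage windows (vocabulary members) from
#'   which surge onsets are drawn per class.
#' @param dispersion negative-binomial dispersion of simulated counts.
#' @param moLog2FC planted knockdown log2 fold change (negative).
#' @param rescueEfficiency fraction of the knockdown shift restored by
#'   rescue (0-1).
#' @param nReplicates replicates per condition/stage.
#' @param libSizeRange library sizes drawn uniformly in 1 +/- this value.
#' @param baseMeanLog,baseMeanSd log-normal parameters of per-gene baseline
#'   count means.
#' @param tcfConsensus,foxh1Consensus planted consensus motifs (IUPAC).
#' @param plantRateTcf,plantRateFoxh1 per-sequence planting probabilities.
#' @param background nucleotide composition (A, C, G, T) of peak sequences.
#' @param seed master seed; every generator derives its own stream from it.
#' @return a validated list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(nGenes = 50, nClass1 = 5, nClass2 = 10)
#' @export
simConfig <- function(nGenes = 500L,
                      nClass1 = 10L,
                      nClass2 = 100L,
                      chromLengths = c(chr1 = 1e7, chr2 = 1e7,
                                       chr3 = 1e7, chr4 = 1e7),
                      geneWidth = 2000L,
                      peakWidth = 200L,
                      placementWindow = 2000L,
                      decoyPeakCount = 1000L,
                      foxh1RateClass1 = 0.8,
                      foxh1RateClass2 = 0.8,
                      foxh1RateBackground = 0.5,
                      baselineTPE = 1000,
                      ceilingTPE = 3e5,
                      class1Window = c(7, 7.5),
                      class2Window = c(8.5, 9.5),
                      dispersion = 0.05,
                      moLog2FC = -3,
                      rescueEfficiency = 0.9,
                      nReplicates = 3L,
                      libSizeRange = 0.3,
                      baseMeanLog = log(200),
                      baseMeanSd = 1,
                      tcfConsensus = "CTTTGWW",
                      foxh1Consensus = "AATCCACA",
                      plantRateTcf = 0.5,
                      plantRateFoxh1 = 0.6,
                      background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                      seed = 20200101L) {
  cfg <- as.list(environment())
  if (nClass1 + nClass2 > nGenes)
    stop("nClass1 + nClass2 must not exceed nGenes")
  if (any(c(foxh1RateClass1, foxh1RateClass2, foxh1RateBackground,
            plantRateTcf, plantRateFoxh1, rescueEfficiency) < 0) ||
      any(c(foxh1RateClass1, foxh1RateClass2, foxh1RateBackground,
            plantRateTcf, plantRateFoxh1, rescueEfficiency) > 1))
    stop("rates must lie in [0, 1]")
  if (dispersion < 0) stop("dispersion must be nonnegative")
  if (nGenes > 0 && is.null(names(chromLengths)))
    stop("chromLengths must be named")
  vocab <- stageVocabulary()
  if (!all(c(class1Window, class2Window) %in% vocab))
    stop("onset windows must be members of stageVocabulary()")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background composition must sum to 1")
  structure(cfg, class = "SimConfig")
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping gene bodies uniformly on the configured
#' chromosomes, keeping a margin of one peak-placement window at each
#' chromosome end so that every peak window fits inside its chromosome, and
#' enforcing a minimum intergenic gap of two placement windows plus one peak
#' width between neighbouring gene bodies. The gap guarantees that a peak
#' planted within the placement window of a gene's TSS is always nearest to
#' that TSS, so planted peak-to-gene links are identifiable by construction.
#' Placement uses the sorted-gap construction, which guarantees zero overlap
#' without rejection sampling.
#'
#' @param config a \code{\link{simConfig}}.
#' @param seed integer; defaults to a stream derived from the master seed.
#' @return list with \code{sizes} (a \link[GenomeInfoDb]{Seqinfo}) and
#'   \code{genes} (a \code{GRanges} as from \code{\link{readGff3}}).
#' @export
generateGenome <- function(config, seed = deriveSeed(config$seed, "genome")) {
  sizes <- chromSizes(names(config$chromLengths), config$chromLengths)
  if (config$nGenes == 0L)
    return(list(sizes = sizes, genes = GRanges()))
  set.seed(seed)
  margin <- config$placementWindow + config$peakWidth
  nchr <- length(config$chromLengths)
  perChr <- tabulate(sample.int(nchr, config$nGenes, replace = TRUE), nchr)
  chromAll <- character(0); startAll <- numeric(0)
  minGap <- 2 * config$placementWindow + config$peakWidth
  for (i in seq_len(nchr)) {
    n <- perChr[i]
    if (n == 0L) next
    pitch <- config$geneWidth + minGap
    usable <- config$chromLengths[i] - 2 * margin - n * pitch
    if (usable < 0)
      stop("cannot place ", n, " genes on ", names(config$chromLengths)[i],
           " without overlap; use larger chromosomes")
    gaps <- sort(floor(runif(n, 0, usable)))
    starts <- margin + gaps + (seq_len(n) - 1L) * pitch + 1
    chromAll <- c(chromAll, rep(names(config$chromLengths)[i], n))
    startAll <- c(startAll, starts)
  }
  str <- sample(c("+", "-"), config$nGenes, replace = TRUE)
  gr <- GRanges(chromAll,
                IRanges(start = startAll, width = config$geneWidth),
                strand = str, seqinfo = sizes)
  ids <- sprintf("gene%04d", seq_len(config$nGenes))
  mcols(gr)$gene_id <- ids
  mcols(gr)$name <- ids
  mcols(gr)$tss <- ifelse(str == "-", end(gr), start(gr))
  names(gr) <- ids
  gr <- gr[order(as.character(seqnames(gr)), start(gr))]
  list(sizes = sizes, genes = gr)
}

#' Generate the ground-truth gene class table
#'
#' Assigns each gene a true class (\code{class1}, \code{class2},
#' \code{wnt_independent}), the implied stage-7/stage-10 binding flags, a
#' Foxh1 co-binding flag drawn at the class rate, and a surge-onset stage
#' drawn uniformly from the class window.
#'
#' @inheritParams generateGenome
#' @param genes \code{GRanges} from \code{\link{generateGenome}}.
#' @return data.frame keyed by \code{gene_id}.
#' @export
generateTruthTable <- function(genes, config,
                               seed = deriveSeed(config$seed, "truth")) {
  set.seed(seed)
  ids <- mcols(genes)$gene_id
  n <- length(ids)
  cls <- rep("wnt_independent", n)
  pick <- sample.int(n, config$nClass1 + config$nClass2)
  cls[pick[seq_len(config$nClass1)]] <- "class1"
  cls[pick[config$nClass1 + seq_len(config$nClass2)]] <- "class2"
  vocab <- stageVocabulary()
  w1 <- vocab[vocab >= config$class1Window[1] & vocab <= config$class1Window[2]]
  w2 <- vocab[vocab >= config$class2Window[1] & vocab <= config$class2Window[2]]
  onset <- rep(NA_real_, n)
  onset[cls == "class1"] <- sample(w1, sum(cls == "class1"), replace = TRUE)
  onset[cls == "class2"] <- sample(w2, sum(cls == "class2"), replace = TRUE)
  fx <- runif(n) < ifelse(cls == "class1", config$foxh1RateClass1,
                   ifelse(cls == "class2", config$foxh1RateClass2, 0))
  data.frame(gene_id = ids,
             true_class = cls,
             has_st7_peak = cls %in% c("class1", "class2"),
             has_st10_peak = cls == "class2",
             foxh1_cobound = fx,
             surge_onset_stage = onset,
             stringsAsFactors = FALSE)
}

#' Generate stage-labelled peak sets
#'
#' Realizes the planted binding architecture: every first-class gene receives
#' a stage-7-only beta-catenin peak near its TSS; every second-class gene
#' receives coincident stage-7 and stage-10 peaks; decoy beta-catenin peaks
#' are placed near Wnt-independent genes at both stages; Foxh1 stage-7 peaks
#' are co-placed on beta-catenin peaks according to the truth table's
#' co-binding flags and, for decoys, the background co-binding rate.
#'
#' @inheritParams generateTruthTable
#' @param truth data.frame from \code{\link{generateTruthTable}}.
#' @return named list of \code{GRanges}: \code{beta_catenin_st7},
#'   \code{beta_catenin_st10}, \code{foxh1_st7}.
#' @export
generatePeaks <- function(genes, truth, config,
                          seed = deriveSeed(config$seed, "peaks")) {
  set.seed(seed)
  sizes <- seqlengths(genes)
  half <- floor(config$peakWidth / 2)
  placeNear <- function(tssChrom, tssPos) {
    centre <- tssPos + round(runif(length(tssPos), -config$placementWindow,
                                   config$placementWindow))
    s <- centre - half
    e <- s + config$peakWidth - 1
    if (length(s) && any(s < 1 | e > sizes[tssChrom]))
      stop("peak placement window exceeds chromosome bounds")
    GRanges(tssChrom, IRanges(s, e), seqinfo = seqinfo(genes))
  }
  tssOf <- function(ids) {
    i <- match(ids, mcols(genes)$gene_id)
    list(chrom = as.character(seqnames(genes))[i], pos = mcols(genes)$tss[i])
  }
  c1 <- truth$gene_id[truth$true_class == "class1"]
  c2 <- truth$gene_id[truth$true_class == "class2"]
  indep <- truth$gene_id[truth$true_class == "wnt_independent"]

  t1 <- tssOf(c1); t2 <- tssOf(c2)
  g1 <- if (length(c1)) placeNear(t1$chrom, t1$pos) else GRanges(seqinfo = seqinfo(genes))
  g2 <- if (length(c2)) placeNear(t2$chrom, t2$pos) else GRanges(seqinfo = seqinfo(genes))

  decoyAt <- function(n) {
    if (n == 0L || length(indep) == 0L)
      return(GRanges(seqinfo = seqinfo(genes)))
    host <- sample(indep, n, replace = TRUE)
    th <- tssOf(host)
    placeNear(th$chrom, th$pos)
  }
  d7 <- decoyAt(config$decoyPeakCount)
  d10 <- decoyAt(config$decoyPeakCount)

  pfx <- function(prefix, ids) if (length(ids)) paste0(prefix, ids)
                               else character(0)
  st7 <- c(g1, g2, d7)
  mcols(st7)$name <- c(pfx("bcat7_", c(c1, c2)),
                       sprintf("bcat7_decoy%04d", seq_along(d7)))
  st10 <- c(g2, d10)
  mcols(st10)$name <- c(pfx("bcat10_", c2),
                        sprintf("bcat10_decoy%04d", seq_along(d10)))

  cobound <- truth$foxh1_cobound[match(c(c1, c2), truth$gene_id)]
  fxTarget <- st7[seq_len(length(c1) + length(c2))][cobound]
  fxDecoy <- d7[runif(length(d7)) < config$foxh1RateBackground]
  fx <- c(fxTarget, fxDecoy)
  # jitter Foxh1 summits slightly off the beta-catenin summit, keep >= 1 bp
  # overlap by construction (shift bounded well below peak width)
  if (length(fx)) {
    sh <- round(runif(length(fx), -half / 2, half / 2))
    fx <- GenomicRanges::shift(fx, sh)
    mcols(fx)$name <- sprintf("foxh1_%05d", seq_along(fx))
  }
  list(
    beta_catenin_st7 = peakSet(st7, score = signif(runif(length(st7), 5, 50), 4),
                               stage = 7, factor = "beta_catenin"),
    beta_catenin_st10 = peakSet(st10, score = signif(runif(length(st10), 5, 50), 4),
                                stage = 10, factor = "beta_catenin"),
    foxh1_st7 = peakSet(fx, score = signif(runif(length(fx), 5, 50), 4),
                        stage = 7, factor = "foxh1")
  )
}

#' Construct two peak sets realizing a prescribed Venn partition
#'
#' Builds set A and set B on a fresh deterministic genome such that exactly
#' \code{nShared} A-peaks coincide with B-peaks, \code{nAOnly} are exclusive
#' to A and \code{nBOnly} exclusive to B, using grid placement so no
#' accidental overlaps can arise. Used to execute printed Venn totals as
#' worked set-arithmetic examples.
#'
#' @param nAOnly,nShared,nBOnly prescribed partition counts.
#' @param peakWidth,gap geometry of the placement grid (bp).
#' @return list of \code{GRanges}: \code{a} and \code{b}.
#' @examples
#' p <- generateVennPeaks(5, 3, 2)
#' vennPartition(p$a, p$b)$counts
#' @export
generateVennPeaks <- function(nAOnly, nShared, nBOnly,
                              peakWidth = 200L, gap = 200L) {
  n <- nAOnly + nShared + nBOnly
  pitch <- peakWidth + gap
  starts <- (seq_len(n) - 1L) * pitch + 1L
  chromLen <- n * pitch + gap
  gr <- function(idx) GRanges("chrV", IRanges(starts[idx], width = peakWidth),
                              seqinfo = Seqinfo("chrV", chromLen))
  aIdx <- seq_len(nAOnly + nShared)
  bIdx <- c(nAOnly + seq_len(nShared), nAOnly + nShared + seq_len(nBOnly))
  list(a = gr(aIdx), b = gr(bIdx))
}

#' Generate staged expression time courses
#'
#' Target genes follow a steep four-parameter logistic ramp in stage-index
#' space, parameterized so the 20,000 transcripts-per-embryo threshold is
#' first reached exactly at the gene's planted onset stage, with baseline
#' below 10,000 before stage 6 and a plateau above 100,000 by stage 10.
#' Wnt-independent genes stay flat at their baseline.
#'
#' @inheritParams generatePeaks
#' @return a \linkS4class{StageSeriesSet} over the full stage vocabulary.
#' @export
generateTimecourses <- function(truth, config,
                                seed = deriveSeed(config$seed, "timecourses")) {
  if (config$ceilingTPE <= 1e5 && any(truth$true_class != "wnt_independent"))
    stop("ceilingTPE must exceed 100,000 when target genes are present")
  set.seed(seed)
  vocab <- stageVocabulary()
  x <- seq_along(vocab)
  n <- nrow(truth)
  tpe <- matrix(0, n, length(vocab),
                dimnames = list(truth$gene_id, as.character(vocab)))
  base <- runif(n, 200, 5000)
  steep <- 8
  for (i in seq_len(n)) {
    if (truth$true_class[i] == "wnt_independent") {
      tpe[i, ] <- base[i]
    } else {
      x0 <- stageIndex(truth$surge_onset_stage[i]) - 0.5
      tpe[i, ] <- base[i] +
        (config$ceilingTPE - base[i]) / (1 + exp(-steep * (x - x0)))
    }
  }
  StageSeriesSet(round(tpe, 1), vocab)
}

#' Generate the knockdown/rescue count experiment
#'
#' Negative-binomial counts for conditions control, MO and MO_rescue at
#' stages 8 and 9 with the configured replicate number. Under the
#' beta-catenin knockdown, first-class genes carry the knockdown shift at
#' both stages while second-class genes (not yet expressed at stage 8) carry
#' it only at stage 9; the rescue condition restores the mean toward control
#' by the configured efficiency. Under the intermediate-factor (sia)
#' knockdown, only second-class genes respond, at stage 9.
#'
#' @inheritParams generatePeaks
#' @param knockdown which planted perturbation to simulate.
#' @return a \linkS4class{CountExperiment}; planted per-sample means and
#'   library sizes are kept in \code{metadata()} for oracle tests.
#' @export
generateCountExperiment <- function(truth, config,
                                    knockdown = c("bcat", "sia"),
                                    seed = deriveSeed(config$seed,
                                      paste0("counts_", knockdown[1L]))) {
  knockdown <- match.arg(knockdown)
  set.seed(seed)
  conds <- if (knockdown == "bcat") c("control", "MO", "MO_rescue")
           else c("control", "sia_MO", "sia_MO_rescue")
  stages <- c(8, 9)
  nrep <- config$nReplicates
  design <- expand.grid(rep = seq_len(nrep), condition = conds,
                        stage = stages, stringsAsFactors = FALSE)
  n <- nrow(truth)
  baseMean <- exp(rnorm(n, config$baseMeanLog, config$baseMeanSd))
  # target genes, once induced, are strongly expressed (their time-course
  # plateaus sit far above the typical transcript level), so their count
  # means are drawn from a higher, tighter distribution
  isTarget <- truth$true_class != "wnt_independent"
  baseMean[isTarget] <- exp(rnorm(sum(isTarget), log(1000), 0.5))
  # second-class genes are essentially silent at stage 8
  lowMean <- runif(n, 1, 10)
  fc <- 2^config$moLog2FC
  eff <- config$rescueEfficiency
  mu <- matrix(0, n, nrow(design))
  for (j in seq_len(nrow(design))) {
    st <- design$stage[j]
    m <- ifelse(truth$true_class == "class2" & st == 8, lowMean, baseMean)
    affected <- if (knockdown == "bcat")
      (truth$true_class == "class1") |
        (truth$true_class == "class2" & st == 9)
    else
      (truth$true_class == "class2" & st == 9)
    mMO <- ifelse(affected, m * fc, m)
    mu[, j] <- switch(sub("^sia_", "", design$condition[j]),
                      control = m,
                      MO = mMO,
                      MO_rescue = mMO + eff * (m - mMO))
  }
  libSize <- runif(nrow(design), 1 - config$libSizeRange,
                   1 + config$libSizeRange)
  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  k <- matrix(rnbinom(length(mu), mu = sweep(mu, 2, libSize, "*"),
                      size = size), n, nrow(design))
  dimnames(k) <- list(truth$gene_id,
                      sprintf("%s_st%d_r%d", design$condition, design$stage,
                              design$rep))
  ce <- CountExperiment(k, design$condition, design$stage)
  metadata(ce)$libSize <- libSize
  metadata(ce)$plantedMu <- mu
  metadata(ce)$knockdown <- knockdown
  ce
}

#' Generate peak sequences with planted motifs
#'
#' Draws i.i.d. background sequence at the configured nucleotide composition
#' for each peak, then independently plants, at the per-motif rates, one
#' instance of each configured consensus (IUPAC codes resolved uniformly) at
#' a random non-overlapping offset and strand. Every planted instance is
#' recorded in the implant log.
#'
#' @param peaks \code{GRanges} naming the sequences (metadata \code{name}
#'   used as FASTA ids; falls back to \code{peak_<i>}).
#' @inheritParams generatePeaks
#' @return list with \code{sequences} (\link[Biostrings]{DNAStringSet}) and
#'   \code{implants} (data.frame: seq_id, motif, offset, strand, instance).
#' @export
generateSequences <- function(peaks, config,
                              seed = deriveSeed(config$seed, "sequences")) {
  set.seed(seed)
  motifs <- c(tcf = config$tcfConsensus, foxh1 = config$foxh1Consensus)
  rates <- c(tcf = config$plantRateTcf, foxh1 = config$plantRateFoxh1)
  wid <- width(peaks)
  if (any(nchar(motifs) > wid))
    stop("motif longer than peak width")
  ids <- if (!is.null(mcols(peaks)$name)) mcols(peaks)$name
         else sprintf("peak_%05d", seq_along(peaks))
  iupac <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
                S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
                K = c("G", "T"), M = c("A", "C"), N = c("A", "C", "G", "T"))
  sampleInstance <- function(consensus) {
    paste(vapply(strsplit(consensus, "")[[1L]],
                 function(ch) {
                   opts <- iupac[[ch]]
                   if (is.null(opts)) stop("unsupported IUPAC code: ", ch)
                   if (length(opts) == 1L) opts else sample(opts, 1L)
                 }, ""), collapse = "")
  }
  nt <- c("A", "C", "G", "T")
  seqs <- character(length(peaks))
  log <- vector("list", length(peaks))
  for (i in seq_along(peaks)) {
    s <- sample(nt, wid[i], replace = TRUE, prob = config$background)
    taken <- integer(0)
    entries <- list()
    for (m in names(motifs)) {
      if (runif(1) >= rates[[m]]) next
      inst <- sampleInstance(motifs[[m]])
      if (runif(1) < 0.5) {
        strandc <- "-"
        planted <- as.character(reverseComplement(DNAStringSet(inst)))
      } else {
        strandc <- "+"
        planted <- inst
      }
      L <- nchar(planted)
      for (try in 1:50) {
        off <- sample.int(wid[i] - L + 1L, 1L)
        span <- off:(off + L - 1L)
        if (!length(intersect(span, taken))) break
        off <- NA_integer_
      }
      if (is.na(off)) next
      s[span] <- strsplit(planted, "")[[1L]]
      taken <- c(taken, span)
      entries[[length(entries) + 1L]] <-
        data.frame(seq_id = ids[i], motif = m, offset = off,
                   strand = strandc, instance = inst,
                   stringsAsFactors = FALSE)
    }
    seqs[i] <- paste(s, collapse = "")
    if (length(entries)) log[[i]] <- do.call(rbind, entries)
  }
  implants <- do.call(rbind, log[!vapply(log, is.null, NA)])
  if (is.null(implants))
    implants <- data.frame(seq_id = character(0), motif = character(0),
                           offset = integer(0), strand = character(0),
                           instance = character(0), stringsAsFactors = FALSE)
  out <- DNAStringSet(seqs)
  names(out) <- ids
  list(sequences = out, implants = implants)
}

#' Generate a complete synthetic study
#'
#' Runs every generator off one master seed and returns all artifacts plus
#' the ground truth: genome and annotation, stage-labelled peak sets, staged
#' time courses, beta-catenin and sia knockdown/rescue count experiments,
#' and motif-planted sequences for the stage-7 peaks at target genes.
#'
#' @param config a \code{\link{simConfig}}.
#' @return named list of study artifacts.
#' @export
simulateStudy <- function(config = simConfig()) {
  genome <- generateGenome(config)
  truth <- generateTruthTable(genome$genes, config)
  peaks <- generatePeaks(genome$genes, truth, config)
  timecourses <- generateTimecourses(truth, config)
  countsBcat <- generateCountExperiment(truth, config, "bcat")
  countsSia <- generateCountExperiment(truth, config, "sia")
  targetIdx <- seq_len(sum(truth$true_class %in% c("class1", "class2")))
  seqres <- generateSequences(peaks$beta_catenin_st7[targetIdx], config)
  list(config = config, sizes = genome$sizes, genes = genome$genes,
       truth = truth, peaks = peaks, timecourses = timecourses,
       countsBcat = countsBcat, countsSia = countsSia,
       sequences = seqres$sequences, implants = seqres$implants)
}
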