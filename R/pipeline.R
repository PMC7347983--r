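#' Full pipeline configuration
#'
#' @param sim a \code{\link{simConfig}}.
#' @param surge a \code{\link{surgeConfig}}.
#' @param motif a \code{\link{motifConfig}}.
#' @param alpha FDR threshold of the regulated-gene caller.
#' @param windowBp peak-to-gene assignment window (bp).
#' @param nPerm permutations for the overlap significance test.
#' @param outdir optional output directory; when set, intermediates (GFF3,
#'   BED, FASTA, TSV tables) and the report JSON are written there.
#' @param seed master seed (overrides \code{sim$seed}).
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(sim = simConfig(), surge = surgeConfig(),
                           motif = motifConfig(), alpha = 0.05,
                           windowBp = 1e5, nPerm = 199L, outdir = NULL,
                           seed = sim$seed) {
  sim$seed <- seed
  structure(list(sim = sim, surge = surge, motif = motif, alpha = alpha,
                 windowBp = windowBp, nPerm = nPerm, outdir = outdir,
                 seed = seed),
            class = "PipelineConfig")
}

#' Run the full synthetic-study pipeline
#'
#' Generates the synthetic study from the master seed, then runs every
#' analysis stage: surge classification of the time courses, rescue-gated
#' regulated-gene calling at stages 8 and 9, peak-to-gene assignment and
#' stage-wise Venn partitioning, direct-target classification, Foxh1
#' co-binding context analysis with a permutation null, de novo motif
#' discovery on target peak sequences, and the feedforward epistasis test.
#' When ground truth is available (always, for generated studies) a
#' per-class confusion matrix is added. With \code{outdir} set, per-record
#' tables and generated files are written to disk together with a
#' machine-readable JSON report and a \code{MANIFEST} of completed stages.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return list of class \code{PipelineReport}.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  manifest <- character(0)
  logLines <- character(0)
  out <- config$outdir
  t0 <- Sys.time()
  emit <- function(stage) {
    manifest <<- c(manifest, stage)
    logLines <<- c(logLines,
                   sprintf("stage=%s elapsed_s=%.2f seed=%d", stage,
                           as.numeric(difftime(Sys.time(), t0, units = "secs")),
                           config$seed))
    if (!is.null(out)) {
      writeLines(manifest, file.path(out, "MANIFEST"))
      writeLines(logLines, file.path(out, "pipeline.log"))
    }
  }
  if (!is.null(out)) dir.create(out, recursive = TRUE, showWarnings = FALSE)

  study <- simulateStudy(config$sim)
  emit("simulate")

  if (config$sim$nGenes == 0L) {
    rep0 <- list(study = study, surgeCalls = NULL, regulated = NULL,
                 vennGenes = c(st8_only = 0, shared = 0, st9_only = 0),
                 peakPartition = c(a_only = 0, shared = 0, b_only = 0,
                                   shared_b = 0),
                 targets = NULL, context = NULL, motifs = NULL,
                 epistasis = NULL, confusion = NULL, manifest = manifest)
    class(rep0) <- "PipelineReport"
    return(rep0)
  }

  surgeCalls <- classifySurge(study$timecourses, config$surge)
  emit("classify-surges")

  reg8 <- callRegulatedGenes(study$countsBcat, 8, config$alpha)
  reg9 <- callRegulatedGenes(study$countsBcat, 9, config$alpha)
  set8 <- reg8$gene_id[reg8$regulated]
  set9 <- reg9$gene_id[reg9$regulated]
  vennGenes <- c(st8_only = length(setdiff(set8, set9)),
                 shared = length(intersect(set8, set9)),
                 st9_only = length(setdiff(set9, set8)))

  asg7 <- assignPeaksToGenes(study$peaks$beta_catenin_st7, study$genes,
                             config$windowBp)
  asg10 <- assignPeaksToGenes(study$peaks$beta_catenin_st10, study$genes,
                              config$windowBp)
  partition <- vennPartition(study$peaks$beta_catenin_st7,
                             study$peaks$beta_catenin_st10)
  targets <- classifyDirectTargets(reg8, reg9, surgeCalls, asg7, asg10)
  emit("call-targets")

  ovl <- permutationOverlapTest(study$peaks$beta_catenin_st7,
                                study$peaks$foxh1_st7, study$sizes,
                                nPerm = config$nPerm,
                                seed = deriveSeed(config$seed, "perm"))
  emit("context")

  background <- makeBackground(study$sequences,
                               seed = deriveSeed(config$seed, "shuffle"))
  libPath <- system.file("extdata", "synthetic_known_motifs.jaspar",
                         package = "maternalWnt")
  lib <- if (nzchar(libPath)) readPFMLibrary(libPath) else NULL
  motifs <- discoverMotifs(study$sequences, background, config$motif,
                           library = lib, bg = config$sim$background)
  emit("motifs")

  epistasis <- knockdownEpistasisCall(study$countsSia,
                                      data.frame(gene_id = study$truth$gene_id,
                                                 true_class = study$truth$true_class),
                                      config$alpha)
  emit("feedforward")

  lev <- c("class1", "class2", "wnt_independent")
  called <- targets$target_class[match(study$truth$gene_id, targets$gene_id)]
  called[called %in% c("not_regulated", "indirect", "direct_other")] <-
    "wnt_independent_or_other"
  confusion <- table(truth = factor(study$truth$true_class, lev),
                     called = called)

  report <- list(study = study, surgeCalls = surgeCalls,
                 regulated = list(st8 = reg8, st9 = reg9),
                 vennGenes = vennGenes,
                 peakPartition = partition$counts,
                 assignments = list(st7 = asg7, st10 = asg10),
                 targets = targets,
                 context = ovl,
                 motifs = motifs,
                 epistasis = epistasis,
                 confusion = confusion,
                 manifest = manifest)
  class(report) <- "PipelineReport"

  if (!is.null(out)) {
    writeGff3(study$genes, file.path(out, "genes.gff3"))
    for (nm in names(study$peaks))
      writeBed(study$peaks[[nm]], file.path(out, paste0(nm, ".bed")),
               columns = 5L)
    writeFastaFile(study$sequences, file.path(out, "target_peaks.fasta"))
    writeTsv(study$truth, file.path(out, "truth.tsv"))
    writeTsv(surgeCalls, file.path(out, "surge_calls.tsv"))
    writeTsv(reg8, file.path(out, "regulated_st8.tsv"))
    writeTsv(reg9, file.path(out, "regulated_st9.tsv"))
    writeTsv(targets, file.path(out, "target_calls.tsv"))
    writeTsv(motifs, file.path(out, "motif_results.tsv"))
    writeTsv(epistasis, file.path(out, "epistasis_calls.tsv"))
    summary <- list(venn_genes = as.list(vennGenes),
                    peak_partition = as.list(partition$counts),
                    foxh1_overlap = ovl[c("fraction_a_in_b", "n_a",
                                          "n_overlap", "p_perm")],
                    seed = config$seed)
    jsonlite::write_json(summary, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("report")
    report$manifest <- manifest
  }
  report
}

#' Render a pipeline report
#'
#' Produces a human-readable Markdown (or TSV) summary: the regulated-gene
#' Venn counts, the stage-wise peak partition, the target-class tally, the
#' Foxh1 co-binding context, and a ranked motif table with columns
#' Rank | Discovered Motif | Best Match | p Value | %.
#'
#' @param report a \code{PipelineReport} from \code{\link{runPipeline}}.
#' @param format \code{"markdown"} or \code{"tsv"}.
#' @return character vector of rendered lines (invisibly printed).
#' @export
renderReport <- function(report, format = c("markdown", "tsv")) {
  format <- match.arg(format)
  if (!format %in% c("markdown", "tsv")) stop("unknown format")
  vg <- report$vennGenes
  pp <- report$peakPartition
  tally <- if (!is.null(report$targets))
    table(report$targets$target_class) else table(character(0))
  motifTab <- report$motifs
  if (format == "tsv") {
    lines <- c("section\tkey\tvalue",
               paste0("venn_genes\t", names(vg), "\t", vg),
               paste0("peak_partition\t", names(pp), "\t", pp),
               paste0("target_classes\t", names(tally), "\t", as.integer(tally)))
    if (!is.null(motifTab) && nrow(motifTab))
      lines <- c(lines,
                 paste0("motif\t", motifTab$rank, "\t",
                        motifTab$consensus, "|", motifTab$best_match, "|",
                        signif(motifTab$p_value, 3), "|",
                        round(motifTab$pct_targets)))
    return(lines)
  }
  lines <- c("# Pipeline report", "",
             "## Regulated genes (Venn)", "",
             paste0("- st8 only: ", vg["st8_only"]),
             paste0("- shared: ", vg["shared"]),
             paste0("- st9 only: ", vg["st9_only"]), "",
             "## Peak partition (st7 vs st10)", "",
             paste0("- exclusively st7: ", pp["a_only"]),
             paste0("- shared (st7 side): ", pp["shared"]),
             paste0("- exclusively st10: ", pp["b_only"]), "",
             "## Target classes", "",
             if (length(tally)) paste0("- ", names(tally), ": ",
                                       as.integer(tally)) else "- (none)",
             "")
  if (!is.null(report$context))
    lines <- c(lines, "## Foxh1 co-binding (st7)", "",
               sprintf("- fraction of beta-catenin peaks Foxh1-co-bound: %.3f (p_perm = %.4g)",
                       report$context$fraction_a_in_b,
                       report$context$p_perm), "")
  lines <- c(lines, "## De novo motifs", "",
             "| Rank | Discovered Motif | Best Match | p Value | % |",
             "|------|------------------|------------|---------|---|")
  if (!is.null(motifTab) && nrow(motifTab))
    lines <- c(lines,
               sprintf("| %d | %s | %s | %.3g | %d |",
                       motifTab$rank, motifTab$consensus,
                       motifTab$best_match, motifTab$p_value,
                       round(motifTab$pct_targets)))
  lines
}
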