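suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
  library(SummarizedExperiment)
})

# random interval set on named chromosome sizes
randomIntervals <- function(n, sizes, width = 200L) {
  chr <- sample(names(sizes), n, replace = TRUE)
  s <- floor(runif(n, 1, sizes[chr] - width))
  GRanges(chr, IRanges(s, s + width - 1L))
}

# all-pairs overlap oracle: for each interval of a, does it overlap any of b?
bruteOverlap <- function(a, b) {
  ca <- as.character(seqnames(a)); cb <- as.character(seqnames(b))
  sa <- start(a); ea <- end(a); sb <- start(b); eb <- end(b)
  vapply(seq_along(a), function(i)
    any(ca[i] == cb & sa[i] <= eb & sb <= ea[i]), NA)
}

# dinucleotide count table of a sequence string
dinucTable <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  table(paste0(ch[-length(ch)], ch[-1L]))
}

smallSim <- function(...) {
  simConfig(nGenes = 60, nClass1 = 5, nClass2 = 15, decoyPeakCount = 40, ...)
}
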