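#' @importFrom GenomicRanges GRanges start end width strand seqnames
#'   findOverlaps countOverlaps mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqlevels
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement letterFrequency width
#' @importFrom utils read.delim write.table
NULL

#' Chromosome sizes
#'
#' @param name chromosome identifiers (unique).
#' @param length chromosome lengths in bp (positive integers).
#' @return a \link[GenomeInfoDb]{Seqinfo} object.
#' @examples
#' chromSizes(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
chromSizes <- function(name, length) {
  if (anyDuplicated(name)) stop("chromosome names must be unique")
  if (any(length <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = as.character(name), seqlengths = as.integer(length))
}

#' Construct a peak set
#'
#' Peaks are held as a \link[GenomicRanges]{GRanges} with metadata columns
#' \code{score} (nonnegative enrichment score), \code{stage} (developmental
#' stage code from \code{\link{stageVocabulary}}) and \code{factor}
#' (\code{beta_catenin} or \code{foxh1}).
#'
#' @param gr a \code{GRanges}.
#' @param score nonnegative numeric, recycled.
#' @param stage numeric stage code, recycled.
#' @param factor character factor label, recycled.
#' @return annotated \code{GRanges}.
#' @export
peakSet <- function(gr, score = 0, stage = NA_real_,
                    factor = c("beta_catenin", "foxh1")) {
  factor <- match.arg(factor)
  if (any(score < 0)) stop("peak scores must be nonnegative")
  if (!all(is.na(stage)) ) stageIndex(stage[!is.na(stage)])
  mcols(gr)$score <- rep_len(score, length(gr))
  mcols(gr)$stage <- rep_len(stage, length(gr))
  mcols(gr)$factor <- rep_len(factor, length(gr))
  gr
}

#' Read a BED file of peaks
#'
#' BED coordinates are 0-based half-open on disk; they are converted to the
#' 1-based closed convention of \code{GRanges} on import (start + 1), so that
#' widths and overlaps agree with the on-disk intervals.
#'
#' @param path BED file (3-6 tab-separated columns).
#' @return \code{GRanges}, in file order, with \code{name} and \code{score}
#'   metadata columns when present.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' readBed(f)
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L))
    stop("BED line ", which(ncols < 3L)[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(s) | is.na(e) | s != floor(s) | e != floor(e)
  if (any(bad))
    stop("BED line ", which(bad)[1L], ": non-integer coordinate")
  if (any(s >= e))
    stop("BED line ", which(s >= e)[1L], ": start >= end")
  if (any(s < 0))
    stop("BED line ", which(s < 0)[1L], ": negative start")
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  if (all(ncols >= 4L))
    mcols(gr)$name <- vapply(fields, `[[`, "", 4L)
  if (all(ncols >= 5L))
    mcols(gr)$score <- as.numeric(vapply(fields, `[[`, "", 5L))
  if (all(ncols >= 6L)) {
    str <- vapply(fields, `[[`, "", 6L)
    if (!all(str %in% c("+", "-", "."))) stop("invalid strand symbol in BED")
    strand(gr) <- str
  }
  gr
}

#' Write a peak set as BED
#'
#' Inverse of \code{\link{readBed}}: GRanges 1-based starts are written as
#' 0-based BED starts. A 3-column file round-trips byte-identically.
#'
#' @param gr \code{GRanges}.
#' @param path output path.
#' @param columns number of BED columns to emit (3-6).
#' @export
writeBed <- function(gr, path, columns = 3L) {
  chrom <- as.character(seqnames(gr))
  s <- format(start(gr) - 1, scientific = FALSE, trim = TRUE)
  e <- format(end(gr), scientific = FALSE, trim = TRUE)
  out <- paste(chrom, s, e, sep = "\t")
  if (columns >= 4L) {
    nm <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else paste0("peak_", seq_along(gr))
    out <- paste(out, nm, sep = "\t")
  }
  if (columns >= 5L) {
    sc <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else 0
    out <- paste(out, format(sc, scientific = FALSE, trim = TRUE), sep = "\t")
  }
  if (columns >= 6L) {
    str <- as.character(strand(gr))
    str[str == "*"] <- "."
    out <- paste(out, str, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps records of type \code{gene}. GFF3 1-based closed coordinates map
#' directly onto \code{GRanges}. The transcription start site is strand-aware:
#' the leftmost base for \code{+} genes, the rightmost for \code{-} genes,
#' stored 1-based in metadata column \code{tss}.
#'
#' @param path GFF3 file.
#' @return \code{GRanges} with metadata \code{gene_id}, \code{name},
#'   \code{tss}.
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9L && f[[3L]] == "gene", NA)
  fields <- fields[keep]
  if (length(fields) == 0L) return(GRanges())
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- as.integer(vapply(fields, `[[`, "", 4L))
  e <- as.integer(vapply(fields, `[[`, "", 5L))
  str <- vapply(fields, `[[`, "", 7L)
  if (!all(str %in% c("+", "-", ".")))
    stop("unknown strand symbol: ", setdiff(str, c("+", "-", "."))[1L])
  attrs <- vapply(fields, `[[`, "", 9L)
  getAttr <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]+)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, "")
  }
  ids <- getAttr(attrs, "ID")
  if (anyNA(ids))
    stop("gene record without ID attribute (record ", which(is.na(ids))[1L], ")")
  if (anyDuplicated(ids))
    stop("duplicate gene ID: ", ids[anyDuplicated(ids)])
  nm <- getAttr(attrs, "Name")
  nm[is.na(nm)] <- ids[is.na(nm)]
  gr <- GRanges(chrom, IRanges(s, e), strand = str)
  mcols(gr)$gene_id <- ids
  mcols(gr)$name <- nm
  mcols(gr)$tss <- ifelse(str == "-", e, s)
  names(gr) <- ids
  gr
}

#' Write gene models as GFF3
#'
#' @param genes \code{GRanges} with \code{gene_id} metadata.
#' @param path output path.
#' @export
writeGff3 <- function(genes, path) {
  str <- as.character(strand(genes))
  str[str == "*"] <- "."
  out <- paste(as.character(seqnames(genes)), "maternalWnt", "gene",
               start(genes), end(genes), ".", str, ".",
               paste0("ID=", mcols(genes)$gene_id,
                      ";Name=", mcols(genes)$name),
               sep = "\t")
  writeLines(c("##gff-version 3", out), path)
  invisible(path)
}

#' Read nucleotide FASTA with validation
#'
#' Sequences are uppercased and must be over the alphabet A, C, G, T, N;
#' record ids must be unique.
#'
#' @param path FASTA file (plain or line-wrapped).
#' @return \link[Biostrings]{DNAStringSet}.
#' @export
readFastaFile <- function(path) {
  seqs <- withCallingHandlers(
    readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-nucleotide symbol in ", path, ": ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  dup <- anyDuplicated(names(seqs))
  if (dup)
    stop("duplicate sequence id: ", names(seqs)[dup])
  seqs <- DNAStringSet(toupper(as.character(seqs)))
  other <- letterFrequency(seqs, letters = "ACGTN")
  bad <- other != Biostrings::width(seqs)
  if (any(bad)) {
    offending <- setdiff(unique(strsplit(as.character(seqs[bad][1L]), "")[[1L]]),
                         c("A", "C", "G", "T", "N"))
    stop("non-nucleotide symbol in ", names(seqs)[bad][1L], ": ",
         paste(offending, collapse = ", "))
  }
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs \code{DNAStringSet} or named character vector.
#' @param path output path.
#' @export
writeFastaFile <- function(seqs, path) {
  if (is.character(seqs)) seqs <- DNAStringSet(seqs)
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a JASPAR-style PFM library
#'
#' Parses text blocks of the form \code{>id name} followed by four rows of
#' counts (\code{A [ .. ]}, \code{C [ .. ]}, \code{G [ .. ]}, \code{T [ .. ]};
#' brackets and row letters optional). Counts are converted to
#' column-stochastic probability matrices after adding a uniform Laplace
#' pseudocount of 0.25 per cell, so no position has probability zero under
#' log-odds scanning.
#'
#' @param path PFM text file.
#' @param pseudocount added to each count cell before normalization.
#' @return named list of \linkS4class{PWM}, in file order; empty list for an
#'   empty file.
#' @export
readPFMLibrary <- function(path, pseudocount = 0.25) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(list())
  hdr <- which(startsWith(lines, ">"))
  if (length(hdr) == 0L) stop("no '>' motif headers found")
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("motif block must have exactly 4 count rows: ", lines[hdr[i]])
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("rows of unequal length in motif ", lines[hdr[i]])
    counts <- do.call(rbind, rows)
    if (any(is.na(counts)) || any(counts < 0))
      stop("negative or unparseable count in motif ", lines[hdr[i]])
    rownames(counts) <- c("A", "C", "G", "T")
    m <- counts + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- strsplit(id, "\\s+")[[1L]]
    nm <- if (length(id) > 1L) id[2L] else id[1L]
    out[[nm]] <- new("PWM", matrix = m, pseudocount = pseudocount, name = nm)
  }
  out
}

#' Read/write a TSV table with header
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' @rdname readTsv
#' @param x data.frame to write.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
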