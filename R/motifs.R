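#' Motif-discovery configuration
#'
#' @param kRange seed k-mer lengths scanned for enrichment (within 4..16).
#' @param nMotifs maximum number of motifs reported.
#' @param emIterations,emTolerance EM stopping rule: stop when the largest
#'   matrix entry change falls below the tolerance or after this many
#'   iterations.
#' @param hitThresholdFrac hit threshold as a fraction of the PWM's maximum
#'   attainable log-odds score.
#' @param seedPValueCutoff stop discovery when no seed k-mer is enriched
#'   below this p-value.
#' @param pseudocount Laplace pseudocount for matrix estimation.
#' @param seed RNG seed used by the background shuffler.
#' @return validated list of class \code{MotifConfig}.
#' @export
motifConfig <- function(kRange = 6:10, nMotifs = 10L, emIterations = 100L,
                        emTolerance = 1e-4, hitThresholdFrac = 0.8,
                        seedPValueCutoff = 0.01, pseudocount = 0.25,
                        seed = 1L) {
  if (min(kRange) < 4L || max(kRange) > 16L)
    stop("kRange must lie within [4, 16]")
  if (nMotifs < 1L) stop("nMotifs must be >= 1")
  structure(as.list(environment()), class = "MotifConfig")
}

.NT <- c("A", "C", "G", "T")

.revcompChar <- function(x) {
  if (length(x) == 0L) return(character(0))
  k <- unique(nchar(x))
  if (length(k) == 1L) {
    # fixed-length fast path: k vectorized substring extractions
    y <- chartr("ACGT", "TGCA", x)
    cols <- lapply(k:1, function(i) substring(y, i, i))
    do.call(paste0, cols)
  } else {
    vapply(x, function(s)
      paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = ""),
      "", USE.NAMES = FALSE)
  }
}

.asCharVec <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) {
    out <- as.character(seqs)
    if (is.null(names(out))) names(out) <- sprintf("seq_%05d", seq_along(out))
    out
  } else {
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%05d", seq_along(seqs))
    toupper(seqs)
  }
}

#' Build a PWM from an IUPAC consensus
#'
#' Allowed bases at each position share probability \code{1 - soft}; the
#' remainder is spread over disallowed bases, so log-odds scanning never
#' meets a zero.
#'
#' @param consensus IUPAC string.
#' @param soft total probability assigned to disallowed bases per position.
#' @param name motif name.
#' @return a \linkS4class{PWM}.
#' @export
consensusPWM <- function(consensus, soft = 0.04, name = consensus) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
                S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
                K = c("G", "T"), M = c("A", "C"), N = .NT)
  chars <- strsplit(toupper(consensus), "")[[1L]]
  m <- vapply(chars, function(ch) {
    opts <- iupac[[ch]]
    if (is.null(opts)) stop("unsupported IUPAC code: ", ch)
    p <- rep(soft / (4 - length(opts) + 1e-12), 4)
    names(p) <- .NT
    if (length(opts) == 4L) p[] <- 0.25
    else p[opts] <- (1 - soft) / length(opts)
    p / sum(p)
  }, numeric(4))
  rownames(m) <- .NT
  new("PWM", matrix = m, pseudocount = 0, name = name)
}

#' Majority-base consensus of a PWM
#'
#' @param pwm a \linkS4class{PWM}.
#' @return character consensus (max-probability base per column; lowercase
#'   when below 0.5).
#' @export
pwmConsensus <- function(pwm) {
  m <- pwm@matrix
  ch <- .NT[apply(m, 2, which.max)]
  lo <- apply(m, 2, max) < 0.5
  ch[lo] <- tolower(ch[lo])
  paste(ch, collapse = "")
}

#' @rdname pwmConsensus
#' @export
motifWidth <- function(pwm) ncol(pwm@matrix)

#' Reverse complement of a PWM
#'
#' @param pwm a \linkS4class{PWM}.
#' @return the reverse-complement \code{PWM}.
#' @export
reverseComplementPWM <- function(pwm) {
  m <- pwm@matrix[c("T", "G", "C", "A"), rev(seq_len(ncol(pwm@matrix))), drop = FALSE]
  rownames(m) <- .NT
  new("PWM", matrix = m, pseudocount = pwm@pseudocount,
      name = paste0(pwm@name, "_rc"))
}

# Altschul-Erickson dinucleotide-preserving shuffle of one character vector.
.dinucShuffleOne <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  if (n < 2L) stop("sequence shorter than 2")
  adj <- split(chars[-1L], factor(chars[-n], levels = verts))
  first <- chars[1L]; last <- chars[n]
  pickLast <- function() {
    le <- list()
    for (v in verts) {
      if (v == last || length(adj[[v]]) == 0L) next
      le[[v]] <- adj[[v]][sample.int(length(adj[[v]]), 1L)]
    }
    le
  }
  reachesLast <- function(le) {
    for (v in names(le)) {
      cur <- v; seen <- character(0)
      while (cur != last) {
        if (cur %in% seen) return(FALSE)
        seen <- c(seen, cur)
        nxt <- le[[cur]]
        if (is.null(nxt)) return(FALSE)
        cur <- nxt
      }
    }
    TRUE
  }
  repeat {
    le <- pickLast()
    if (reachesLast(le)) break
  }
  ordered <- list()
  for (v in verts) {
    edges <- adj[[v]]
    if (length(edges) == 0L) { ordered[[v]] <- edges; next }
    if (v != last) {
      # remove one instance of the chosen last edge, shuffle, append it
      i <- match(le[[v]], edges)
      rest <- edges[-i]
      ordered[[v]] <- c(rest[sample.int(length(rest))], le[[v]])
    } else {
      ordered[[v]] <- edges[sample.int(length(edges))]
    }
  }
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1L] <- first
  cur <- first
  for (i in 2L:n) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Build background sequences for motif discovery
#'
#' Dinucleotide-preserving shuffle (Altschul-Erickson Euler-path shuffle)
#' of each target sequence, or pass-through of a provided background set.
#'
#' @param targets \code{DNAStringSet} or character vector.
#' @param mode \code{"dinucleotide_shuffle"} or \code{"provided"}.
#' @param provided background set for \code{mode = "provided"}.
#' @param seed RNG seed (fixed seed gives identical shuffles).
#' @return named character vector of background sequences.
#' @export
makeBackground <- function(targets, mode = c("dinucleotide_shuffle", "provided"),
                           provided = NULL, seed = 1L) {
  mode <- match.arg(mode)
  targets <- .asCharVec(targets)
  if (length(targets) == 0L) stop("no target sequences")
  if (mode == "provided") {
    if (is.null(provided)) stop("mode 'provided' needs a background set")
    return(.asCharVec(provided))
  }
  set.seed(seed)
  out <- vapply(targets, function(s)
    paste(.dinucShuffleOne(strsplit(s, "")[[1L]]), collapse = ""), "")
  names(out) <- paste0(names(targets), "_shuf")
  out
}

# Canonical (lexicographically smaller of k-mer and reverse complement)
# presence sets per sequence.
.presenceCounts <- function(seqs, k) {
  kmersBySeq <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    km <- substring(s, 1:(L - k + 1), k:L)
    km <- km[!grepl("N", km, fixed = TRUE)]
    if (length(km) == 0L) return(character(0))
    rc <- .revcompChar(km)
    unique(pmin(km, rc))
  })
  all <- unlist(kmersBySeq, use.names = FALSE)
  if (length(all) == 0L) return(integer(0))
  table(all)
}

#' Seed k-mer enrichment (ZOOPS presence counts)
#'
#' Counts, per canonical k-mer (k-mer collapsed with its reverse
#' complement), the number of target and background sequences containing at
#' least one instance, and tests enrichment in targets with a one-sided
#' hypergeometric (Fisher exact) p-value. Ranked by ascending p, then by
#' descending target presence, then lexicographically.
#'
#' @param targets,background sequence sets.
#' @param k k-mer length.
#' @return data.frame: kmer, n_targets, n_background, p.
#' @export
kmerEnrichment <- function(targets, background, k) {
  targets <- .asCharVec(targets); background <- .asCharVec(background)
  if (any(nchar(c(targets, background)) < k))
    stop("all sequences must be at least ", k, " bases long")
  tT <- .presenceCounts(targets, k)
  tB <- .presenceCounts(background, k)
  kmers <- sort(unique(c(names(tT), names(tB))))
  if (length(kmers) == 0L)
    return(data.frame(kmer = character(0), n_targets = integer(0),
                      n_background = integer(0), p = numeric(0)))
  nT <- as.integer(tT[kmers]); nT[is.na(nT)] <- 0L
  nB <- as.integer(tB[kmers]); nB[is.na(nB)] <- 0L
  NT <- length(targets); NB <- length(background)
  p <- stats::phyper(nT - 1L, nT + nB, NT + NB - nT - nB, NT,
                     lower.tail = FALSE)
  out <- data.frame(kmer = kmers, n_targets = nT, n_background = nB, p = p,
                    stringsAsFactors = FALSE)
  out[order(out$p, -out$n_targets, out$kmer), , drop = FALSE]
}

# Window log-odds scores of one PWM over one encoded sequence.
# enc: integer codes 1..4, NA for N. Returns numeric vector (one per offset);
# windows touching an N score -Inf.
.windowScores <- function(enc, lodds) {
  w <- ncol(lodds)
  L <- length(enc)
  if (L < w) return(numeric(0))
  nOff <- L - w + 1L
  sc <- numeric(nOff)
  bad <- logical(nOff)
  for (j in seq_len(w)) {
    v <- lodds[cbind(enc[j:(j + nOff - 1L)], j)]
    nas <- is.na(v)
    bad <- bad | nas
    v[nas] <- 0
    sc <- sc + v
  }
  sc[bad] <- -Inf
  sc
}

.encode <- function(s) {
  e <- match(strsplit(s, "")[[1L]], .NT)
  e
}

#' Scan sequences with a PWM
#'
#' Log-odds scoring against a 0-order background, both strands; windows
#' containing N are skipped. A minus-strand hit at offset o means the
#' reverse complement of the window starting at o matches the motif.
#'
#' @param pwm a \linkS4class{PWM}.
#' @param seqs sequence set.
#' @param threshold minimum log-odds score of a reported hit.
#' @param bg background nucleotide frequencies (A, C, G, T).
#' @return data.frame: seq_id, offset (1-based), strand, score.
#' @export
scanSequences <- function(pwm, seqs, threshold,
                          bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  seqs <- .asCharVec(seqs)
  loddsF <- log2(pwm@matrix / bg)
  loddsR <- log2(reverseComplementPWM(pwm)@matrix / bg)
  res <- lapply(names(seqs), function(id) {
    enc <- .encode(seqs[[id]])
    sF <- .windowScores(enc, loddsF)
    sR <- .windowScores(enc, loddsR)
    hF <- which(sF >= threshold); hR <- which(sR >= threshold)
    if (!length(hF) && !length(hR)) return(NULL)
    data.frame(seq_id = id,
               offset = c(hF, hR),
               strand = rep(c("+", "-"), c(length(hF), length(hR))),
               score = c(sF[hF], sR[hR]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(seq_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Maximum attainable log-odds score of a PWM
#'
#' @inheritParams scanSequences
#' @return numeric scalar.
#' @export
maxLogOdds <- function(pwm, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  sum(apply(log2(pwm@matrix / bg), 2, max))
}

#' Refine a seed k-mer into a PWM by ZOOPS EM
#'
#' Zero-or-one-occurrence-per-sequence expectation maximization: each
#' sequence either contains one motif site at an unknown offset/strand or is
#' pure background. The E-step computes, per sequence, posterior window
#' responsibilities under the current matrix, site prior and uniform
#' positional prior; the M-step re-estimates the matrix from
#' responsibility-weighted windows with a Laplace pseudocount (a Dirichlet
#' MAP update, so the penalized objective is nondecreasing) and updates the
#' site prior. Iteration stops when the largest matrix change drops below
#' \code{emTolerance} or after \code{emIterations} rounds. Both strands are
#' scanned.
#'
#' @param seedKmer seed string (init: 0.7 on the seed base per position).
#' @param targets sequence set.
#' @param config a \code{\link{motifConfig}}.
#' @param bg background nucleotide frequencies.
#' @return list: \code{pwm}, \code{siteProb} (per-sequence posterior of
#'   containing a site), \code{gamma} (site prior), \code{objective}
#'   (penalized log-likelihood trace).
#' @export
expandToPWM <- function(seedKmer, targets, config = motifConfig(),
                        bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  targets <- .asCharVec(targets)
  w <- nchar(seedKmer)
  if (w < min(config$kRange) || w > max(config$kRange))
    stop("seed length outside kRange")
  if (!any(nchar(targets) >= w)) stop("no sequence at least as long as the seed")
  pc <- config$pseudocount
  m <- consensusPWM(seedKmer, soft = 0.3)@matrix
  nSeq <- length(targets)

  # stack every window of every sequence (both strands, motif-aligned base
  # codes) into one matrix; windows touching an N are dropped up front
  winList <- vector("list", 2L * nSeq)
  seqList <- vector("list", 2L * nSeq)
  for (i in seq_len(nSeq)) {
    enc <- .encode(targets[[i]])
    L <- length(enc)
    if (L < w) next
    nOff <- L - w + 1L
    Wf <- vapply(seq_len(w), function(j) enc[j:(j + nOff - 1L)],
                 integer(nOff))
    if (nOff == 1L) Wf <- matrix(Wf, 1L, w)
    Wr <- (5L - Wf)[, w:1, drop = FALSE]
    winList[[2L * i - 1L]] <- Wf
    winList[[2L * i]] <- Wr
    seqList[[2L * i - 1L]] <- rep.int(i, nOff)
    seqList[[2L * i]] <- rep.int(i, nOff)
  }
  W <- do.call(rbind, winList)
  seqIdx <- unlist(seqList)
  if (is.null(W) || nrow(W) == 0L) stop("no scannable window in targets")
  ok <- rowSums(is.na(W)) == 0L
  W <- W[ok, , drop = FALSE]; seqIdx <- seqIdx[ok]
  nWperSeq <- tabulate(seqIdx, nSeq)
  withWin <- which(nWperSeq > 0L)
  sfac <- factor(seqIdx, levels = withWin)

  gamma <- 0.5
  obj <- numeric(0)
  posterior <- function(m, gamma) {
    lodds <- log(m / bg)
    sc <- numeric(nrow(W))
    for (j in seq_len(w)) sc <- sc + lodds[W[, j] + (j - 1L) * 4L]
    lw <- sc + log(gamma) - log(nWperSeq[seqIdx])
    mseq <- vapply(split(lw, sfac), max, numeric(1))
    lmax <- pmax(mseq, log1p(-gamma))
    ssum <- rowsum(exp(lw - lmax[sfac]), sfac)[, 1L]
    denom <- exp(log1p(-gamma) - lmax) + ssum
    z <- exp(lw - lmax[sfac]) / denom[sfac]
    ll <- sum(lmax + log(denom)) + (nSeq - length(withWin)) * log1p(-gamma)
    list(z = z, ll = ll, siteProb = ssum / denom)
  }
  for (iter in seq_len(config$emIterations)) {
    e <- posterior(m, gamma)
    newCnt <- matrix(pc, 4, w)
    for (j in seq_len(w)) {
      rs <- rowsum(e$z, factor(W[, j], levels = 1:4))
      newCnt[, j] <- newCnt[, j] + ifelse(is.na(rs[, 1L]), 0, rs[, 1L])
    }
    mNew <- sweep(newCnt, 2, colSums(newCnt), "/")
    obj <- c(obj, e$ll + pc * sum(log(m)))
    delta <- max(abs(mNew - m))
    gamma <- min(max(sum(e$z) / nSeq, 1e-4), 1 - 1e-4)
    m <- mNew
    if (delta < config$emTolerance) break
  }
  rownames(m) <- .NT
  pwm <- new("PWM", matrix = m, pseudocount = pc, name = seedKmer)
  e <- posterior(m, gamma)
  siteProb <- numeric(nSeq)
  siteProb[withWin] <- e$siteProb
  list(pwm = pwm, siteProb = siteProb, gamma = gamma, objective = obj)
}

#' Match a PWM against a known-motif library
#'
#' Slides the matrix (both strands) along each library matrix over all
#' ungapped offsets with at least four overlapping columns; the similarity
#' is the mean column-wise Pearson correlation over the aligned span,
#' length-penalized by overlap divided by the wider motif's width. Ties go
#' to the earlier library entry.
#'
#' @param pwm a \linkS4class{PWM} (width >= 4).
#' @param library named list of \code{PWM} (as from
#'   \code{\link{readPFMLibrary}}).
#' @return list: best_match, match_score.
#' @export
matchKnown <- function(pwm, library) {
  if (motifWidth(pwm) < 4L) stop("pwm width must be >= 4")
  if (length(library) == 0L) stop("empty motif library")
  colCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  alignScore <- function(a, b) {
    wa <- ncol(a); wb <- ncol(b)
    best <- -Inf
    for (off in (-(wa - 4L)):(wb - 4L)) {
      ia <- max(1L, 1L - off); ib <- max(1L, 1L + off)
      ov <- min(wa - ia, wb - ib) + 1L
      if (ov < 4L) next
      cols <- vapply(seq_len(ov) - 1L,
                     function(j) colCor(a[, ia + j], b[, ib + j]), numeric(1))
      sc <- mean(cols) * ov / max(wa, wb)
      if (sc > best) best <- sc
    }
    best
  }
  fwd <- pwm@matrix
  rev <- reverseComplementPWM(pwm)@matrix
  bestName <- NA_character_; bestScore <- -Inf
  for (nm in names(library)) {
    lm <- library[[nm]]@matrix
    sc <- max(alignScore(fwd, lm), alignScore(rev, lm))
    if (sc > bestScore) { bestScore <- sc; bestName <- nm }
  }
  list(best_match = bestName, match_score = bestScore)
}

#' De novo ZOOPS motif discovery
#'
#' Iteratively: find the most enriched seed k-mer across the configured k
#' range (hypergeometric ZOOPS presence test versus background), refine it
#' into a PWM by \code{\link{expandToPWM}}, record the motif, mask its hit
#' windows with N in the working copy of the targets, and repeat until the
#' requested number of motifs is found or no seed is enriched below the
#' cutoff. Hit percentages are computed by re-scanning the unmasked
#' originals at the hit threshold (a fraction of the maximum attainable
#' log-odds).
#'
#' @param targets,background sequence sets.
#' @param config a \code{\link{motifConfig}}.
#' @param library optional known-motif library for best-match annotation.
#' @param bg background nucleotide frequencies for scanning.
#' @return data.frame with one row per motif: rank, consensus, seed_kmer,
#'   p_value, pct_targets, best_match, match_score; discovered
#'   \linkS4class{PWM}s in attribute \code{"pwms"}.
#' @export
discoverMotifs <- function(targets, background, config = motifConfig(),
                           library = NULL,
                           bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  targets <- .asCharVec(targets); background <- .asCharVec(background)
  if (length(targets) == 0L || length(background) == 0L)
    stop("targets and background must be non-empty")
  work <- targets
  rows <- list(); pwms <- list()
  for (r in seq_len(config$nMotifs)) {
    best <- NULL
    for (k in config$kRange) {
      if (all(nchar(work) < k)) next
      tab <- kmerEnrichment(work[nchar(work) >= k],
                            background[nchar(background) >= k], k)
      if (nrow(tab) == 0L) next
      if (is.null(best) || tab$p[1L] < best$p)
        best <- list(kmer = tab$kmer[1L], p = tab$p[1L])
    }
    if (is.null(best) || best$p >= config$seedPValueCutoff) break
    fit <- expandToPWM(best$kmer, work, config, bg = bg)
    thr <- config$hitThresholdFrac * maxLogOdds(fit$pwm, bg)
    hitsOrig <- scanSequences(fit$pwm, targets, thr, bg)
    pct <- 100 * length(unique(hitsOrig$seq_id)) / length(targets)
    hitsWork <- scanSequences(fit$pwm, work, thr, bg)
    w <- motifWidth(fit$pwm)
    if (nrow(hitsWork)) {
      for (i in seq_len(nrow(hitsWork))) {
        id <- hitsWork$seq_id[i]; off <- hitsWork$offset[i]
        substr(work[[id]], off, off + w - 1L) <-
          paste(rep("N", w), collapse = "")
      }
    } else {
      # no scannable hit to mask: drop the seed's exact instances instead
      work <- gsub(best$kmer, paste(rep("N", nchar(best$kmer)), collapse = ""),
                   work, fixed = TRUE)
    }
    mk <- if (!is.null(library)) matchKnown(fit$pwm, library)
          else list(best_match = NA_character_, match_score = NA_real_)
    rows[[r]] <- data.frame(consensus = pwmConsensus(fit$pwm),
                            seed_kmer = best$kmer,
                            p_value = best$p,
                            pct_targets = pct,
                            best_match = mk$best_match,
                            match_score = mk$match_score,
                            stringsAsFactors = FALSE)
    pwms[[r]] <- fit$pwm
  }
  if (length(rows) == 0L) {
    out <- data.frame(rank = integer(0), consensus = character(0),
                      seed_kmer = character(0), p_value = numeric(0),
                      pct_targets = numeric(0), best_match = character(0),
                      match_score = numeric(0), stringsAsFactors = FALSE)
    attr(out, "pwms") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  o <- order(out$p_value, -out$pct_targets, out$seed_kmer)
  out <- out[o, , drop = FALSE]
  pwms <- pwms[o]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "pwms") <- pwms
  out
}
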