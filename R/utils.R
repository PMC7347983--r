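#' Derive a stage-specific RNG seed from a master seed
#'
#' Each stochastic generator draws from its own RNG stream, seeded by a
#' stable hash of its label combined with the master seed, so adding one
#' generator never perturbs another's output.
#'
#' @param master integer master seed.
#' @param label character stream label.
#' @return integer seed in [0, 2^31 - 1).
#' @keywords internal
deriveSeed <- function(master, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 1977326743
  as.integer((as.numeric(master) * 48271 + h) %% 2147483629)
}

# Count, for each query interval, whether it overlaps (>= 1 bp) any subject
# interval. Plain numeric implementation used inside tight permutation loops;
# subject must be pre-sorted by start. Overlap of [s1,e1], [s2,e2] (closed,
# 1-based) iff s1 <= e2 && s2 <= e1.
.anyOverlapSorted <- function(qs, qe, ss, se, cummaxSe) {
  # index of last subject with start <= query end
  j <- findInterval(qe, ss)
  ok <- j >= 1L
  ok[ok] <- cummaxSe[j[ok]] >= qs[ok]
  ok
}

# Precompute the sorted-subject structure for .anyOverlapSorted, per chromosome.
.subjectIndex <- function(chrom, s, e) {
  out <- list()
  for (cc in unique(chrom)) {
    i <- chrom == cc
    o <- order(s[i])
    ss <- s[i][o]; se <- e[i][o]
    out[[cc]] <- list(ss = ss, se = se, cummax = cummax(se))
  }
  out
}

# Per-chromosome disjoint-union coverage index: merged subject intervals
# with cumulative covered-bp, for O(log n) covered-length queries.
.coverageIndex <- function(chrom, s, e) {
  out <- list()
  for (cc in unique(chrom)) {
    i <- chrom == cc
    o <- order(s[i])
    ss <- s[i][o]; se <- cummax(e[i][o])
    # merge overlapping/adjacent runs
    newRun <- c(TRUE, ss[-1L] > se[-length(se)] + 1L)
    grp <- cumsum(newRun)
    us <- ss[newRun]
    ue <- vapply(split(se, grp), max, numeric(1))
    out[[cc]] <- list(us = us, ue = ue,
                      cum = cumsum(ue - us + 1))
  }
  out
}

# Total bp of the query intervals covered by the (unioned) subject index.
.coveredBp <- function(chrom, s, e, covIdx) {
  covAt <- function(x, ci) {
    # covered bp in [1, x]
    j <- findInterval(x, ci$us)
    out <- numeric(length(x))
    pos <- j >= 1L
    out[pos] <- ci$cum[j[pos]] - pmax(ci$ue[j[pos]] - x[pos], 0)
    out
  }
  tot <- 0
  for (cc in unique(chrom)) {
    ci <- covIdx[[cc]]
    if (is.null(ci)) next
    i <- which(chrom == cc)
    tot <- tot + sum(covAt(e[i], ci) - covAt(s[i] - 1, ci))
  }
  tot
}

# Overlap indicator for query intervals against an index from .subjectIndex.
.queryOverlaps <- function(chrom, s, e, idx) {
  hit <- logical(length(s))
  for (cc in unique(chrom)) {
    i <- which(chrom == cc)
    sub <- idx[[cc]]
    if (is.null(sub)) next
    hit[i] <- .anyOverlapSorted(s[i], e[i], sub$ss, sub$se, sub$cummax)
  }
  hit
}
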