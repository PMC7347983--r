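#' Fraction of peaks co-occupied by a second factor
#'
#' The proportion of A peaks overlapping (>= 1 bp) at least one B peak.
#'
#' @param a,b \code{GRanges} peak sets on the same assembly.
#' @return list: fraction_a_in_b, n_a, n_overlap.
#' @export
overlapFraction <- function(a, b) {
  if (length(a) == 0L) stop("empty A set: overlap fraction undefined")
  nov <- sum(countOverlaps(a, b, minoverlap = 1L) > 0)
  list(fraction_a_in_b = nov / length(a), n_a = length(a), n_overlap = nov)
}

#' Permutation test of peak-set overlap
#'
#' The test statistic is the total number of A base pairs covered by the B
#' peak union; being a sum of near-continuous quantities it is essentially
#' tie-free, so the permutation p-value is close to exact rather than
#' conservative (an integer peak-hit count would tie heavily between
#' permutations). The reported fraction and \code{n_overlap} still count A
#' peaks overlapping B by >= 1 bp. The null re-places A's intervals
#' uniformly at random on their own chromosome, preserving each interval's
#' width and the per-chromosome interval counts, and recomputes the
#' statistic; \code{p = (1 + #\{null >= observed\}) / (nPerm + 1)}. The
#' null preserves chromosome occupancy and widths but not inter-peak
#' spacing; a circular-shift null (\code{null = "circular"}) that rigidly
#' rotates all of a chromosome's peaks by one random offset is available
#' for correlated peak landscapes.
#'
#' @param a,b \code{GRanges} peak sets.
#' @param sizes \link[GenomeInfoDb]{Seqinfo} or named lengths vector
#'   covering A's chromosomes.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @param null null model, \code{"uniform"} or \code{"circular"}.
#' @return list: fraction_a_in_b, n_a, n_overlap, p_perm, z, n_perm.
#' @export
permutationOverlapTest <- function(a, b, sizes, nPerm = 999L,
                                   seed = 1L, null = c("uniform", "circular")) {
  null <- match.arg(null)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  if (methods::is(sizes, "Seqinfo"))
    sizes <- stats::setNames(seqlengths(sizes), seqlevels(sizes))
  chromA <- as.character(seqnames(a))
  wA <- width(a)
  if (anyNA(sizes[chromA])) stop("missing chromosome length for A peaks")
  if (any(wA > sizes[chromA])) stop("interval wider than its chromosome")
  idx <- .subjectIndex(as.character(seqnames(b)), start(b), end(b))
  nHit <- sum(.queryOverlaps(chromA, start(a), end(a), idx))
  cov <- .coverageIndex(as.character(seqnames(b)), start(b), end(b))
  obs <- .coveredBp(chromA, start(a), end(a), cov)
  # use a private RNG stream; leave the caller's RNG state untouched
  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()))
  }
  set.seed(seed)
  maxStart <- sizes[chromA] - wA + 1
  startA <- start(a)
  nullStat <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    if (null == "uniform") {
      s <- floor(runif(length(a), 1, maxStart + 1))
    } else {
      s <- startA
      for (cc in unique(chromA)) {
        sel <- chromA == cc
        off <- floor(runif(1, 0, sizes[cc]))
        s[sel] <- ((startA[sel] - 1 + off) %% (sizes[cc] - wA[sel] + 1)) + 1
      }
    }
    nullStat[i] <- .coveredBp(chromA, s, s + wA - 1, cov)
  }
  sdNull <- stats::sd(nullStat)
  list(fraction_a_in_b = nHit / length(a),
       n_a = length(a),
       n_overlap = nHit,
       stat_bp = obs,
       p_perm = (1 + sum(nullStat >= obs)) / (nPerm + 1),
       z = if (isTRUE(sdNull > 0)) (obs - mean(nullStat)) / sdNull else NA_real_,
       n_perm = nPerm)
}

#' Overlap between a regulated-gene set and a condition-response set
#'
#' @param regulated character vector of regulated gene ids (non-empty).
#' @param reduced character vector of gene ids reduced in the perturbation.
#' @return list: fraction (|intersection| / |regulated|) and Venn counts
#'   (regulated_only, shared, reduced_only).
#' @export
responseOverlap <- function(regulated, reduced) {
  regulated <- unique(regulated); reduced <- unique(reduced)
  if (length(regulated) == 0L) stop("empty regulated set")
  shared <- length(intersect(regulated, reduced))
  list(fraction = shared / length(regulated),
       counts = c(regulated_only = length(regulated) - shared,
                  shared = shared,
                  reduced_only = length(reduced) - shared))
}

#' Test independence of occupancy from a perturbation
#'
#' Per locus, a 95 percent t-interval on the mean log occupancy ratio
#' (treated over control; Welch) is transformed back to the ratio scale;
#' the locus is called \code{reduced} only when the interval's upper bound
#' falls below \code{1 - margin}, i.e., when at least a margin-sized drop is
#' demonstrated, not merely not excluded. Occupancy ratios are summarized
#' by geometric means, matching the log-scale symmetry of qPCR-style data.
#'
#' @param occupancy data.frame: locus, condition, occupancy (> 0), with
#'   >= 2 replicates per condition per locus.
#' @param treated,control condition labels to compare.
#' @param margin minimal relative drop regarded as a reduction.
#' @return data.frame: locus, ratio, ci_low, ci_high, reduced.
#' @export
bindingIndependence <- function(occupancy, treated = "foxh1_MO",
                                control = "control", margin = 0.2) {
  if (any(occupancy$occupancy <= 0)) {
    bad <- occupancy$locus[occupancy$occupancy <= 0][1L]
    stop("non-positive occupancy at locus ", bad)
  }
  res <- lapply(split(occupancy, occupancy$locus), function(d) {
    x <- log(d$occupancy[d$condition == treated])
    y <- log(d$occupancy[d$condition == control])
    if (length(x) < 2L || length(y) < 2L)
      stop("need >= 2 replicates per condition at locus ", d$locus[1L])
    if (stats::sd(c(x, y)) == 0) {
      ci <- c(0, 0); est <- 0
    } else {
      tt <- stats::t.test(x, y, conf.level = 0.95)
      ci <- tt$conf.int; est <- mean(x) - mean(y)
    }
    data.frame(locus = d$locus[1L],
               ratio = exp(est),
               ci_low = exp(ci[1L]),
               ci_high = exp(ci[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$reduced <- out$ci_high < 1 - margin
  out
}
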