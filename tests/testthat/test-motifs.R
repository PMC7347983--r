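randomSeq <- function(n, len, prob = c(0.3, 0.2, 0.2, 0.3)) {
  out <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob), collapse = ""), "")
  names(out) <- sprintf("s%04d", seq_len(n))
  out
}

plantIn <- function(seqs, instance, rate, seed = 1) {
  set.seed(seed)
  for (i in seq_along(seqs)) {
    if (runif(1) < rate) {
      off <- sample.int(nchar(seqs[[i]]) - nchar(instance) + 1L, 1L)
      substr(seqs[[i]], off, off + nchar(instance) - 1L) <- instance
    }
  }
  seqs
}

test_that("dinucleotide shuffling preserves dinucleotide counts exactly", {
  set.seed(51)
  seqs <- randomSeq(10, 150)
  shuf <- makeBackground(seqs, seed = 9)
  for (i in seq_along(seqs))
    expect_equal(dinucTable(shuf[[i]]), dinucTable(seqs[[i]]))
  # determinism and pass-through
  expect_identical(makeBackground(seqs, seed = 9), shuf)
  expect_equal(unname(makeBackground(seqs, mode = "provided",
                                     provided = c(x = "ACGT"))),
               "ACGT")
  expect_error(makeBackground(c(a = "A"), seed = 1), "shorter than 2")
})

test_that("k-mer enrichment seeds on the planted motif", {
  set.seed(52)
  targets <- plantIn(randomSeq(200, 120), "AATCCACA", 0.6, seed = 2)
  bg <- randomSeq(200, 120)
  tab <- kmerEnrichment(targets, bg, 8)
  canonical <- min("AATCCACA",
                   as.character(reverseComplement(DNAString("AATCCACA"))))
  expect_equal(tab$kmer[1], canonical)
  expect_lt(tab$p[1], 1e-10)

  # no enrichment when targets equal background
  tab0 <- kmerEnrichment(bg, bg, 6)
  expect_gte(min(tab0$p), 0.5)

  expect_error(kmerEnrichment(c(a = "ACG"), bg, 6), "at least 6")
})

test_that("palindromic k-mers are counted once per sequence", {
  s <- c(one = paste0("GGGGGG", "AACGTT", "GGGGGG"))  # AACGTT is its own RC
  tab <- kmerEnrichment(s, c(b = "GGGGGGGGGGGGGGGGGG"), 6)
  row <- tab[tab$kmer == "AACGTT", ]
  expect_equal(row$n_targets, 1L)
})

test_that("EM refinement converges to planted matrices monotonically", {
  set.seed(53)
  # degenerate case: identical exact instances dominate the matrix
  targets <- plantIn(randomSeq(60, 80), "AATCCACA", 1, seed = 3)
  fit <- expandToPWM("AATCCACA", targets)
  inst <- strsplit("AATCCACA", "")[[1L]]
  for (j in seq_along(inst))
    expect_gte(fit$pwm@matrix[inst[j], j], 0.9)
  expect_true(validObject(fit$pwm))
  # penalized objective is nondecreasing
  expect_true(all(diff(fit$objective) > -1e-6))

  # noisy planted motif: recovered columns correlate with the truth
  planted <- consensusPWM("AATCCACA", soft = 0.1)
  noisy <- randomSeq(300, 100)
  set.seed(54)
  for (i in seq_along(noisy)) {
    inst <- paste(apply(planted@matrix, 2, function(p)
      sample(c("A", "C", "G", "T"), 1, prob = p)), collapse = "")
    off <- sample.int(93, 1)
    substr(noisy[[i]], off, off + 7L) <- inst
  }
  fit2 <- expandToPWM("AATCCACA", noisy)
  cors <- vapply(1:8, function(j)
    cor(fit2$pwm@matrix[, j], planted@matrix[, j]), numeric(1))
  expect_gte(mean(cors), 0.8)

  expect_error(expandToPWM("ACA", noisy), "kRange")
})

test_that("PWM scanning matches brute-force rescoring", {
  pwm <- consensusPWM("CTTTGAT")
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  mx <- maxLogOdds(pwm, bg)
  hit <- scanSequences(pwm, c(x = "GGGGCTTTGATGGGG"), mx - 1e-9, bg)
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$offset, 5L)
  expect_equal(hit$score, mx, tolerance = 1e-9)
  expect_equal(nrow(scanSequences(pwm, c(x = "GGGGCTTTGATGGGG"), mx + 1, bg)),
               0L)
  # minus-strand hit: reverse complement ATCAAAG at the same window
  hitRC <- scanSequences(pwm, c(x = "GGGGATCAAAGGGGG"), mx - 1e-9, bg)
  expect_equal(hitRC$strand, "-")
  # N windows are excluded: 9 offsets per strand, 6 touch the N
  expect_equal(nrow(scanSequences(pwm, c(x = "GGGGCTTTGNTGGGG"), -100, bg)),
               6L)

  set.seed(55)
  seqs <- randomSeq(30, 60)
  hits <- scanSequences(pwm, seqs, 0.5 * mx, bg)
  # brute force re-scan
  logodds <- log2(pwm@matrix / 0.25)
  score1 <- function(s, off, strand) {
    win <- substr(s, off, off + 6L)
    if (strand == "-")
      win <- as.character(reverseComplement(DNAString(win)))
    sum(vapply(1:7, function(j)
      logodds[substr(win, j, j), j], numeric(1)))
  }
  brute <- 0L
  for (id in names(seqs))
    for (off in 1:(nchar(seqs[[id]]) - 6L))
      for (strand in c("+", "-"))
        if (score1(seqs[[id]], off, strand) >= 0.5 * mx) brute <- brute + 1L
  expect_equal(nrow(hits), brute)
})

test_that("known-motif matching is strand-aware and identity-calibrated", {
  lib <- readPFMLibrary(system.file("extdata", "synthetic_known_motifs.jaspar",
                                    package = "maternalWnt"))
  self <- matchKnown(lib$FOXH1, lib)
  expect_equal(self$best_match, "FOXH1")
  expect_equal(self$match_score, 1, tolerance = 1e-9)

  rc <- reverseComplementPWM(lib$FOXH1)
  expect_equal(matchKnown(rc, lib)$best_match, "FOXH1")

  built <- consensusPWM("AATCCACA")
  expect_equal(matchKnown(built, lib)$best_match, "FOXH1")

  narrow <- new("PWM", matrix = matrix(0.25, 4, 3,
                                       dimnames = list(c("A", "C", "G", "T"),
                                                       NULL)),
                pseudocount = 0, name = "n")
  expect_error(matchKnown(narrow, lib), "width")
})

test_that("discovery recovers two planted motifs and stays deterministic", {
  set.seed(56)
  targets <- randomSeq(150, 100)
  targets <- plantIn(targets, "AATCCACA", 0.6, seed = 6)
  targets <- plantIn(targets, "CTTTGATT", 0.5, seed = 7)
  bg <- makeBackground(targets, seed = 8)
  lib <- readPFMLibrary(system.file("extdata", "synthetic_known_motifs.jaspar",
                                    package = "maternalWnt"))
  res <- discoverMotifs(targets, bg, motifConfig(nMotifs = 3), library = lib)
  expect_true(all(c("FOXH1") %in% res$best_match[1:2]) ||
              all(c("TCF7L2", "LEF1", "FOXH1") %in% res$best_match[1:3]))
  top3 <- res$best_match[1:min(3, nrow(res))]
  expect_true("FOXH1" %in% top3)
  expect_true(any(c("TCF7L2", "LEF1") %in% top3))
  expect_equal(res$rank, seq_len(nrow(res)))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$pct_targets >= 0 & res$pct_targets <= 100))
  for (p in attr(res, "pwms"))
    expect_true(all(abs(colSums(p@matrix) - 1) < 1e-9))

  res2 <- discoverMotifs(targets, bg, motifConfig(nMotifs = 3), library = lib)
  expect_identical(res, res2)
})

test_that("shuffled backgrounds do not yield strongly enriched motifs", {
  set.seed(57)
  for (s in 1:5) {
    seqs <- randomSeq(80, 100)
    bg <- makeBackground(seqs, seed = 100 + s)
    res <- discoverMotifs(seqs, bg, motifConfig(nMotifs = 2, kRange = 6:8))
    if (nrow(res)) expect_gte(min(res$p_value), 1e-4)
  }
})
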