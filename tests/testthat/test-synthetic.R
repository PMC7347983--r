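test_that("generated genomes are deterministic and overlap-free", {
  cfg <- smallSim()
  g1 <- generateGenome(cfg)$genes
  g2 <- generateGenome(cfg)$genes
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeGff3(g1, f1); writeGff3(g2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # brute-force all-pairs overlap check within chromosomes
  ov <- 0L
  for (cc in unique(as.character(seqnames(g1)))) {
    gi <- g1[seqnames(g1) == cc]
    s <- start(gi); e <- end(gi)
    for (i in seq_along(gi)[-1])
      ov <- ov + sum(s[seq_len(i - 1)] <= e[i] & s[i] <= e[seq_len(i - 1)])
  }
  expect_equal(ov, 0L)

  empty <- generateGenome(simConfig(nGenes = 0L, nClass1 = 0L, nClass2 = 0L))
  expect_length(empty$genes, 0L)
})

test_that("peak generation realizes the planted binding architecture", {
  cfg <- simConfig(nGenes = 30, nClass1 = 10, nClass2 = 0, decoyPeakCount = 0,
                   foxh1RateClass1 = 1)
  genome <- generateGenome(cfg)
  truth <- generateTruthTable(genome$genes, cfg)
  pk <- generatePeaks(genome$genes, truth, cfg)
  expect_length(pk$beta_catenin_st7, 10L)
  expect_length(pk$beta_catenin_st10, 0L)
  # full co-binding: every target beta-catenin peak overlaps a Foxh1 peak
  expect_true(all(countOverlaps(pk$beta_catenin_st7, pk$foxh1_st7) > 0))

  # placement window wider than the chromosome: placement must fail loudly
  tiny <- GRanges("c1", IRanges(5, 24), strand = "+",
                  seqinfo = GenomeInfoDb::Seqinfo("c1", 60L))
  mcols(tiny)$gene_id <- "g1"; mcols(tiny)$name <- "g1"; mcols(tiny)$tss <- 5
  names(tiny) <- "g1"
  t1 <- data.frame(gene_id = "g1", true_class = "class1",
                   has_st7_peak = TRUE, has_st10_peak = FALSE,
                   foxh1_cobound = FALSE, surge_onset_stage = 7)
  expect_error(generatePeaks(tiny, t1, cfg), "exceeds chromosome bounds")
})

test_that("prescribed Venn partitions are realized exactly", {
  p <- generateVennPeaks(5, 3, 2)
  v <- vennPartition(p$a, p$b)$counts
  expect_equal(unname(v[c("a_only", "shared", "b_only")]), c(5, 3, 2))
})

test_that("time courses cross the induction threshold at the planted onset", {
  cfg <- smallSim()
  genome <- generateGenome(cfg)
  truth <- generateTruthTable(genome$genes, cfg)
  tc <- generateTimecourses(truth, cfg)
  tpe <- assay(tc, "tpe")
  for (i in seq_len(nrow(truth))) {
    v <- tpe[truth$gene_id[i], ]
    if (truth$true_class[i] == "wnt_independent") {
      expect_true(max(v) < 20000)
    } else {
      expect_equal(onsetStage(v, 20000), truth$surge_onset_stage[i])
    }
  }
  expect_true(all(tpe[, "4"] < 10000))  # maternal baseline constraint
  expect_error(generateTimecourses(truth, simConfig(ceilingTPE = 9e4)),
               "ceilingTPE")
})

test_that("class1 onsets fall in the first-surge window", {
  cfg <- smallSim()
  genome <- generateGenome(cfg)
  truth <- generateTruthTable(genome$genes, cfg)
  on1 <- truth$surge_onset_stage[truth$true_class == "class1"]
  expect_true(all(on1 >= 7 & on1 <= 7.5))
  on2 <- truth$surge_onset_stage[truth$true_class == "class2"]
  expect_true(all(on2 > 8 & on2 <= 9.5))
})

test_that("count generator plants the knockdown design faithfully", {
  # null knockdown: all three condition means identical per gene
  cfg0 <- smallSim(moLog2FC = 0)
  genome <- generateGenome(cfg0)
  truth <- generateTruthTable(genome$genes, cfg0)
  ce0 <- generateCountExperiment(truth, cfg0)
  mu <- metadata(ce0)$plantedMu
  cd <- colData(ce0)
  for (st in c(8, 9)) {
    cols <- split(seq_len(ncol(ce0))[cd$stage == st],
                  cd$condition[cd$stage == st])
    expect_equal(mu[, cols$control], mu[, cols$MO])
    expect_equal(mu[, cols$control], mu[, cols$MO_rescue])
  }

  # class2 genes carry no planted effect at stage 8
  cfg <- smallSim()
  truth <- generateTruthTable(generateGenome(cfg)$genes, cfg)
  ce <- generateCountExperiment(truth, cfg)
  mu <- metadata(ce)$plantedMu; cd <- colData(ce)
  i2 <- which(truth$true_class == "class2")
  c8 <- which(cd$stage == 8 & cd$condition == "control")
  m8 <- which(cd$stage == 8 & cd$condition == "MO")
  expect_equal(mu[i2, c8], mu[i2, m8])
  # ... but do at stage 9
  c9 <- which(cd$stage == 9 & cd$condition == "control")
  m9 <- which(cd$stage == 9 & cd$condition == "MO")
  expect_true(all(mu[i2, m9] < mu[i2, c9]))
})

test_that("simulated count means match planted means (law of large numbers)", {
  cfg <- simConfig(nGenes = 5, nClass1 = 1, nClass2 = 1, nReplicates = 1000L,
                   libSizeRange = 0)
  truth <- generateTruthTable(generateGenome(cfg)$genes, cfg)
  ce <- generateCountExperiment(truth, cfg)
  mu <- metadata(ce)$plantedMu
  cd <- colData(ce)
  k <- assay(ce, "counts")
  ctrl9 <- cd$stage == 9 & cd$condition == "control"
  obs <- rowMeans(k[, ctrl9])
  planted <- mu[, which(ctrl9)[1]]
  big <- planted > 100
  expect_true(all(abs(obs[big] / planted[big] - 1) < 0.02))
})

test_that("motif planting respects rates and records a faithful implant log", {
  cfg <- simConfig(nGenes = 4, nClass1 = 1, nClass2 = 1, peakWidth = 60L)
  peaks <- GRanges("chr1", IRanges(seq(1, by = 100, length.out = 100),
                                   width = 60))
  mcols(peaks)$name <- sprintf("p%03d", 1:100)

  none <- generateSequences(peaks, simConfig(plantRateTcf = 0,
                                             plantRateFoxh1 = 0))
  expect_equal(nrow(none$implants), 0L)

  all2 <- generateSequences(peaks, simConfig(plantRateTcf = 1,
                                             plantRateFoxh1 = 1))
  expect_equal(nrow(all2$implants), 200L)

  # every logged implant is present at its offset (as planted strand)
  for (i in seq_len(50)) {
    row <- all2$implants[i, ]
    s <- as.character(all2$sequences[[row$seq_id]])
    found <- substr(s, row$offset, row$offset + nchar(row$instance) - 1L)
    want <- if (row$strand == "+") row$instance
            else as.character(reverseComplement(DNAString(row$instance)))
    expect_equal(found, want)
  }

  # determinism
  again <- generateSequences(peaks, simConfig(plantRateTcf = 1,
                                              plantRateFoxh1 = 1))
  expect_identical(as.character(again$sequences),
                   as.character(all2$sequences))

  expect_error(generateSequences(peaks, simConfig(peakWidth = 60,
                                                  tcfConsensus = paste(rep("A", 80),
                                                                       collapse = ""))),
               "longer than peak width")
})

test_that("observed planting frequency matches the binomial rate", {
  peaks <- GRanges("chr1", IRanges(seq(1, by = 70, length.out = 4000),
                                   width = 50))
  cfg <- simConfig(plantRateTcf = 0.3, plantRateFoxh1 = 0)
  res <- generateSequences(peaks, cfg)
  n <- sum(res$implants$motif == "tcf")
  ci <- qbinom(c(0.005, 0.995), 4000, 0.3)
  expect_gte(n, ci[1]); expect_lte(n, ci[2])
})
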