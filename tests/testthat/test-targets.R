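mkGenes <- function(tss, ids = paste0("g", seq_along(tss)), strand = "+") {
  g <- GRanges("chr1", IRanges(tss, tss + 999), strand = strand)
  mcols(g)$gene_id <- ids; mcols(g)$name <- ids; mcols(g)$tss <- tss
  names(g) <- ids
  g
}

test_that("peaks are assigned to the nearest TSS within the window", {
  genes <- mkGenes(c(10000, 50000))
  atTss <- GRanges("chr1", IRanges(9951, 10050))  # midpoint 10000
  asg <- assignPeaksToGenes(atTss, genes, windowBp = 1000)
  expect_equal(asg$assigned$gene_id, "g1")
  expect_equal(asg$assigned$distance, 0)

  far <- GRanges("chr1", IRanges(11002, 11002))  # midpoint window+2 away
  expect_length(assignPeaksToGenes(far, genes, windowBp = 1000)$assigned$gene_id, 0L)
  expect_equal(assignPeaksToGenes(far, genes, windowBp = 1000)$unassigned, 1L)

  # equidistant tie: lexicographically smaller gene id wins
  tied <- mkGenes(c(1000, 3000), ids = c("gB", "gA"))
  mid <- GRanges("chr1", IRanges(2000, 2000))
  expect_equal(assignPeaksToGenes(mid, tied, windowBp = 5000)$assigned$gene_id,
               "gA")
  expect_error(assignPeaksToGenes(mid, tied, windowBp = 0), "positive")
})

test_that("upstream distances are negative in gene orientation", {
  plus <- mkGenes(10000, strand = "+")
  minus <- mkGenes(10000, strand = "-")
  minus$tss <- 10999; mcols(minus)$tss <- 10999
  upstreamOfPlus <- GRanges("chr1", IRanges(9500, 9500))
  expect_lt(assignPeaksToGenes(upstreamOfPlus, plus, 5000)$assigned$distance, 0)
  downstreamish <- GRanges("chr1", IRanges(9500, 9500))
  expect_gt(assignPeaksToGenes(downstreamish, minus, 5000)$assigned$distance, 0)
})

test_that("venn partition handles degenerate set relations", {
  p <- generateVennPeaks(4, 0, 3)
  v <- vennPartition(p$a, p$b)$counts
  expect_equal(unname(v), c(4, 0, 3, 0))

  v2 <- vennPartition(p$a, p$a)$counts
  expect_equal(unname(v2), c(0, length(p$a), 0, length(p$a)))
})

test_that("venn partition counts are conserved on fuzzed inputs", {
  set.seed(31)
  sizes <- c(c1 = 1e5, c2 = 5e4)
  for (i in 1:40) {
    a <- randomIntervals(sample.int(60, 1), sizes, width = 500)
    b <- randomIntervals(sample.int(60, 1), sizes, width = 300)
    v <- vennPartition(a, b)$counts
    expect_equal(v[["a_only"]] + v[["shared"]], length(a))
    expect_equal(v[["b_only"]] + v[["shared_b"]], length(b))
    expect_equal(v[["shared"]], sum(bruteOverlap(a, b)))
    expect_equal(v[["shared_b"]], sum(bruteOverlap(b, a)))
  }
})

test_that("consensus peak filtering keeps caller-1 coordinates", {
  a <- GRanges("chr1", IRanges(c(100, 500, 900), width = 100))
  expect_identical(consensusPeaks(a, a), a)
  b <- GRanges("chr1", IRanges(5000, 5100))
  expect_length(consensusPeaks(a, b), 0L)
  nested <- GRanges("chr1", IRanges(120, 130))
  expect_identical(consensusPeaks(a, nested), a[1])
})

test_that("direct-target classes follow binding persistence and timing", {
  reg <- function(ids, all) data.frame(gene_id = all, stage = 9,
                                       regulated = all %in% ids)
  asg <- function(ids) list(assigned = data.frame(gene_id = ids),
                            unassigned = integer(0))
  all <- c("gA", "gB", "gC", "gD")
  surge <- data.frame(gene_id = all,
                      surge = c("first", "second", "second", "none"))
  tc <- classifyDirectTargets(
    regulatedSt8 = reg("gA", all),
    regulatedSt9 = reg(c("gA", "gB", "gC"), all),
    surgeCalls = surge,
    assignmentsSt7 = asg(c("gA", "gB")),
    assignmentsSt10 = asg("gB"))
  expect_equal(tc$target_class[tc$gene_id == "gA"], "class1")
  expect_equal(tc$target_class[tc$gene_id == "gB"], "class2")
  expect_equal(tc$target_class[tc$gene_id == "gC"], "indirect")
  expect_equal(tc$target_class[tc$gene_id == "gD"], "not_regulated")

  # st8-regulated but not st9: logged as a Venn violation
  tv <- classifyDirectTargets(reg(c("gA", "gD"), all),
                              reg(c("gA", "gB"), all),
                              surge, asg("gA"), asg(character(0)))
  expect_equal(attr(tv, "venn_violations"), "gD")
})

test_that("target classes partition the regulated gene set", {
  cfg <- smallSim()
  st <- simulateStudy(cfg)
  sc <- classifySurge(st$timecourses)
  r8 <- callRegulatedGenes(st$countsBcat, 8)
  r9 <- callRegulatedGenes(st$countsBcat, 9)
  a7 <- assignPeaksToGenes(st$peaks$beta_catenin_st7, st$genes)
  a10 <- assignPeaksToGenes(st$peaks$beta_catenin_st10, st$genes)
  tc <- classifyDirectTargets(r8, r9, sc, a7, a10)
  regulated <- tc$regulated_st8 | tc$regulated_st9
  expect_true(all(tc$target_class[regulated] %in%
                  c("class1", "class2", "direct_other", "indirect")))
  expect_true(all(tc$target_class[!regulated] == "not_regulated"))
})
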