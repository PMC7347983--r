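test_that("loop classification agrees with the exhaustive sign-pattern table", {
  # independent oracle: coherence by the sign-product rule, type by the
  # (W->A, A->B) pattern
  patterns <- expand.grid(wa = c("+", "-"), wb = c("+", "-"),
                          ab = c("+", "-"), stringsAsFactors = FALSE)
  toNum <- function(s) ifelse(s == "+", 1, -1)
  for (i in seq_len(nrow(patterns))) {
    p <- patterns[i, ]
    want <- paste0(
      if (toNum(p$wb) == toNum(p$wa) * toNum(p$ab)) "coherent_type"
      else "incoherent_type",
      c("++" = 1, "-+" = 2, "+-" = 3, "--" = 4)[paste0(p$wa, p$ab)])
    expect_equal(fflClassify(p$wa, p$wb, p$ab), unname(want))
  }
  # the all-activator loop is the canonical coherent type 1
  expect_equal(fflClassify("+", "+", "+"), "coherent_type1")
  expect_error(fflClassify("+", NA, "+"), "signs")
  expect_error(fflClassify("+", "0", "+"), "signs")
})

test_that("intermediate-factor knockdown separates the two target classes", {
  cfg <- simConfig(nGenes = 150, nClass1 = 8, nClass2 = 40,
                   decoyPeakCount = 0)
  truth <- generateTruthTable(generateGenome(cfg)$genes, cfg)
  ce <- generateCountExperiment(truth, cfg, knockdown = "sia")
  ep <- knockdownEpistasisCall(ce, data.frame(gene_id = truth$gene_id,
                                              true_class = truth$true_class))
  isC2 <- ep$class_label == "class2"
  expect_gte(mean(ep$ffl_consistent[isC2]), 0.9)
  expect_length(attr(ep, "class1_affected_at_st8"), 0L)
  expect_true(attr(ep, "class1_unaffected_at_st8"))

  # no planted effects: consistency calls collapse to chance level
  cfg0 <- simConfig(nGenes = 150, nClass1 = 8, nClass2 = 40, moLog2FC = 0)
  truth0 <- generateTruthTable(generateGenome(cfg0)$genes, cfg0)
  ce0 <- generateCountExperiment(truth0, cfg0, knockdown = "sia")
  ep0 <- knockdownEpistasisCall(ce0, data.frame(gene_id = truth0$gene_id,
                                                true_class = truth0$true_class))
  expect_lte(mean(ep0$ffl_consistent[ep0$class_label == "class2"]), 0.05)
})

test_that("a first-class gene responding to the knockdown is flagged", {
  cfg <- simConfig(nGenes = 100, nClass1 = 5, nClass2 = 20)
  truth <- generateTruthTable(generateGenome(cfg)$genes, cfg)
  ce <- generateCountExperiment(truth, cfg, knockdown = "sia")
  k <- assay(ce, "counts")
  cd <- colData(ce)
  g1 <- truth$gene_id[truth$true_class == "class1"][1]
  mo8 <- cd$stage == 8 & cd$condition == "sia_MO"
  k[g1, mo8] <- k[g1, mo8] %/% 15L
  ce2 <- CountExperiment(k, cd$condition, cd$stage)
  ep <- knockdownEpistasisCall(ce2, data.frame(gene_id = truth$gene_id,
                                               true_class = truth$true_class))
  expect_true(g1 %in% attr(ep, "class1_affected_at_st8"))
  # the violation invalidates feedforward consistency across the experiment
  expect_false(any(ep$ffl_consistent))
})

test_that("epistasis calls are invariant to gene and sample order", {
  cfg <- simConfig(nGenes = 80, nClass1 = 4, nClass2 = 15)
  truth <- generateTruthTable(generateGenome(cfg)$genes, cfg)
  ce <- generateCountExperiment(truth, cfg, knockdown = "sia")
  labels <- data.frame(gene_id = truth$gene_id,
                       true_class = truth$true_class)
  ep1 <- knockdownEpistasisCall(ce, labels)

  set.seed(61)
  gperm <- sample.int(nrow(ce)); sperm <- sample.int(ncol(ce))
  k <- assay(ce, "counts")[gperm, sperm]
  ce2 <- CountExperiment(k, colData(ce)$condition[sperm],
                         colData(ce)$stage[sperm])
  ep2 <- knockdownEpistasisCall(ce2, labels)
  ep2 <- ep2[match(ep1$gene_id, ep2$gene_id), ]
  rownames(ep2) <- NULL
  expect_equal(ep1$ffl_consistent, ep2$ffl_consistent)
  expect_equal(ep1$affected_at_st9, ep2$affected_at_st9)
})
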