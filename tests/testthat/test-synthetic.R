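test_that("designArray tiles windows at the design spacing", {
  # one 20 kb gene, 5 kb pad, 200 bp spacing -> 30 kb window, 150 probes
  p <- arrayDesignParams(nGenes = 1L, geneLengthRange = c(20000L, 20000L),
                         probeSpacingBp = 200L, padBp = 5000L)
  des <- designArray(p, seed = 1L)
  expect_equal(length(des$probes), 150L)
  expect_equal(GenomicRanges::width(windowRanges(des$windows)), 30000L)

  # spacing larger than the window still emits at least one probe
  pBig <- arrayDesignParams(nGenes = 1L, geneLengthRange = c(2000L, 2000L),
                            probeSpacingBp = 50000L, padBp = 0L)
  expect_gte(length(designArray(pBig, seed = 1L)$probes), 1L)

  # determinism
  d1 <- designArray(arrayDesignParams(nGenes = 5L), seed = 9L)
  d2 <- designArray(arrayDesignParams(nGenes = 5L), seed = 9L)
  expect_identical(d1$windows, d2$windows)
  expect_identical(d1$probes, d2$probes)

  # flank probes exist outside every window and carry no gene
  dF <- designArray(arrayDesignParams(nGenes = 2L, flankBp = 10000L),
                    seed = 2L, includeFlanks = TRUE)
  expect_true(any(is.na(S4Vectors::mcols(dF$probes)$gene_symbol)))
})

test_that("noiseless implants shift exactly their probes, rest stays zero", {
  des <- designArray(arrayDesignParams(nGenes = 4L,
                                       geneLengthRange = c(15000L, 25000L)),
                     seed = 5L)
  prm <- cohortSimParams(nSamples = 6L, noiseSd = 0, microRate = 1.0,
                         macroRate = 0.3, seed = 5L)
  co <- suppressMessages(simulateCohort(des$windows, des$probes, prm))
  vals <- SummarizedExperiment::assay(logRatios(co), "log2ratio")
  pr <- SummarizedExperiment::rowRanges(logRatios(co))
  tr <- as.data.frame(truthRecords(co))
  expect_gt(nrow(tr), 0L)
  expected <- matrix(0, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  for (i in seq_len(nrow(tr))) {
    idx <- which(S4Vectors::mcols(pr)$gene_symbol == tr$gene_symbol[i] &
                   GenomicRanges::start(pr) >= tr$start[i] &
                   GenomicRanges::start(pr) <= tr$end[i])
    eff <- if (tr$kind[i] %in% c("macro-gain", "micro-amp")) 0.6 else -0.6
    expected[idx, tr$sample_id[i]] <- expected[idx, tr$sample_id[i]] + eff
  }
  expect_equal(vals, expected)
})

test_that("no implants means pure noise and empty truth", {
  des <- designArray(arrayDesignParams(nGenes = 8L,
                                       geneLengthRange = c(10000L, 30000L)),
                     seed = 21L)
  prm <- cohortSimParams(nSamples = 30L, noiseSd = 0.15, microRate = 0,
                         macroRate = 0, seed = 21L)
  co <- simulateCohort(des$windows, des$probes, prm)
  expect_equal(nrow(truthRecords(co)), 0L)
  vals <- SummarizedExperiment::assay(logRatios(co), "log2ratio")
  # fraction with |log2| > 0.30 under N(0, 0.15): 2*pnorm(-2) ~ 0.0455
  frac <- mean(abs(vals) > 0.30)
  se <- sqrt(0.0455 * (1 - 0.0455) / length(vals))
  expect_lt(abs(frac - 2 * pnorm(-2)), 4 * se)
})

test_that("same seed reproduces the cohort bit-identically", {
  des <- designArray(arrayDesignParams(nGenes = 3L), seed = 7L)
  prm <- cohortSimParams(nSamples = 8L, seed = 7L)
  c1 <- suppressMessages(simulateCohort(des$windows, des$probes, prm))
  c2 <- suppressMessages(simulateCohort(des$windows, des$probes, prm))
  expect_identical(SummarizedExperiment::assay(logRatios(c1), "log2ratio"),
                   SummarizedExperiment::assay(logRatios(c2), "log2ratio"))
  expect_identical(as.data.frame(truthRecords(c1)),
                   as.data.frame(truthRecords(c2)))
  expect_identical(as.data.frame(clinicalData(c1)),
                   as.data.frame(clinicalData(c2)))
})

test_that("truth summary conserves implant counts", {
  co <- smallCohort()
  ts <- truthSummary(co)
  tr <- as.data.frame(truthRecords(co))
  expect_equal(sum(ts$perSample$total), nrow(tr))
  expect_equal(sum(ts$perGene$total), nrow(tr))
  kinds <- c("macro-gain", "macro-loss", "micro-amp", "micro-del")
  expect_equal(colSums(ts$perSample[, kinds]),
               colSums(ts$perGene[, kinds]))

  # empty truth -> all-zero table
  des <- designArray(arrayDesignParams(nGenes = 2L), seed = 3L)
  co0 <- simulateCohort(des$windows, des$probes,
                        cohortSimParams(nSamples = 4L, microRate = 0,
                                        macroRate = 0, seed = 3L))
  expect_equal(sum(truthSummary(co0)$perSample$total), 0L)
})

test_that("full expression coupling puts every micro-amp sample above the median", {
  des <- designArray(arrayDesignParams(nGenes = 10L,
                                       geneLengthRange = c(10000L, 30000L)),
                     seed = 13L)
  prm <- cohortSimParams(nSamples = 96L, exprCoupling = 1, exprShift = 5,
                         macroRate = 0, seed = 13L)
  co <- suppressMessages(simulateCohort(des$windows, des$probes, prm))
  tr <- as.data.frame(truthRecords(co))
  # cells carrying implants of both signs have no defined direction
  key <- paste(tr$gene_symbol, tr$sample_id)
  delKeys <- key[tr$kind %in% c("micro-del", "macro-loss")]
  amp <- tr[tr$kind == "micro-amp" & !(key %in% delKeys), ]
  vals <- SummarizedExperiment::assay(expressionData(co), "expr")
  med <- apply(vals, 1, median)
  above <- mapply(function(g, s) vals[g, s] > med[g],
                  amp$gene_symbol, amp$sample_id)
  expect_true(all(above))
})

test_that("five-prime bias mode concentrates micro implants in the 5'End quadrant", {
  des <- designArray(arrayDesignParams(nGenes = 10L,
                                       geneLengthRange = c(20000L, 60000L)),
                     seed = 17L)
  prm <- cohortSimParams(nSamples = 40L, fivePrimeBias = TRUE, macroRate = 0,
                         seed = 17L)
  co <- suppressMessages(simulateCohort(des$windows, des$probes, prm))
  tr <- as.data.frame(truthRecords(co))
  in5 <- grepl("5'End", tr$quadrants, fixed = TRUE)
  expect_gt(mean(in5), 0.95)
})
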