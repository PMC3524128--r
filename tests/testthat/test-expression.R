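test_that("dichotomization labels values about the per-gene median", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  d <- dichotomizeExpression(m)
  expect_equal(unname(d["g1", ]), c("below", "at", "above"))
  expect_equal(unname(d["g2", ]), rep("at", 3))
  # even count: midpoint median
  d2 <- dichotomizeExpression(rbind(g = c(1, 2, 3, 4)))
  expect_equal(unname(d2["g", ]), c("below", "below", "above", "above"))
  # genes with < 3 present values are excluded with a message
  m3 <- rbind(ok = c(1, 2, 3, 4), sparse = c(1, 2, NA, NA))
  expect_message(d3 <- dichotomizeExpression(m3), "fewer than 3")
  expect_equal(rownames(d3), "ok")
})

test_that("gene concordance counts 100% and >=50% concordant genes", {
  status <- rbind(
    gA = c("micro-amp", "micro-amp", "none", "none"),
    gB = c("micro-amp", "micro-amp", "none", "none"),
    gC = c("none", "none", "none", "none"))
  colnames(status) <- sprintf("s%d", 1:4)
  dicho <- rbind(
    gA = c("above", "above", "below", "below"),
    gB = c("above", "below", "below", "above"),
    gC = c("above", "below", "above", "below"))
  colnames(dicho) <- colnames(status)
  cs <- geneConcordance(status, dicho)
  amp <- cs[cs$class == "micro-amp", ]
  expect_equal(amp$n_genes_with_class, 2L)  # gC never bears the class
  expect_equal(amp$n_100pct, 1L)            # gA fully concordant
  expect_equal(amp$n_ge50pct, 2L)           # gB half concordant
  # invariant on random data: n_100 <= n_ge50 <= denominator
  set.seed(42)
  for (r in 1:5) {
    st <- matrix(sample(c("micro-amp", "micro-del", "gross-gain", "gross-loss",
                          "none"), 60, TRUE, prob = c(.1, .1, .1, .1, .6)),
                 6, 10, dimnames = list(sprintf("g%d", 1:6), sprintf("s%d", 1:10)))
    dc <- matrix(sample(c("above", "below", "at"), 60, TRUE),
                 6, 10, dimnames = dimnames(st))
    out <- geneConcordance(st, dc)
    expect_true(all(out$n_100pct <= out$n_ge50pct))
    expect_true(all(out$n_ge50pct <= out$n_genes_with_class))
  }
})

test_that("pooled contingency pools pairs and excludes at-median entries", {
  status <- rbind(g1 = c("micro-amp", "none", "none"),
                  g2 = c("none", "micro-amp", "none"))
  colnames(status) <- sprintf("s%d", 1:3)
  dicho <- rbind(g1 = c("above", "below", "at"),
                 g2 = c("below", "above", "below"))
  colnames(dicho) <- colnames(status)
  tb <- pooledContingency(status, dicho, "micro-amp")
  expect_equal(tb["above", "present"], 2L)
  expect_equal(tb["below", "present"], 0L)
  expect_equal(sum(tb), 5L)  # the "at" pair is excluded
  # empty input
  tb0 <- pooledContingency(status[0, , drop = FALSE], dicho[0, , drop = FALSE],
                           "any-micro")
  expect_equal(sum(tb0), 0L)
})

test_that("fisherExact2x2 matches enumeration, conventions and fisher.test", {
  # closed-form check: [3,1;1,3] has two-sided p = 34/70
  expect_equal(fisherExact2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  # zero margin convention
  expect_equal(fisherExact2x2(0, 5, 0, 7), 1)
  expect_equal(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  # invariance to swapping both rows and both columns
  set.seed(3)
  for (r in 1:10) {
    x <- matrix(rpois(4, 8), 2)
    expect_equal(fisherExact2x2(x), fisherExact2x2(x[2:1, 2:1]))
  }
  # agreement with the reference implementation on a grid
  for (a in c(0, 2, 7)) for (b in c(1, 5)) for (cc in c(0, 3)) for (d in c(2, 9)) {
    tab <- matrix(c(a, b, cc, d), 2, byrow = TRUE)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      expect_equal(fisherExact2x2(tab), fisher.test(tab)$p.value,
                   tolerance = 1e-9)
  }
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("two-group ANOVA matches closed-form and handles degenerate groups", {
  res <- anovaByStatus(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$F, 13.5, tolerance = 1e-12)
  expect_equal(res$p, pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # identical groups: F = 0, p = 1
  res0 <- anovaByStatus(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # large shift: decisive
  set.seed(1)
  resBig <- anovaByStatus(c(rnorm(10), rnorm(10, 10)), rep(c("a", "b"), each = 10))
  expect_lt(resBig$p, 0.001)
  # a group below 2 samples is NA with warning
  expect_warning(resNA <- anovaByStatus(c(1, 2, 3), c("a", "b", "b")), "at least 2")
  expect_true(is.na(resNA$F))
})

test_that("full coupling yields directional pooled tables with small p", {
  des <- designArray(arrayDesignParams(nGenes = 10L,
                                       geneLengthRange = c(10000L, 30000L)),
                     seed = 19L)
  co <- suppressMessages(simulateCohort(
    des$windows, des$probes,
    cohortSimParams(nSamples = 48L, exprCoupling = 1, exprShift = 3,
                    macroRate = 0.3, seed = 19L)))
  seg <- segmentCohort(logRatios(co))
  calls <- callAberrations(seg)
  dicho <- dichotomizeExpression(expressionData(co))
  tbAmp <- pooledContingency(calls$status, dicho, "micro-amp")
  tbDel <- pooledContingency(calls$status, dicho, "micro-del")
  # micro-amps concentrate above the median, micro-dels below
  expect_gt(tbAmp["above", "present"], tbAmp["below", "present"])
  expect_gt(tbDel["below", "present"], tbDel["above", "present"])
  expect_lt(fisherExact2x2(tbAmp), 0.05)
  expect_lt(fisherExact2x2(tbDel), 0.05)
})

test_that("per-gene ANOVA table covers testable genes only", {
  co <- smallCohort()
  calls <- smallCalls()
  tab <- perGeneAnova(expressionData(co), calls$status)
  expect_true(all(tab$n_aberrant >= 2L))
  expect_true(all(tab$F >= 0))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
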