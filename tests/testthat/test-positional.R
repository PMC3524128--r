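# windows helper with explicit spans and no pad
exactWindows <- function(df) geneWindowsFromTable(df, padBp = 0L)

test_that("quadrant bounds partition the window and orient by strand", {
  gw <- exactWindows(data.frame(
    gene = c("P", "M"), chrom = "chr1", strand = c("+", "-"),
    gene_start = c(1L, 10001L), gene_end = c(4000L, 14000L)))
  qp <- quadrantBounds(gw, "P")
  expect_equal(qp$label, c("5'End", "5'Mid", "3'Mid", "3'End"))
  expect_equal(qp$start, c(1L, 1001L, 2001L, 3001L))
  expect_equal(qp$end, c(1000L, 2000L, 3000L, 4000L))
  # minus strand: 5'End is the rightmost interval
  qm <- quadrantBounds(gw, "M")
  expect_equal(qm$start[qm$label == "5'End"], 13001L)
  expect_equal(qm$end[qm$label == "5'End"], 14000L)

  # non-divisible width: floor boundaries, oriented 3'End absorbs remainder
  gw2 <- exactWindows(data.frame(gene = "R", chrom = "chr1", strand = "+",
                                 gene_start = 1L, gene_end = 4002L))
  qr <- quadrantBounds(gw2, "R")
  expect_equal(qr$end[qr$label == "3'End"] - qr$start[qr$label == "3'End"] + 1L,
               1002L)
  # partition: no gaps, no overlaps, union is the window
  g <- qr[order(qr$start), ]
  expect_equal(g$start[-1], g$end[-4] + 1L)
  expect_equal(sum(g$end - g$start + 1L), 4002L)

  expect_error(quadrantBounds(gw, "nope"), "unknown gene")
})

test_that("quadrant tallies match a per-base brute-force oracle", {
  set.seed(88)
  for (r in 1:6) {
    L <- sample(2000:9000, 1)
    strand <- sample(c("+", "-"), 1)
    gw <- exactWindows(data.frame(gene = "G", chrom = "chr1", strand = strand,
                                  gene_start = 1000L, gene_end = 1000L + L - 1L))
    n <- 8L
    a <- sample(1000:(1000 + L - 50), n)
    b <- pmin(a + sample(10:2000, n, replace = TRUE), 1000L + L - 1L)
    micros <- data.frame(Gene = "G", Start = a, Stop = b)
    got <- tallyQuadrants(micros, gw)
    qb <- quadrantBounds(gw, "G")
    for (qi in 1:4) {
      bases <- qb$start[qi]:qb$end[qi]
      want <- sum(vapply(seq_len(n), function(j) any(a[j]:b[j] %in% bases),
                         logical(1)))
      expect_equal(got$quadrants$affected[got$quadrants$label == qb$label[qi]],
                   want)
    }
    expect_true(all(got$quadrants$possible == n))
    # every instance lies in the window, so it overlaps at least one quadrant
    expect_true(all(rowSums(got$flags[, 1:4]) >= 1))
  }
})

test_that("whole-window and confined instances give extreme proportions", {
  gw <- tinyWindows()
  gr <- windowRanges(gw)
  ws <- GenomicRanges::start(gr)[1]; we <- GenomicRanges::end(gr)[1]
  # one instance spanning the whole window: all proportions 1
  tq <- tallyQuadrants(data.frame(Gene = "GA", Start = ws, Stop = we), gw)
  expect_equal(tq$quadrants$proportion, rep(1, 4))
  # two instances confined to the 5'End quadrant
  q5 <- quadrantBounds(gw, "GA")
  q5 <- q5[q5$label == "5'End", ]
  m <- data.frame(Gene = "GA", Start = c(q5$start, q5$start + 10L),
                  Stop = c(q5$start + 100L, q5$start + 200L))
  tq2 <- tallyQuadrants(m, gw)
  expect_equal(tq2$quadrants$proportion,
               c(1, 0, 0, 0)[match(tq2$quadrants$label,
                                   c("5'End", "5'Mid", "3'Mid", "3'End"))])
})

test_that("quadrant summary is invariant under mirror + strand flip", {
  C <- 200000L
  df <- data.frame(gene = "G", chrom = "chr1", strand = "+",
                   gene_start = 10001L, gene_end = 33123L)
  gw <- exactWindows(df)
  set.seed(5)
  a <- sample(10001:30000, 10L)
  b <- pmin(a + sample(50:4000, 10L, replace = TRUE), 33123L)
  micros <- data.frame(Gene = "G", Start = a, Stop = b)
  t1 <- tallyQuadrants(micros, gw)

  dfm <- data.frame(gene = "G", chrom = "chr1", strand = "-",
                    gene_start = C - 33123L, gene_end = C - 10001L)
  gwm <- exactWindows(dfm)
  mirrored <- data.frame(Gene = "G", Start = C - b, Stop = C - a)
  t2 <- tallyQuadrants(mirrored, gwm)
  expect_equal(t1$quadrants, t2$quadrants)
  expect_equal(t1$promoter_rate, t2$promoter_rate)
})

test_that("promoter and 5'UTR overlap follow strand orientation", {
  gw <- tinyWindows()  # 5 kb pad, GA on +, GB on -
  gr <- windowRanges(gw)
  # instance entirely in GA's upstream pad touches the promoter
  tq <- tallyQuadrants(data.frame(Gene = "GA", Start = 6000L, Stop = 7000L), gw)
  expect_equal(tq$promoter_rate, 1)
  # same coordinates relative to GB (minus strand): promoter is on the right
  upstartB <- 70001L
  tqB <- tallyQuadrants(data.frame(Gene = "GB", Start = upstartB + 100L,
                                   Stop = upstartB + 400L), gw)
  expect_equal(tqB$promoter_rate, 1)
  # 5'UTR overlap uses the recorded utr5 coordinates
  tqU <- tallyQuadrants(data.frame(Gene = "GA", Start = 10100L, Stop = 10150L), gw)
  expect_equal(tqU$utr5_rate, 1)
  expect_error(tallyQuadrants(data.frame(Gene = "ZZ", Start = 1L, Stop = 2L), gw),
               "unknown gene")
})

test_that("five-prime-only breakdown restricts to 5'End-only instances", {
  gw <- tinyWindows()
  q <- quadrantBounds(gw, "GA")
  q5 <- q[q$label == "5'End", ]
  # no 5'End-only instances -> NA rates
  mid <- q[q$label == "3'Mid", ]
  none <- fivePrimeOnlyBreakdown(
    data.frame(Gene = "GA", Start = mid$start, Stop = mid$end), gw)
  expect_equal(none$n, 0L)
  expect_true(is.na(none$promoter_rate))
  # one 5'End-only instance inside the promoter interval
  one <- fivePrimeOnlyBreakdown(
    data.frame(Gene = "GA", Start = 6000L, Stop = 7000L), gw)
  expect_equal(one$n, 1L)
  expect_equal(one$promoter_rate, 1)
  # an instance spanning two quadrants is excluded from the restriction
  two <- fivePrimeOnlyBreakdown(
    data.frame(Gene = "GA", Start = c(6000L, q5$end - 10L),
               Stop = c(7000L, q5$end + 500L)), gw)
  expect_equal(two$n, 1L)
})

test_that("biased synthetic cohorts show 5' concentration in the tallies", {
  des <- designArray(arrayDesignParams(nGenes = 8L,
                                       geneLengthRange = c(20000L, 50000L)),
                     seed = 31L)
  co <- suppressMessages(simulateCohort(
    des$windows, des$probes,
    cohortSimParams(nSamples = 30L, fivePrimeBias = TRUE, macroRate = 0,
                    seed = 31L)))
  seg <- segmentCohort(logRatios(co))
  calls <- callAberrations(seg)
  tq <- tallyQuadrants(calls$micro, geneWindows(co))
  p <- tq$quadrants$proportion
  names(p) <- tq$quadrants$label
  expect_gt(p[["5'End"]], max(p[c("3'Mid", "3'End")]))
  # implants centred upstream of the tss touch the promoter more than the UTR
  expect_gt(tq$promoter_rate, tq$utr5_rate)
})
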