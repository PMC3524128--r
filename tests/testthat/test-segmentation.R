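# exhaustive Welch-scan oracle for bestSplit
bruteBestSplit <- function(v, minProbes) {
  n <- length(v)
  best <- list(index = NA_integer_, statistic = -Inf)
  for (k in minProbes:(n - minProbes)) {
    xl <- v[1:k]; xr <- v[(k + 1):n]
    dn <- sqrt(var(xl) / k + var(xr) / (n - k))
    dm <- abs(mean(xl) - mean(xr))
    st <- if (dn > 0) dm / dn else if (dm > 0) Inf else 0
    if (st > best$statistic) best <- list(index = k, statistic = st)
  }
  best
}

test_that("bestSplit finds exact steps and matches the exhaustive scan", {
  bs <- bestSplit(c(rep(0, 5), rep(1, 5)), minProbes = 2L)
  expect_equal(bs$index, 5L)
  expect_equal(bs$statistic, Inf)

  # constant vector: statistic 0 everywhere
  expect_equal(bestSplit(rep(2, 20), minProbes = 3L)$statistic, 0)

  # too short to split
  expect_true(is.na(bestSplit(c(1, 2, 3), minProbes = 2L)$index))

  # random vectors of length 30 match the brute-force scan
  for (s in 1:10) {
    set.seed(s)
    v <- rnorm(30)
    got <- bestSplit(v, minProbes = 4L)
    want <- bruteBestSplit(v, 4L)
    expect_equal(got$index, want$index)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  }
})

test_that("segmentGeneProfile recovers noiseless breakpoints exactly", {
  prm <- segmentationParams()
  pos <- seq(1L, by = 200L, length.out = 200L)

  # flat profile: one neutral segment
  seg <- segmentGeneProfile(rep(0, 200), pos, prm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$call, "neutral")
  expect_equal(seg$n_probes, 200L)

  # noiseless step at probe 100 -> two segments, the second a gain
  v <- c(rep(0, 100), rep(0.6, 100))
  seg <- segmentGeneProfile(v, pos, prm)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$probe_end[1], 100L)
  expect_equal(seg$call, c("neutral", "gain"))

  # runs of <= 50 probes with <= 2 implanted breakpoints, zero noise:
  # recovered boundaries equal the implanted ones exactly
  cases <- list(
    list(n = 50L, bp = c(20L), levels = c(0, -0.8)),
    list(n = 40L, bp = c(10L, 30L), levels = c(0, 0.7, 0)),
    list(n = 48L, bp = c(24L), levels = c(0.5, -0.5)),
    list(n = 50L, bp = c(15L, 35L), levels = c(-0.6, 0, 0.6))
  )
  for (cs in cases) {
    lens <- diff(c(0L, cs$bp, cs$n))
    v <- rep(cs$levels, lens)
    seg <- segmentGeneProfile(v, seq_len(cs$n), prm)
    expect_equal(seg$probe_end[-nrow(seg)], cs$bp)
  }
})

test_that("profiles shorter than minProbes give a single segment", {
  seg <- segmentGeneProfile(c(0.9, 0.8, 0.85), c(10L, 20L, 30L),
                            segmentationParams())
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$call, "gain")
})

test_that("noisy steps are recovered within +/-2 probes in >=90% of replicates", {
  prm <- segmentationParams()
  pos <- seq_len(200L)
  hit <- logical(50)
  set.seed(2024)
  for (r in seq_len(50)) {
    v <- rnorm(200, 0, 0.15)
    v[80:119] <- v[80:119] + 0.6
    seg <- segmentGeneProfile(v, pos, prm)
    b <- seg$probe_end[-nrow(seg)]
    hit[r] <- any(abs(b - 79L) <= 2L) && any(abs(b - 119L) <= 2L)
  }
  expect_gte(mean(hit), 0.9)
})

test_that("segments tile the probe run without gaps or overlaps", {
  set.seed(99)
  for (r in 1:5) {
    n <- sample(20:300, 1)
    v <- rnorm(n, 0, 0.2)
    if (n > 40) v[10:25] <- v[10:25] + 0.8
    seg <- segmentGeneProfile(v, seq_len(n), segmentationParams())
    expect_equal(seg$probe_start[1], 0L)
    expect_equal(seg$probe_end[nrow(seg)], n)
    if (nrow(seg) > 1)
      expect_equal(seg$probe_start[-1], seg$probe_end[-nrow(seg)])
    expect_equal(sum(seg$n_probes), n)
  }
})

test_that("lowering the split threshold never decreases the segment count", {
  set.seed(7)
  for (r in 1:5) {
    v <- rnorm(150, 0, 0.15)
    v[40:70] <- v[40:70] + 0.5
    counts <- vapply(c(8, 6, 4, 2), function(th) {
      nrow(segmentGeneProfile(v, seq_len(150),
                              segmentationParams(splitStatThreshold = th)))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("aberrant segments use a strict 0.30 cutoff", {
  seg <- data.frame(sample = "s", gene = "g", chrom = "c",
                    probe_start = 0L, probe_end = 10L, start = 1L, end = 10L,
                    n_probes = 10L,
                    mean_log2 = c(0.30, -0.31, 0.29, 0.35, -0.30),
                    call = c("neutral", "loss", "neutral", "gain", "neutral"),
                    stringsAsFactors = FALSE)
  ab <- aberrantSegments(seg, segmentationParams())
  expect_equal(ab$mean_log2, c(-0.31, 0.35))
  expect_equal(nrow(aberrantSegments(seg[0, ], segmentationParams())), 0L)
})

test_that("segmentCohort skips missing values per sample", {
  co <- smallCohort()
  se <- logRatios(co)[, 1:2]
  vals <- SummarizedExperiment::assay(se, "log2ratio")
  vals[3:5, 1] <- NA
  SummarizedExperiment::assays(se)$log2ratio <- vals
  seg <- segmentCohort(se)
  firstGene <- S4Vectors::mcols(SummarizedExperiment::rowRanges(se))$gene_symbol[1]
  nProbesGene <- sum(
    S4Vectors::mcols(SummarizedExperiment::rowRanges(se))$gene_symbol == firstGene)
  s1 <- seg[seg$gene == firstGene & seg$sample == colnames(vals)[1], ]
  expect_equal(sum(s1$n_probes), nProbesGene - 3L)
})
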