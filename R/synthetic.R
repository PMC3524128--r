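#' Array design parameters
#'
#' Parameters of the simulated gene-centric tiling array. Defaults mirror
#' the study design the generator emulates: 128 gene windows tiled at
#' 200 bp spacing, gene spans padded by 5 kb, with optional +/- 150 kb
#' flanking probes (array content outside every analysis window).
#'
#' @param nGenes Number of genes (default 128).
#' @param probeSpacingBp Probe spacing in bp (default 200).
#' @param geneLengthRange Two-element bp interval for gene lengths
#'   (default 10-100 kb).
#' @param padBp Analysis window padding in bp (default 5000).
#' @param flankBp Flank size in bp tiled outside the window when
#'   `includeFlanks = TRUE` in [designArray()] (default 150000).
#' @return A validated parameter list of class `ArrayDesignParams`.
#' @export
arrayDesignParams <- function(nGenes = 128L, probeSpacingBp = 200L,
                              geneLengthRange = c(10000L, 100000L),
                              padBp = 5000L, flankBp = 150000L) {
  stopifnot(nGenes >= 1L, probeSpacingBp > 0L,
            length(geneLengthRange) == 2L, all(geneLengthRange > 0L),
            geneLengthRange[1L] <= geneLengthRange[2L],
            padBp >= 0L, flankBp >= 0L)
  structure(list(nGenes = as.integer(nGenes),
                 probeSpacingBp = as.integer(probeSpacingBp),
                 geneLengthRange = as.integer(geneLengthRange),
                 padBp = as.integer(padBp), flankBp = as.integer(flankBp)),
            class = "ArrayDesignParams")
}

#' Cohort simulation parameters
#'
#' Statistical structure of the synthetic cohort: per-probe Gaussian
#' noise, Poisson-distributed macro (whole-window) and micro (< 64
#' probe-equivalent) implants with fixed log2 effects, expression shifts
#' coupled to copy-number status, and exponential survival whose hazard
#' scales with the sample's micro-aberration tercile.
#'
#' Defaults reflect the cohort the generator emulates: 96 samples
#' (94 tumors + 2 cell lines), noise SD 0.15 log2 units, about 3.5 micro
#' implants per sample (the study cohort's weighted mean), |effect| 0.6,
#' and micro spans of 1-12 kb so that every implanted micro event stays
#' below the 64-probe cutoff at 200 bp spacing.
#'
#' @param nSamples Number of samples (default 96).
#' @param noiseSd Per-probe log2 noise SD (default 0.15).
#' @param macroRate Expected macro implants per sample (default 1).
#' @param microRate Expected micro implants per sample (default 3.5).
#' @param microSpanRange Two-element bp interval for micro spans
#'   (default 1000-12000).
#' @param ampEffect,delEffect Mean log2 shift of amplified/deleted probes
#'   (defaults +0.6 / -0.6).
#' @param exprCoupling Probability an implant shifts the gene's
#'   expression concordantly in that sample (default 0.7).
#' @param exprShift Magnitude of the concordant expression shift, in SD
#'   units of the expression baseline (default 1.5).
#' @param survivalHazardRatio Hazard multiplier per micro-count tercile
#'   (default 2).
#' @param censorRate Expected fraction of censored samples (default 0.3).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @param fivePrimeBias If `TRUE`, micro implants are concentrated in the
#'   5' end quadrant of each window (used to exercise the positional
#'   analysis); default `FALSE` places them uniformly.
#' @return A validated parameter list of class `CohortSimParams`.
#' @export
cohortSimParams <- function(nSamples = 96L, noiseSd = 0.15,
                            macroRate = 1.0, microRate = 3.5,
                            microSpanRange = c(1000L, 12000L),
                            ampEffect = 0.6, delEffect = -0.6,
                            exprCoupling = 0.7, exprShift = 1.5,
                            survivalHazardRatio = 2.0, censorRate = 0.3,
                            seed = 1L, fivePrimeBias = FALSE) {
  stopifnot(nSamples >= 1L, noiseSd >= 0, macroRate >= 0, microRate >= 0,
            length(microSpanRange) == 2L, all(microSpanRange > 0),
            microSpanRange[1L] <= microSpanRange[2L],
            ampEffect > 0, delEffect < 0,
            exprCoupling >= 0, exprCoupling <= 1, exprShift >= 0,
            survivalHazardRatio > 0,
            censorRate >= 0, censorRate <= 1,
            is.numeric(seed), length(seed) == 1L)
  structure(list(nSamples = as.integer(nSamples), noiseSd = noiseSd,
                 macroRate = macroRate, microRate = microRate,
                 microSpanRange = as.integer(microSpanRange),
                 ampEffect = ampEffect, delEffect = delEffect,
                 exprCoupling = exprCoupling, exprShift = exprShift,
                 survivalHazardRatio = survivalHazardRatio,
                 censorRate = censorRate, seed = as.integer(seed),
                 fivePrimeBias = isTRUE(fivePrimeBias)),
            class = "CohortSimParams")
}

#' Design a synthetic tiling array
#'
#' Places `nGenes` non-overlapping genes across chromosomes, builds their
#' padded analysis windows and tiles each window with probes at the
#' design spacing. At least one probe is emitted per window even when the
#' spacing exceeds the window. With `includeFlanks = TRUE` the +/- flank
#' regions are tiled as well; those probes belong to no analysis window
#' (`gene_symbol` `NA`) and are dropped on matrix read.
#'
#' @param params An [arrayDesignParams()] list.
#' @param seed Integer RNG seed (gene lengths and strands are random).
#' @param includeFlanks Tile the flanks too (default `FALSE`).
#' @return A list with elements `windows` (a [GeneWindows-class]) and
#'   `probes` (a `GRanges` with `probe_id`, `gene_symbol`).
#' @export
designArray <- function(params = arrayDesignParams(), seed = 1L,
                        includeFlanks = FALSE) {
  stopifnot(inherits(params, "ArrayDesignParams"))
  set.seed(as.integer(seed))
  n <- params$nGenes
  lens <- as.integer(round(stats::runif(n, params$geneLengthRange[1L],
                                        params$geneLengthRange[2L])))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  chroms <- paste0("chr", rep_len(1:22, n))
  # lay genes out per chromosome with gaps comfortably exceeding window+flank
  gap <- 2L * (params$padBp + params$flankBp) + 100000L
  gene_start <- integer(n)
  cursor <- stats::setNames(rep(1000000L, 22L), paste0("chr", 1:22))
  for (i in seq_len(n)) {
    gene_start[i] <- cursor[chroms[i]]
    cursor[chroms[i]] <- cursor[chroms[i]] + lens[i] + gap
  }
  df <- data.frame(gene = sprintf("G%03d", seq_len(n)), chrom = chroms,
                   strand = strands, gene_start = gene_start,
                   gene_end = gene_start + lens - 1L,
                   stringsAsFactors = FALSE)
  # 5'UTR: first 1% of the gene span (oriented), at least 100 bp
  u5len <- pmax(100L, as.integer(round(lens * 0.01)))
  df$utr5_start <- ifelse(strands == "+", df$gene_start,
                          df$gene_end - u5len + 1L)
  df$utr5_end <- ifelse(strands == "+", df$gene_start + u5len - 1L,
                        df$gene_end)
  windows <- geneWindowsFromTable(df, padBp = params$padBp)
  gr <- windowRanges(windows)
  sp <- params$probeSpacingBp
  posList <- lapply(seq_len(n), function(i) {
    p <- seq.int(start(gr)[i], end(gr)[i], by = sp)
    if (includeFlanks && params$flankBp > 0L) {
      left <- seq.int(max(1L, start(gr)[i] - params$flankBp),
                      start(gr)[i] - 1L, by = sp)
      right <- seq.int(end(gr)[i] + 1L, end(gr)[i] + params$flankBp, by = sp)
      p <- c(left, p, right)
    }
    p
  })
  counts <- lengths(posList)
  pos <- unlist(posList, use.names = FALSE)
  prChrom <- rep(chroms, counts)
  probes <- GRanges(prChrom, IRanges(pos, width = 1L))
  mcols(probes)$probe_id <- sprintf("P%07d", seq_along(probes))
  # ownership by containment in a window
  hits <- findOverlaps(probes, gr, ignore.strand = TRUE)
  gene <- rep(NA_character_, length(probes))
  gene[queryHits(hits)] <- mcols(gr)$gene_symbol[subjectHits(hits)]
  mcols(probes)$gene_symbol <- gene
  list(windows = windows, probes = probes)
}

# Oriented 5'End quadrant of a window (used by the biased placement mode).
.firstQuadrant <- function(winStart, winEnd, strandChar) {
  L <- winEnd - winStart + 1L
  q <- L %/% 4L
  if (strandChar == "+") c(winStart, winStart + q - 1L)
  else c(winEnd - q + 1L, winEnd)
}

#' Simulate a synthetic cohort
#'
#' Generates probe-level log2 ratios (Gaussian baseline plus implanted
#' macro/micro aberrations), a gene-level expression matrix statistically
#' coupled to copy-number status, censored survival times whose hazard
#' grows with the sample's micro-implant tercile, and a truth table of
#' every implant. Implants that would overlap an existing implant in the
#' same gene and sample are rejected (and counted in a message).
#' Regenerating with the same parameters and seed reproduces all values
#' bit-identically.
#'
#' @param windows A [GeneWindows-class] (from [designArray()]).
#' @param probes Probe `GRanges` (from [designArray()]).
#' @param params A [cohortSimParams()] list; `params$seed` drives all
#'   randomness.
#' @return A [SyntheticCohort-class] object.
#' @export
simulateCohort <- function(windows, probes, params = cohortSimParams()) {
  stopifnot(inherits(params, "CohortSimParams"))
  set.seed(params$seed)
  gr <- windowRanges(windows)
  genes <- mcols(gr)$gene_symbol
  inWin <- !is.na(mcols(probes)$gene_symbol)
  probes <- probes[inWin]
  ord <- order(match(mcols(probes)$gene_symbol, genes), start(probes))
  probes <- probes[ord]
  nP <- length(probes)
  nS <- params$nSamples
  samples <- sprintf("S%03d", seq_len(nS))

  vals <- matrix(stats::rnorm(nP * nS, 0, params$noiseSd), nrow = nP,
                 dimnames = list(mcols(probes)$probe_id, samples))

  probeGene <- mcols(probes)$gene_symbol
  probePos <- start(probes)
  winStart <- start(gr); winEnd <- end(gr)
  strandChar <- as.character(strand(gr))
  names(winStart) <- names(winEnd) <- names(strandChar) <- genes

  truth <- list()
  rejected <- 0L
  for (s in seq_len(nS)) {
    nMacro <- stats::rpois(1L, params$macroRate)
    nMicro <- stats::rpois(1L, params$microRate)
    placed <- list()  # per gene: matrix of intervals
    addImplant <- function(g, a, b, kind) {
      iv <- placed[[g]]
      if (!is.null(iv) && any(a <= iv[, 2L] & b >= iv[, 1L])) return(FALSE)
      placed[[g]] <<- rbind(iv, c(a, b))
      truth[[length(truth) + 1L]] <<- list(
        sample_id = samples[s], gene_symbol = g, kind = kind,
        start = a, end = b)
      TRUE
    }
    if (nMacro > 0L) {
      gs <- sample(genes, nMacro, replace = TRUE)
      kinds <- sample(c("macro-gain", "macro-loss"), nMacro, replace = TRUE)
      for (j in seq_len(nMacro)) {
        g <- gs[j]
        if (!addImplant(g, winStart[[g]], winEnd[[g]], kinds[j]))
          rejected <- rejected + 1L
      }
    }
    if (nMicro > 0L) {
      gs <- sample(genes, nMicro, replace = TRUE)
      kinds <- sample(c("micro-amp", "micro-del"), nMicro, replace = TRUE)
      spans <- as.integer(round(stats::runif(nMicro, params$microSpanRange[1L],
                                             params$microSpanRange[2L])))
      for (j in seq_len(nMicro)) {
        g <- gs[j]
        len <- min(spans[j], winEnd[[g]] - winStart[[g]] + 1L)
        if (params$fivePrimeBias) {
          fq <- .firstQuadrant(winStart[[g]], winEnd[[g]], strandChar[[g]])
          lo <- fq[1L]; hi <- max(fq[1L], fq[2L] - len + 1L)
        } else {
          lo <- winStart[[g]]; hi <- winEnd[[g]] - len + 1L
        }
        a <- as.integer(floor(stats::runif(1L, lo, hi + 1L)))
        b <- min(a + len - 1L, winEnd[[g]])
        if (!addImplant(g, a, b, kinds[j]))
          rejected <- rejected + 1L
      }
    }
    # apply implanted effects to this sample's probes
    if (length(placed) > 0L) {
      recs <- truth[vapply(truth, function(r) r$sample_id == samples[s], logical(1))]
      for (r in recs) {
        idx <- which(probeGene == r$gene_symbol &
                       probePos >= r$start & probePos <= r$end)
        eff <- if (r$kind %in% c("macro-gain", "micro-amp")) params$ampEffect
               else params$delEffect
        vals[idx, s] <- vals[idx, s] + eff
      }
    }
  }
  if (rejected > 0L)
    message(sprintf("rejected %d overlapping implant(s)", rejected))

  truthDf <- if (length(truth) > 0L) {
    DataFrame(
      sample_id = vapply(truth, `[[`, character(1), "sample_id"),
      gene_symbol = vapply(truth, `[[`, character(1), "gene_symbol"),
      kind = vapply(truth, `[[`, character(1), "kind"),
      start = vapply(truth, `[[`, integer(1), "start"),
      end = vapply(truth, `[[`, integer(1), "end")
    )
  } else {
    DataFrame(sample_id = character(0), gene_symbol = character(0),
              kind = character(0), start = integer(0), end = integer(0))
  }
  # affected quadrants and expression coupling annotations
  if (nrow(truthDf) > 0L) {
    qlab <- character(nrow(truthDf))
    for (i in seq_len(nrow(truthDf))) {
      g <- truthDf$gene_symbol[i]
      wi <- match(g, genes)
      qb <- quadrantBounds(windows, g)
      hit <- truthDf$start[i] <= qb$end & truthDf$end[i] >= qb$start
      qlab[i] <- paste(qb$label[hit], collapse = ",")
    }
    truthDf$quadrants <- qlab
  } else {
    truthDf$quadrants <- character(0)
  }

  exprVals <- matrix(stats::rnorm(length(genes) * nS), nrow = length(genes),
                     dimnames = list(genes, samples))
  # one expression shift per aberrant (gene, sample) cell, in the direction
  # of the largest implant there (ties to the first record)
  shifted <- logical(nrow(truthDf))
  if (nrow(truthDf) > 0L) {
    key <- paste(truthDf$gene_symbol, truthDf$sample_id, sep = "\r")
    for (k in unique(key)) {
      rows <- which(key == k)
      couple <- stats::runif(1L) < params$exprCoupling
      if (!couple) next
      span <- truthDf$end[rows] - truthDf$start[rows]
      dom <- rows[which.max(span)]
      dir <- if (truthDf$kind[dom] %in% c("macro-gain", "micro-amp")) 1 else -1
      gi <- match(truthDf$gene_symbol[dom], genes)
      si <- match(truthDf$sample_id[dom], samples)
      exprVals[gi, si] <- exprVals[gi, si] + dir * params$exprShift
      recDir <- ifelse(truthDf$kind[rows] %in% c("macro-gain", "micro-amp"), 1, -1)
      shifted[rows[recDir == dir]] <- TRUE
    }
  }
  truthDf$expression_shifted <- shifted

  exprSe <- SummarizedExperiment(
    assays = list(expr = exprVals, present = !is.na(exprVals)))

  # clinical: subtype mix from the emulated cohort; exponential survival
  subtypes <- sample(c("Basal-like", "Luminal A", "Luminal B",
                       "HER2-enriched", "Normal-like"),
                     nS, replace = TRUE,
                     prob = c(31, 27, 21, 10, 5) / 94)
  microCount <- integer(nS)
  if (nrow(truthDf) > 0L) {
    mc <- table(truthDf$sample_id[grepl("^micro", truthDf$kind)])
    microCount[match(names(mc), samples)] <- as.integer(mc)
  }
  tert <- .tercile(microCount)
  baseHazard <- 0.1
  hz <- baseHazard * params$survivalHazardRatio^tert
  osT <- stats::rexp(nS, hz)
  rfsT <- stats::rexp(nS, hz * 1.5)
  osCens <- stats::runif(nS) < params$censorRate
  rfsCens <- stats::runif(nS) < params$censorRate
  osT[osCens] <- osT[osCens] * stats::runif(sum(osCens))
  rfsT[rfsCens] <- rfsT[rfsCens] * stats::runif(sum(rfsCens))
  clinical <- DataFrame(
    sample_id = samples, subtype = subtypes,
    os_time = osT, os_event = as.integer(!osCens),
    rfs_time = rfsT, rfs_event = as.integer(!rfsCens)
  )

  lrSe <- SummarizedExperiment(assays = list(log2ratio = vals),
                               rowRanges = probes)
  new("SyntheticCohort", windows = windows, logRatios = lrSe,
      expression = exprSe, clinical = clinical, truth = truthDf,
      params = unclass(params))
}

# rank-based tercile index 0/1/2 (ascending), ties share the tercile of
# their first occurrence
.tercile <- function(x) {
  n <- length(x)
  ord <- order(x)
  cut1 <- floor(n / 3); cut2 <- floor(2 * n / 3)
  t_sorted <- c(rep(0L, cut1), rep(1L, cut2 - cut1), rep(2L, n - cut2))
  # keep tied values together: tercile of a value = tercile at its first
  # occurrence in sort order
  xs <- x[ord]
  firstT <- t_sorted[match(xs, xs)]
  out <- integer(n)
  out[ord] <- firstT
  out
}

#' Summarise implanted ground truth
#'
#' @param cohort A [SyntheticCohort-class].
#' @return A list with `perSample` and `perGene` data.frames of implant
#'   counts by kind (plus a `total` column); the grand total equals the
#'   number of truth records.
#' @export
truthSummary <- function(cohort) {
  tr <- as.data.frame(truthRecords(cohort))
  kinds <- c("macro-gain", "macro-loss", "micro-amp", "micro-del")
  samples <- clinicalData(cohort)$sample_id
  genes <- geneSymbols(geneWindows(cohort))
  mk <- function(keys, field) {
    tab <- matrix(0L, nrow = length(keys), ncol = length(kinds),
                  dimnames = list(keys, kinds))
    if (nrow(tr) > 0L) {
      tt <- table(factor(tr[[field]], levels = keys),
                  factor(tr$kind, levels = kinds))
      tab[] <- as.integer(tt)
    }
    df <- as.data.frame(tab)
    df$total <- rowSums(tab)
    df
  }
  list(perSample = mk(samples, "sample_id"), perGene = mk(genes, "gene_symbol"))
}

#' Write all cohort tables to a directory
#'
#' Writes the windows, probe log2-ratio matrix, expression matrix,
#' clinical table and truth table as TSVs.
#'
#' @param cohort A [SyntheticCohort-class].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeGeneWindows(geneWindows(cohort), file.path(dir, "gene_windows.tsv"))
  writeLogRatioMatrix(logRatios(cohort), file.path(dir, "probes_log2.tsv"))
  writeExpressionMatrix(expressionData(cohort), file.path(dir, "expression.tsv"))
  writeClinical(clinicalData(cohort), file.path(dir, "clinical.tsv"))
  utils::write.table(as.data.frame(truthRecords(cohort)),
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
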