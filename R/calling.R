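#' Micro-aberration size definition
#'
#' An aberrant segment is a micro-aberration when it spans fewer than
#' `maxProbes` contiguous probes (strict; 64 probes is roughly 15 kb at
#' 200 bp spacing). In `"cohort_percentile"` mode the probe cutoff is
#' recomputed from the cohort's aberrant-segment size distribution as the
#' smallest-`percentile` bound, the way the operative 64-probe rule was
#' originally derived.
#'
#' @param maxProbes Exclusive probe-count bound for micro calls
#'   (default 64).
#' @param approxSpanBp Informational approximate bp span (default 15000).
#' @param percentile Fraction defining the size cutoff in
#'   `"cohort_percentile"` mode (default 0.25).
#' @param mode `"fixed_probes"` (default) or `"cohort_percentile"`.
#' @return A validated list of class `MicroDefinition`.
#' @export
microDefinition <- function(maxProbes = 64L, approxSpanBp = 15000L,
                            percentile = 0.25,
                            mode = c("fixed_probes", "cohort_percentile")) {
  mode <- match.arg(mode)
  stopifnot(maxProbes >= 2L, percentile > 0, percentile < 1)
  structure(list(maxProbes = as.integer(maxProbes),
                 approxSpanBp = as.integer(approxSpanBp),
                 percentile = percentile, mode = mode),
            class = "MicroDefinition")
}

#' Size cutoff from the cohort's aberrant-segment sizes
#'
#' Returns the smallest integer `k` such that the fraction of aberrant
#' segments with fewer than `k` probes is at least `percentile`
#' (empirical quantile with a lower-exclusive convention). When all
#' segment sizes are equal the cutoff degenerates to that size plus one
#' (everything micro) and a warning is raised.
#'
#' @param segmentProbeCounts Integer vector of aberrant-segment probe
#'   counts (nonempty).
#' @param percentile Target fraction (default 0.25).
#' @return The integer cutoff `k`.
#' @export
sizeThresholdFromCohort <- function(segmentProbeCounts, percentile = 0.25) {
  if (length(segmentProbeCounts) == 0L)
    stop("no aberrant segments: cannot derive a size cutoff")
  stopifnot(percentile > 0, percentile < 1)
  counts <- as.integer(segmentProbeCounts)
  if (length(unique(counts)) == 1L) {
    warning("degenerate size distribution: all aberrant segments have the same probe count")
    return(counts[1L] + 1L)
  }
  # the empirical fraction below k only changes at k = value + 1
  cand <- sort(unique(counts)) + 1L
  frac <- vapply(cand, function(k) mean(counts < k), numeric(1))
  cand[which(frac >= percentile)[1L]]
}

#' Classify aberrant segments as micro/macro amplification/deletion
#'
#' Micro iff the segment spans strictly fewer than the probe cutoff;
#' amplification versus deletion by the sign of the segment mean.
#' Neutral segments are a contract violation.
#'
#' @param segments Aberrant segment data.frame (columns `n_probes`,
#'   `mean_log2`, `call`).
#' @param microDef A [microDefinition()]; in `"cohort_percentile"` mode
#'   the cutoff is computed from `segments` itself.
#' @return Character vector: `"micro-amp"`, `"micro-del"`, `"macro-gain"`
#'   or `"macro-loss"` per segment.
#' @export
classifySegments <- function(segments, microDef = microDefinition()) {
  if (nrow(segments) == 0L) return(character(0))
  if (any(segments$call == "neutral"))
    stop("classifySegments received neutral segment(s)")
  cutoff <- if (microDef$mode == "cohort_percentile") {
    sizeThresholdFromCohort(segments$n_probes, microDef$percentile)
  } else {
    microDef$maxProbes
  }
  micro <- segments$n_probes < cutoff
  amp <- segments$mean_log2 > 0
  ifelse(micro, ifelse(amp, "micro-amp", "micro-del"),
         ifelse(amp, "macro-gain", "macro-loss"))
}

#' @rdname classifySegments
#' @param nProbes,meanLog2 Scalar segment size and mean for the
#'   single-segment form.
#' @export
classifySegment <- function(nProbes, meanLog2, microDef = microDefinition()) {
  if (meanLog2 == 0) stop("classifySegment received a neutral segment")
  classifySegments(data.frame(n_probes = nProbes, mean_log2 = meanLog2,
                              call = ifelse(meanLog2 > 0, "gain", "loss")),
                   microDef)
}

#' Per-(gene, sample) copy-number status
#'
#' Reduces all segments of one gene in one sample to a single status:
#' `"none"` without aberrant segments; a gross status when any macro
#' segment is present (sign of the macro segment with the largest
#' `|mean x n_probes|`); otherwise the micro status of the micro segment
#' with the largest `|mean|`.
#'
#' @param segments Segment data.frame for one (gene, sample), including
#'   neutral segments.
#' @param classes Optional precomputed classes for the aberrant rows (in
#'   order); computed with `microDef` when `NULL`.
#' @param microDef A [microDefinition()].
#' @return One of `"gross-gain"`, `"gross-loss"`, `"micro-amp"`,
#'   `"micro-del"`, `"none"`.
#' @export
assignGeneSampleStatus <- function(segments, microDef = microDefinition(),
                                   classes = NULL) {
  ab <- segments[segments$call != "neutral", , drop = FALSE]
  if (nrow(ab) == 0L) return("none")
  if (is.null(classes)) classes <- classifySegments(ab, microDef)
  isMacro <- classes %in% c("macro-gain", "macro-loss")
  if (any(isMacro)) {
    sc <- abs(ab$mean_log2 * ab$n_probes)
    sc[!isMacro] <- -Inf
    top <- which.max(sc)
    return(if (ab$mean_log2[top] > 0) "gross-gain" else "gross-loss")
  }
  top <- which.max(abs(ab$mean_log2))
  if (ab$mean_log2[top] > 0) "micro-amp" else "micro-del"
}

#' Call micro/macro aberrations across a cohort
#'
#' Filters segments to aberrant ones, classifies each, assembles the
#' micro-aberration instance table, and assigns one copy-number status
#' per (gene, sample) (macro events take precedence over micro events in
#' the same gene and sample).
#'
#' @param segments Segment data.frame from [segmentCohort()].
#' @param microDef A [microDefinition()].
#' @param clinical Optional clinical data.frame supplying `subtype` per
#'   sample (samples without one are labelled `"unknown"`).
#' @param genes,samples Optional full universes for the status matrix;
#'   defaults to those present in `segments`.
#' @return A list: `micro` (instance table with `Sample`, `Subtype`,
#'   `Gene`, `Chrom`, `Start`, `Stop`, `N_Probes`, `Avg_log2`, `Kind`),
#'   `aberrant` (all aberrant segments with a `class` column), `status`
#'   (gene x sample character matrix) and `cutoff` (probe cutoff used).
#' @export
callAberrations <- function(segments, microDef = microDefinition(),
                            clinical = NULL, genes = NULL, samples = NULL) {
  ab <- segments[segments$call != "neutral", , drop = FALSE]
  cutoff <- if (microDef$mode == "cohort_percentile" && nrow(ab) > 0L) {
    sizeThresholdFromCohort(ab$n_probes, microDef$percentile)
  } else {
    microDef$maxProbes
  }
  fixedDef <- microDefinition(maxProbes = cutoff, mode = "fixed_probes")
  classes <- classifySegments(ab, fixedDef)
  ab$class <- classes
  if (is.null(genes)) genes <- unique(segments$gene)
  if (is.null(samples)) samples <- unique(segments$sample)

  subtypeOf <- function(s) {
    if (is.null(clinical)) return(rep("unknown", length(s)))
    st <- clinical$subtype[match(s, clinical$sample_id)]
    st[is.na(st) | st == ""] <- "unknown"
    st
  }
  isMicro <- grepl("^micro", classes)
  micro <- data.frame(
    Sample = ab$sample[isMicro],
    Subtype = subtypeOf(ab$sample[isMicro]),
    Gene = ab$gene[isMicro],
    Chrom = ab$chrom[isMicro],
    Start = ab$start[isMicro],
    Stop = ab$end[isMicro],
    N_Probes = ab$n_probes[isMicro],
    Avg_log2 = ab$mean_log2[isMicro],
    Kind = classes[isMicro],
    stringsAsFactors = FALSE
  )

  status <- matrix("none", nrow = length(genes), ncol = length(samples),
                   dimnames = list(genes, samples))
  if (nrow(ab) > 0L) {
    key <- paste(ab$gene, ab$sample, sep = "\r")
    for (k in unique(key)) {
      rows <- which(key == k)
      g <- ab$gene[rows[1L]]; s <- ab$sample[rows[1L]]
      status[g, s] <- assignGeneSampleStatus(ab[rows, , drop = FALSE],
                                             fixedDef, classes[rows])
    }
  }
  list(micro = micro, aberrant = ab, status = status, cutoff = cutoff)
}

#' Per-subtype micro-aberration summary
#'
#' Mean and median micro-aberration count per sample, and the percentage
#' of samples carrying at least one micro-aberration, by subtype. Samples
#' without a subtype are grouped under `"unknown"`.
#'
#' @param micro Micro-aberration instance table (from [callAberrations()]).
#' @param clinical Clinical data.frame (defines the sample universe, so
#'   samples without any micro-aberration count as zeros).
#' @return A data.frame with one row per subtype: `subtype`, `n_samples`,
#'   `mean_micro`, `median_micro`, `pct_with_micro`.
#' @export
perSubtypeSummary <- function(micro, clinical) {
  if (nrow(clinical) == 0L)
    return(data.frame(subtype = character(0), n_samples = integer(0),
                      mean_micro = numeric(0), median_micro = numeric(0),
                      pct_with_micro = numeric(0)))
  counts <- integer(nrow(clinical))
  if (nrow(micro) > 0L) {
    tb <- table(micro$Sample)
    idx <- match(names(tb), clinical$sample_id)
    counts[idx[!is.na(idx)]] <- as.integer(tb)[!is.na(idx)]
  }
  st <- clinical$subtype
  st[is.na(st) | st == ""] <- "unknown"
  agg <- lapply(split(counts, st), function(x) {
    c(n = length(x), mean = mean(x), median = stats::median(x),
      pct = 100 * mean(x >= 1))
  })
  out <- data.frame(
    subtype = names(agg),
    n_samples = vapply(agg, `[[`, numeric(1), "n"),
    mean_micro = vapply(agg, `[[`, numeric(1), "mean"),
    median_micro = vapply(agg, `[[`, numeric(1), "median"),
    pct_with_micro = vapply(agg, `[[`, numeric(1), "pct"),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$subtype), , drop = FALSE]
}
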