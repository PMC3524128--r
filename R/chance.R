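#' Empirical probe exceedance probability
#'
#' Fraction of log2 values whose absolute value strictly exceeds the
#' threshold, over the pooled empirical distribution of the dataset.
#'
#' @param values Numeric log2 ratios (missing values ignored).
#' @param threshold Absolute cutoff (default 0.30).
#' @return A probability in `[0, 1]`.
#' @export
exceedanceProbability <- function(values, threshold = 0.30) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to compute exceedance from")
  mean(abs(values) > threshold)
}

#' Expected micro-aberration count under the chance model
#'
#' Scan-statistic expectation of the number of maximal runs of
#' consecutive threshold exceedances with length in
#' `[minProbes, maxProbes)` among `nProbesGene` independent probes, over
#' `nSamples` samples. For run length `r` there are `nProbesGene - r + 1`
#' windows; interior windows require a non-exceeding probe on both sides
#' (factor `(1-p)^2`), the two boundary windows a single such probe, and
#' a run covering the whole gene none. This window count is the
#' gene-size correction: longer genes admit proportionally more runs.
#'
#' @param nProbesGene Number of probes in the gene's window.
#' @param pExceed Per-probe exceedance probability (limits 0 and 1 are
#'   handled exactly).
#' @param minProbes Smallest callable run (default 5).
#' @param maxProbes Exclusive micro size bound (default 64).
#' @param nSamples Number of samples in the cohort (default 1).
#' @return The expected count (nonnegative; monotone nondecreasing in
#'   `pExceed`, `nProbesGene` and `nSamples`).
#' @export
expectedMicroCount <- function(nProbesGene, pExceed, minProbes = 5L,
                               maxProbes = 64L, nSamples = 1L) {
  stopifnot(nProbesGene >= 1L, pExceed >= 0, pExceed <= 1,
            minProbes >= 1L, maxProbes > minProbes, nSamples >= 1L)
  n <- as.integer(nProbesGene)
  p <- pExceed; q <- 1 - p
  rs <- seq.int(minProbes, min(maxProbes - 1L, n))
  if (length(rs) == 0L || p == 0) return(0)
  term <- function(r) {
    if (r == n) return(p^r)
    2 * p^r * q + max(n - r - 1L, 0L) * p^r * q^2
  }
  nSamples * sum(vapply(rs, term, numeric(1)))
}

#' Observed versus expected micro-aberration test
#'
#' Compares an observed micro-aberration count against its chance-model
#' expectation. The default `"exact"` mode reports the Poisson upper
#' tail `P(X >= observed)` at rate `max(expected, eps)`; `"chisq"` mode
#' reports the one-degree-of-freedom chi-square test with the expected
#' count floored at `eps` (with near-zero expectations this is
#' degenerate and useful only for display parity with `"<.001"`-style
#' reporting).
#'
#' @param observed Observed integer count (>= 0).
#' @param expected Expected count (>= 0).
#' @param mode `"exact"` (default) or `"chisq"`.
#' @param eps Floor for the expectation (default 1e-12).
#' @return The p-value.
#' @seealso [formatPValue()] for the `"<.001"` display convention.
#' @export
observedVsExpectedTest <- function(observed, expected,
                                   mode = c("exact", "chisq"), eps = 1e-12) {
  mode <- match.arg(mode)
  stopifnot(observed >= 0, observed == round(observed), expected >= 0)
  lambda <- max(expected, eps)
  if (mode == "exact") {
    if (observed == 0) return(1)
    return(stats::ppois(observed - 1, lambda, lower.tail = FALSE))
  }
  stat <- (observed - expected)^2 / lambda
  stats::pchisq(stat, df = 1L, lower.tail = FALSE)
}

#' Display-format a p-value
#'
#' Values below 0.001 print as `"<.001"`; otherwise rounded to
#' `digits` significant digits.
#'
#' @param p Numeric p-value(s).
#' @param digits Significant digits (default 2).
#' @return Character vector.
#' @export
formatPValue <- function(p, digits = 2L) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<.001", as.character(signif(p, digits))))
}

#' Per-gene chance-model table
#'
#' For every gene window: the observed micro-aberration counts
#' (all/amplifications/deletions), the expected count under the
#' scan-statistic null built from the pooled empirical log2-ratio
#' distribution with gene-size correction, and the observed-vs-expected
#' p-value.
#'
#' @param se Probe-level `SummarizedExperiment` (assay `"log2ratio"`,
#'   `rowRanges` with `gene_symbol`).
#' @param micro Micro-aberration instance table (from
#'   [callAberrations()]).
#' @param threshold Absolute log2 cutoff (default 0.30).
#' @param minProbes,maxProbes Run-length bounds (defaults 5 and 64).
#' @param mode Test mode, see [observedVsExpectedTest()].
#' @return A data.frame sorted by decreasing observed count: `gene`,
#'   `n_probes`, `observed_all`, `observed_amp`, `observed_del`,
#'   `p_exceed`, `expected`, `p_value`, `p_display`.
#' @export
chanceModelTable <- function(se, micro, threshold = 0.30, minProbes = 5L,
                             maxProbes = 64L, mode = "exact") {
  vals <- assay(se, "log2ratio")
  pExceed <- exceedanceProbability(as.vector(vals), threshold)
  geneOf <- mcols(rowRanges(se))$gene_symbol
  genes <- unique(geneOf)
  nProbes <- as.integer(table(factor(geneOf, levels = genes)))
  nSamples <- ncol(vals)
  obsAll <- integer(length(genes)); obsAmp <- integer(length(genes))
  obsDel <- integer(length(genes))
  if (nrow(micro) > 0L) {
    f <- factor(micro$Gene, levels = genes)
    obsAll <- as.integer(table(f))
    obsAmp <- as.integer(table(f[micro$Kind == "micro-amp"]))
    obsDel <- as.integer(table(f[micro$Kind == "micro-del"]))
  }
  expected <- vapply(nProbes, expectedMicroCount, numeric(1),
                     pExceed = pExceed, minProbes = minProbes,
                     maxProbes = maxProbes, nSamples = nSamples)
  pv <- mapply(observedVsExpectedTest, obsAll, expected,
               MoreArgs = list(mode = mode))
  out <- data.frame(
    gene = genes, n_probes = nProbes,
    observed_all = obsAll, observed_amp = obsAmp, observed_del = obsDel,
    p_exceed = pExceed, expected = expected, p_value = pv,
    p_display = formatPValue(pv), stringsAsFactors = FALSE
  )
  out[order(-out$observed_all, out$gene), , drop = FALSE]
}
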