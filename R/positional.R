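QUADRANT_LABELS <- c("5'End", "5'Mid", "3'Mid", "3'End")

#' Quadrant bounds of a gene's analysis window
#'
#' Splits the analysis window into four equal-length, non-overlapping,
#' exhaustive genomic intervals. Boundaries fall at floor offsets; the
#' 3'End quadrant (in gene orientation) absorbs any remainder, so the
#' split is symmetric under coordinate mirroring plus strand flip. On the
#' `-` strand the 5'End quadrant is the rightmost interval.
#'
#' @param windows A [GeneWindows-class].
#' @param gene Gene symbol selecting the window.
#' @return A data.frame with columns `label` (5'End, 5'Mid, 3'Mid, 3'End,
#'   in that order), `start`, `end` (1-based inclusive genomic bp).
#' @export
quadrantBounds <- function(windows, gene) {
  gr <- windowRanges(windows)
  i <- match(gene, mcols(gr)$gene_symbol)
  if (is.na(i)) stop(sprintf("unknown gene: %s", gene))
  ws <- start(gr)[i]; we <- end(gr)[i]
  L <- we - ws + 1L
  q <- L %/% 4L
  lens <- c(q, q, q, L - 3L * q)  # 5'End .. 3'End in gene orientation
  minus <- as.character(strand(gr))[i] == "-"
  genomicLens <- if (minus) rev(lens) else lens
  starts <- ws + cumsum(c(0L, genomicLens[-4L]))
  ends <- starts + genomicLens - 1L
  labs <- if (minus) rev(QUADRANT_LABELS) else QUADRANT_LABELS
  out <- data.frame(label = labs, start = starts, end = ends,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[match(QUADRANT_LABELS, out$label), , drop = FALSE]
}

# promoter interval (upstream of the 5' anchor, within the window);
# returns c(start, end) or NULL when empty
.promoterInterval <- function(ws, we, strandChar, tss) {
  if (strandChar == "+") {
    if (tss - 1L < ws) return(NULL)
    c(ws, tss - 1L)
  } else {
    if (tss + 1L > we) return(NULL)
    c(tss + 1L, we)
  }
}

# Per-instance overlap flags: quadrants (in QUADRANT_LABELS order),
# promoter and 5'UTR. Overlap rule: >= minOverlap bp.
.instanceFlags <- function(micros, windows, minOverlap = 1L,
                           promoterDefinition = c("tss", "cds")) {
  promoterDefinition <- match.arg(promoterDefinition)
  gr <- windowRanges(windows)
  mc <- mcols(gr)
  idx <- match(micros$Gene, mc$gene_symbol)
  if (anyNA(idx))
    stop(sprintf("micro-aberration(s) reference unknown gene(s): %s",
                 paste(unique(micros$Gene[is.na(idx)]), collapse = ", ")))
  n <- nrow(micros)
  quad <- matrix(FALSE, n, 4L, dimnames = list(NULL, QUADRANT_LABELS))
  promoter <- logical(n)
  utr5 <- rep(NA, n)
  ov <- function(a1, a2, b1, b2) (pmin(a2, b2) - pmax(a1, b1) + 1L) >= minOverlap
  for (i in seq_len(n)) {
    wi <- idx[i]
    qb <- quadrantBounds(windows, micros$Gene[i])
    quad[i, ] <- ov(micros$Start[i], micros$Stop[i], qb$start, qb$end)
    # promoter anchor: the tss; the "cds" variant anchors at the gene span's
    # 5' edge, which coincides with the tss when no separate CDS start is
    # recorded in the window table
    anchor <- mc$tss[wi]
    pi <- .promoterInterval(start(gr)[wi], end(gr)[wi],
                            as.character(strand(gr))[wi], anchor)
    promoter[i] <- !is.null(pi) && ov(micros$Start[i], micros$Stop[i], pi[1L], pi[2L])
    if (!is.na(mc$utr5_start[wi]) && !is.na(mc$utr5_end[wi]))
      utr5[i] <- ov(micros$Start[i], micros$Stop[i],
                    mc$utr5_start[wi], mc$utr5_end[wi])
  }
  data.frame(quad, promoter = promoter, utr5 = utr5, check.names = FALSE)
}

#' Tally quadrant, promoter and 5'UTR occupancy of micro-aberrations
#'
#' For every micro-aberration instance, a quadrant is affected iff the
#' instance overlaps it by at least `minOverlap` bp (default 1). The
#' possible count per quadrant equals the number of instances, so each
#' proportion is the fraction of instances touching that quadrant.
#' Promoter overlap tests the interval from the window's upstream edge to
#' the transcription start site, oriented by strand; 5'UTR overlap is
#' reported when the windows carry 5'UTR coordinates.
#'
#' @param micros Micro-aberration instance table (columns `Gene`, `Start`,
#'   `Stop`; e.g. from [callAberrations()]).
#' @param windows A [GeneWindows-class].
#' @param minOverlap Minimum overlap in bp (default 1).
#' @param promoterDefinition `"tss"` (default) or `"cds"`.
#' @return A list: `quadrants` (data.frame `label`, `affected`,
#'   `possible`, `proportion`), `promoter_rate`, `utr5_rate` (`NA` when
#'   no 5'UTR coordinates exist), `five_prime_only` (rates among
#'   instances confined to the 5'End quadrant; see
#'   [fivePrimeOnlyBreakdown()]) and `flags` (per-instance logical table).
#' @export
tallyQuadrants <- function(micros, windows, minOverlap = 1L,
                           promoterDefinition = "tss") {
  flags <- .instanceFlags(micros, windows, minOverlap, promoterDefinition)
  n <- nrow(flags)
  affected <- if (n > 0L) colSums(flags[, QUADRANT_LABELS, drop = FALSE]) else
    stats::setNames(rep(0L, 4L), QUADRANT_LABELS)
  quad <- data.frame(
    label = QUADRANT_LABELS,
    affected = as.integer(affected),
    possible = n,
    proportion = if (n > 0L) as.numeric(affected) / n else rep(NA_real_, 4L),
    stringsAsFactors = FALSE
  )
  utr5Known <- !all(is.na(flags$utr5))
  list(
    quadrants = quad,
    promoter_rate = if (n > 0L) mean(flags$promoter) else NA_real_,
    utr5_rate = if (n > 0L && utr5Known) mean(flags$utr5, na.rm = TRUE) else NA_real_,
    five_prime_only = .fivePrimeOnlyFromFlags(flags),
    flags = flags
  )
}

.fivePrimeOnlyFromFlags <- function(flags) {
  only5 <- flags[["5'End"]] & !flags[["5'Mid"]] & !flags[["3'Mid"]] &
    !flags[["3'End"]]
  if (!any(only5))
    return(list(n = 0L, promoter_rate = NA_real_, utr5_rate = NA_real_))
  sub <- flags[only5, , drop = FALSE]
  utr5Known <- !all(is.na(sub$utr5))
  list(n = sum(only5),
       promoter_rate = mean(sub$promoter),
       utr5_rate = if (utr5Known) mean(sub$utr5, na.rm = TRUE) else NA_real_)
}

#' Promoter/5'UTR rates among 5'End-only micro-aberrations
#'
#' Restricts to instances overlapping the 5'End quadrant and no other
#' quadrant, and reports the fraction of those touching the promoter and
#' the 5'UTR. Rates are `NA` when no instance qualifies.
#'
#' @inheritParams tallyQuadrants
#' @return A list with `n`, `promoter_rate`, `utr5_rate`.
#' @export
fivePrimeOnlyBreakdown <- function(micros, windows, minOverlap = 1L,
                                   promoterDefinition = "tss") {
  flags <- .instanceFlags(micros, windows, minOverlap, promoterDefinition)
  .fivePrimeOnlyFromFlags(flags)
}
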