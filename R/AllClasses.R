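#' @import methods
#' @importFrom GenomicRanges GRanges start end width strand seqnames findOverlaps
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors mcols mcols<- DataFrame queryHits subjectHits
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays assays<- rowRanges colData
#' @importClassesFrom SummarizedExperiment SummarizedExperiment RangedSummarizedExperiment
NULL

#' Gene analysis windows
#'
#' Container for the per-gene analysis windows of a gene-centric tiling
#' array: each gene's genomic span padded by a fixed upstream/downstream
#' margin (default 5 kb), together with strand, transcription start site
#' and optional 5'UTR coordinates. Coordinates are 1-based inclusive, the
#' convention of both the on-disk tables and the underlying
#' [GenomicRanges::GRanges] ranges.
#'
#' @slot windows A `GRanges` of analysis windows with metadata columns
#'   `gene_symbol`, `gene_start`, `gene_end`, `tss`, `utr5_start`,
#'   `utr5_end`; strand is carried on the ranges.
#' @slot padBp Integer padding added on each side of the gene span.
#'
#' @seealso [readGeneWindows()], [designArray()]
#' @export
setClass("GeneWindows",
  slots = c(windows = "GRanges", padBp = "integer")
)

setValidity("GeneWindows", function(object) {
  gr <- object@windows
  mc <- mcols(gr)
  need <- c("gene_symbol", "gene_start", "gene_end", "tss")
  miss <- setdiff(need, colnames(mc))
  if (length(miss) > 0L)
    return(sprintf("missing metadata column(s): %s", paste(miss, collapse = ", ")))
  if (any(duplicated(mc$gene_symbol)))
    return("duplicated gene symbols")
  if (any(mc$gene_start >= mc$gene_end))
    return("gene_start must be < gene_end for every gene")
  if (any(start(gr) != pmax(1L, mc$gene_start - object@padBp)))
    return("window start must equal gene_start - padBp (floored at 1)")
  if (any(end(gr) != mc$gene_end + object@padBp))
    return("window end must equal gene_end + padBp")
  plus <- as.character(strand(gr)) == "+"
  tss_ok <- ifelse(plus, mc$tss == mc$gene_start, mc$tss == mc$gene_end)
  if (!all(tss_ok))
    return("tss must equal gene_start on '+' strand and gene_end on '-' strand")
  TRUE
})

#' Synthetic tiling-array cohort with recorded ground truth
#'
#' Bundles everything [simulateCohort()] generates: the gene windows, the
#' probe-level log2 ratio matrix (a [SummarizedExperiment::SummarizedExperiment]
#' whose `rowRanges` are the probes), the gene-level expression matrix,
#' the clinical table and the truth table of implanted aberrations.
#'
#' @slot windows A [GeneWindows-class] object.
#' @slot logRatios `SummarizedExperiment`, assay `"log2ratio"` (probe x sample).
#' @slot expression `SummarizedExperiment`, assays `"expr"` and `"present"`
#'   (gene x sample).
#' @slot clinical `DataFrame` with `sample_id`, `subtype`, `os_time`,
#'   `os_event`, `rfs_time`, `rfs_event`.
#' @slot truth `DataFrame` of implanted aberrations (`sample_id`,
#'   `gene_symbol`, `kind`, `start`, `end`, `quadrants`, `expression_shifted`).
#' @slot params The [cohortSimParams()] list used for generation.
#'
#' @export
setClass("SyntheticCohort",
  slots = c(
    windows = "GeneWindows",
    logRatios = "RangedSummarizedExperiment",
    expression = "SummarizedExperiment",
    clinical = "DataFrame",
    truth = "DataFrame",
    params = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  tr <- object@truth
  if (nrow(tr) > 0L) {
    if (any(tr$start >= tr$end))
      return("truth records must have start < end")
    gr <- object@windows@windows
    idx <- match(tr$gene_symbol, mcols(gr)$gene_symbol)
    if (anyNA(idx))
      return("truth records refer to unknown genes")
    if (any(tr$start < start(gr)[idx] | tr$end > end(gr)[idx]))
      return("truth intervals must lie inside their gene's analysis window")
    micro <- grepl("^micro", tr$kind)
    span <- tr$end - tr$start + 1L
    upper <- object@params$microSpanRange[2L]
    if (!is.null(upper) && any(micro & span > upper))
      return("micro truth records exceed microSpanRange upper bound")
  }
  cl <- object@clinical
  if (nrow(cl) != ncol(object@logRatios))
    return("clinical rows must match the number of samples")
  if (any(cl$os_time < 0) || any(cl$rfs_time < 0))
    return("survival times must be nonnegative")
  if (!all(cl$os_event %in% c(0, 1)) || !all(cl$rfs_event %in% c(0, 1)))
    return("events must be binary")
  TRUE
})

#' @describeIn GeneWindows-class Number of gene windows.
#' @param x A `GeneWindows` object.
#' @export
setMethod("length", "GeneWindows", function(x) length(x@windows))

#' @describeIn GeneWindows-class Gene symbols.
#' @export
setMethod("names", "GeneWindows", function(x) mcols(x@windows)$gene_symbol)

#' Accessors for GeneWindows
#'
#' `windowRanges()` returns the window `GRanges`; `padBp()` the padding;
#' `geneSymbols()` the gene identifiers.
#'
#' @param x A [GeneWindows-class] object.
#' @return `windowRanges`: a `GRanges`; `padBp`: an integer;
#'   `geneSymbols`: a character vector.
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))

#' @rdname windowRanges
#' @export
setMethod("windowRanges", "GeneWindows", function(x) x@windows)

#' @rdname windowRanges
#' @export
setGeneric("padBp", function(x) standardGeneric("padBp"))

#' @rdname windowRanges
#' @export
setMethod("padBp", "GeneWindows", function(x) x@padBp)

#' @rdname windowRanges
#' @export
setGeneric("geneSymbols", function(x) standardGeneric("geneSymbols"))

#' @rdname windowRanges
#' @export
setMethod("geneSymbols", "GeneWindows", function(x) mcols(x@windows)$gene_symbol)

setMethod("show", "GeneWindows", function(object) {
  cat(sprintf("GeneWindows with %d gene(s), pad %d bp\n",
              length(object), object@padBp))
  if (length(object) > 0L) {
    gr <- object@windows
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(as.character(seqnames(gr))), collapse = ", ")))
    cat(sprintf("  window widths: %d-%d bp\n", min(width(gr)), max(width(gr))))
  }
  invisible(object)
})

#' Accessors for SyntheticCohort
#'
#' Slot accessors for [SyntheticCohort-class] objects.
#'
#' @param x A `SyntheticCohort`.
#' @return `geneWindows`: a [GeneWindows-class]; `logRatios` and
#'   `expressionData`: `SummarizedExperiment`s; `clinicalData` and
#'   `truthRecords`: `DataFrame`s.
#' @export
setGeneric("geneWindows", function(x) standardGeneric("geneWindows"))
#' @rdname geneWindows
#' @export
setMethod("geneWindows", "SyntheticCohort", function(x) x@windows)

#' @rdname geneWindows
#' @export
setGeneric("logRatios", function(x) standardGeneric("logRatios"))
#' @rdname geneWindows
#' @export
setMethod("logRatios", "SyntheticCohort", function(x) x@logRatios)

#' @rdname geneWindows
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))
#' @rdname geneWindows
#' @export
setMethod("expressionData", "SyntheticCohort", function(x) x@expression)

#' @rdname geneWindows
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))
#' @rdname geneWindows
#' @export
setMethod("clinicalData", "SyntheticCohort", function(x) x@clinical)

#' @rdname geneWindows
#' @export
setGeneric("truthRecords", function(x) standardGeneric("truthRecords"))
#' @rdname geneWindows
#' @export
setMethod("truthRecords", "SyntheticCohort", function(x) x@truth)

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d genes x %d samples, %d probes\n",
              length(object@windows), ncol(object@logRatios),
              nrow(object@logRatios)))
  tr <- object@truth
  if (nrow(tr) > 0L) {
    tab <- table(tr$kind)
    cat("  implanted truth:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  } else {
    cat("  implanted truth: none\n")
  }
  invisible(object)
})
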