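#' Read gene analysis windows from a BED-like table
#'
#' Reads a tab-separated table of gene spans (columns `gene`, `chrom`,
#' `strand`, `gene_start`, `gene_end`, optionally `utr5_start`,
#' `utr5_end`; 1-based inclusive coordinates) and builds the per-gene
#' analysis windows: the gene span padded by `padBp` on both sides. The
#' transcription start site is `gene_start` on the `+` strand and
#' `gene_end` on the `-` strand.
#'
#' @param path Path to the TSV file.
#' @param padBp Padding in bp added on each side of the gene span
#'   (default 5000).
#' @return A [GeneWindows-class] object.
#' @export
readGeneWindows <- function(path, padBp = 5000L) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  geneWindowsFromTable(df, padBp = padBp)
}

#' Build GeneWindows from an in-memory table
#'
#' @param df A data.frame with the columns described in [readGeneWindows()].
#' @inheritParams readGeneWindows
#' @return A [GeneWindows-class] object.
#' @export
geneWindowsFromTable <- function(df, padBp = 5000L) {
  padBp <- as.integer(padBp)
  stopifnot(length(padBp) == 1L, padBp >= 0L)
  need <- c("gene", "chrom", "strand", "gene_start", "gene_end")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop(sprintf("gene window table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (nrow(df) == 0L) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(gene_symbol = character(0), gene_start = integer(0),
                           gene_end = integer(0), tss = integer(0),
                           utr5_start = integer(0), utr5_end = integer(0))
    return(new("GeneWindows", windows = gr, padBp = padBp))
  }
  bad <- which(df$gene_start >= df$gene_end)
  if (length(bad) > 0L)
    stop(sprintf("gene_start >= gene_end for record(s): %s",
                 paste(df$gene[bad], collapse = ", ")))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  gs <- as.integer(df$gene_start)
  ge <- as.integer(df$gene_end)
  tss <- ifelse(df$strand == "+", gs, ge)
  u5s <- if ("utr5_start" %in% colnames(df)) as.integer(df$utr5_start) else rep(NA_integer_, nrow(df))
  u5e <- if ("utr5_end" %in% colnames(df)) as.integer(df$utr5_end) else rep(NA_integer_, nrow(df))
  gr <- GRanges(
    seqnames = df$chrom,
    ranges = IRanges(pmax(1L, gs - padBp), ge + padBp),
    strand = df$strand,
    gene_symbol = as.character(df$gene),
    gene_start = gs, gene_end = ge, tss = as.integer(tss),
    utr5_start = u5s, utr5_end = u5e
  )
  ov <- findOverlaps(gr, gr, ignore.strand = TRUE)
  ov <- ov[queryHits(ov) < subjectHits(ov)]
  if (length(ov) > 0L)
    warning(sprintf("%d pair(s) of gene windows overlap on the same chromosome",
                    length(ov)))
  new("GeneWindows", windows = gr, padBp = padBp)
}

#' Write gene windows back to disk
#'
#' Inverse of [readGeneWindows()]; only the gene-level columns are
#' written (windows are recomputed from `padBp` on read).
#'
#' @param windows A [GeneWindows-class] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeGeneWindows <- function(windows, path) {
  gr <- windowRanges(windows)
  mc <- mcols(gr)
  df <- data.frame(
    gene = mc$gene_symbol, chrom = as.character(seqnames(gr)),
    strand = as.character(strand(gr)),
    gene_start = mc$gene_start, gene_end = mc$gene_end,
    utr5_start = mc$utr5_start, utr5_end = mc$utr5_end,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe x sample log2-ratio matrix
#'
#' Reads a TSV whose first three columns are `probe_id`, `chrom`,
#' `position` (probe midpoint, 1-based) followed by one numeric column
#' per sample. Probes are assigned to the gene window containing them;
#' probes falling in no window are dropped with a message. The result is
#' ordered by gene then position.
#'
#' @param path Path to the TSV file.
#' @param windows A [GeneWindows-class] object.
#' @param missingToken String representing missing values (default `"NA"`).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"log2ratio"` and probe `rowRanges` (metadata columns `probe_id`,
#'   `gene_symbol`).
#' @export
readLogRatioMatrix <- function(path, windows, missingToken = "NA") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = missingToken)
  need <- c("probe_id", "chrom", "position")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop(sprintf("probe matrix is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe id(s) in probe matrix")
  sampleCols <- setdiff(colnames(df), need)
  vals <- as.matrix(df[, sampleCols, drop = FALSE])
  if (!is.numeric(vals))
    stop("non-numeric value(s) in sample columns (other than the missing token)")
  if (any(!is.finite(vals) & !is.na(vals)))
    stop("log2 ratios must be finite where present")
  pr <- GRanges(df$chrom, IRanges(as.integer(df$position), width = 1L),
                probe_id = as.character(df$probe_id))
  assignProbesToWindows(pr, vals, windows)
}

# Assign probes to owning windows, drop orphans, sort by gene then position.
assignProbesToWindows <- function(pr, vals, windows) {
  gr <- windowRanges(windows)
  hits <- findOverlaps(pr, gr, ignore.strand = TRUE)
  multi <- duplicated(queryHits(hits))
  if (any(multi)) {
    warning(sprintf("%d probe(s) fall in more than one window; assigned to the first",
                    length(unique(queryHits(hits)[multi]))))
    hits <- hits[!multi]
  }
  keep <- queryHits(hits)
  dropped <- length(pr) - length(keep)
  if (dropped > 0L)
    message(sprintf("dropped %d probe(s) falling in no gene window", dropped))
  pr <- pr[keep]
  mcols(pr)$gene_symbol <- mcols(gr)$gene_symbol[subjectHits(hits)]
  vals <- vals[keep, , drop = FALSE]
  ord <- order(match(mcols(pr)$gene_symbol, mcols(gr)$gene_symbol), start(pr))
  pr <- pr[ord]
  vals <- vals[ord, , drop = FALSE]
  rownames(vals) <- mcols(pr)$probe_id
  SummarizedExperiment(assays = list(log2ratio = vals), rowRanges = pr)
}

#' Write a probe x sample log2-ratio matrix
#'
#' @param se SummarizedExperiment from [readLogRatioMatrix()] or
#'   [simulateCohort()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeLogRatioMatrix <- function(se, path) {
  pr <- rowRanges(se)
  df <- data.frame(
    probe_id = mcols(pr)$probe_id,
    chrom = as.character(seqnames(pr)),
    position = start(pr),
    as.data.frame(assay(se, "log2ratio"), check.names = FALSE),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene x sample expression matrix
#'
#' First column `gene`, remaining columns numeric per-sample log2 ratios.
#'
#' @param path Path to the TSV file.
#' @return A `SummarizedExperiment` with assays `"expr"` and `"present"`
#'   (present = non-missing).
#' @export
readExpressionMatrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% colnames(df))
    stop("expression table is missing column(s): gene")
  vals <- as.matrix(df[, setdiff(colnames(df), "gene"), drop = FALSE])
  rownames(vals) <- df$gene
  SummarizedExperiment(assays = list(expr = vals, present = !is.na(vals)))
}

#' Write a gene x sample expression matrix
#'
#' @param se SummarizedExperiment with assay `"expr"`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(se, path) {
  vals <- assay(se, "expr")
  df <- data.frame(gene = rownames(vals),
                   as.data.frame(vals, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter expression rows by presence
#'
#' Keeps genes whose fraction of present values is at least `minPresent`
#' (default 0.70, i.e. the common "70% present" rule). Presence is taken
#' from per-channel intensities when supplied (both channels at or above
#' `minIntensity`), otherwise from the `"present"` assay, otherwise from
#' non-missingness.
#'
#' @param expr SummarizedExperiment with assay `"expr"`.
#' @param minIntensity Minimum per-channel intensity for a value to count
#'   as present (default 10); only used with `intensityR`/`intensityG`.
#' @param minPresent Minimum fraction of present values per gene,
#'   in `[0, 1]` (default 0.70).
#' @param intensityR,intensityG Optional per-channel intensity matrices,
#'   same shape as the expression assay.
#' @return The filtered `SummarizedExperiment`; surviving row order is
#'   preserved. Filtering is idempotent.
#' @export
applyPresenceFilter <- function(expr, minIntensity = 10, minPresent = 0.70,
                                intensityR = NULL, intensityG = NULL) {
  if (!is.numeric(minPresent) || length(minPresent) != 1L ||
      minPresent < 0 || minPresent > 1)
    stop("minPresent must be a single value in [0, 1]")
  vals <- assay(expr, "expr")
  if (!is.null(intensityR) || !is.null(intensityG)) {
    if (is.null(intensityR) || is.null(intensityG))
      stop("both channel intensity matrices are required")
    present <- intensityR >= minIntensity & intensityG >= minIntensity &
      !is.na(vals)
  } else if ("present" %in% names(assays(expr))) {
    present <- assay(expr, "present")
  } else {
    present <- !is.na(vals)
  }
  present[is.na(present)] <- FALSE
  frac <- rowMeans(present)
  keep <- frac >= minPresent
  se <- expr[keep, ]
  assays(se)$present <- present[keep, , drop = FALSE]
  se
}

#' Read a clinical table
#'
#' Requires columns `sample_id`, `subtype`, `os_time`, `os_event`,
#' `rfs_time`, `rfs_event`; times nonnegative, events 0/1.
#'
#' @param path Path to the TSV file.
#' @return A data.frame.
#' @export
readClinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "subtype", "os_time", "os_event", "rfs_time", "rfs_event")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop(sprintf("clinical table is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  if (any(df$os_time < 0) || any(df$rfs_time < 0))
    stop("survival times must be nonnegative")
  if (!all(df$os_event %in% c(0, 1)) || !all(df$rfs_event %in% c(0, 1)))
    stop("event indicators must be 0/1")
  df
}

#' Write segments in SEG format
#'
#' Standard tab-separated SEG: columns `Sample`, `Chromosome`, `Start`,
#' `End`, `Num_Probes`, `Segment_Mean`, 1-based inclusive coordinates.
#' The gene symbol and call are carried in extra columns `Gene` and
#' `Call` so the file round-trips through [readSegmentsSeg()].
#'
#' @param segments A segment data.frame as returned by [segmentCohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSegmentsSeg <- function(segments, path) {
  df <- data.frame(
    Sample = segments$sample,
    Chromosome = segments$chrom,
    Start = segments$start,
    End = segments$end,
    Num_Probes = segments$n_probes,
    Segment_Mean = segments$mean_log2,
    Gene = segments$gene,
    Call = segments$call,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segments from SEG format
#'
#' @param path SEG file written by [writeSegmentsSeg()] (or any standard
#'   SEG file; `Gene`/`Call` columns are optional).
#' @return A segment data.frame with internal column names.
#' @export
readSegmentsSeg <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  miss <- setdiff(need, colnames(df))
  if (length(miss) > 0L)
    stop(sprintf("SEG file is missing column(s): %s", paste(miss, collapse = ", ")))
  out <- data.frame(
    sample = as.character(df$Sample),
    gene = if ("Gene" %in% colnames(df)) as.character(df$Gene) else NA_character_,
    chrom = as.character(df$Chromosome),
    start = as.integer(df$Start),
    end = as.integer(df$End),
    n_probes = as.integer(df$Num_Probes),
    mean_log2 = as.numeric(df$Segment_Mean),
    call = if ("Call" %in% colnames(df)) as.character(df$Call) else NA_character_,
    stringsAsFactors = FALSE
  )
  out
}

#' Write a clinical table
#'
#' @param clinical data.frame or DataFrame of clinical records.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  utils::write.table(as.data.frame(clinical), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
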