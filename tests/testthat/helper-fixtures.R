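# Shared fixtures, built in code.

# two-gene window table (one per strand), pad applied by the constructor
tinyWindowTable <- function() {
  data.frame(
    gene = c("GA", "GB"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "-"),
    gene_start = c(10001L, 50001L),
    gene_end = c(20000L, 70000L),
    utr5_start = c(10001L, 69801L),
    utr5_end = c(10200L, 70000L),
    stringsAsFactors = FALSE
  )
}

tinyWindows <- function(padBp = 5000L) {
  geneWindowsFromTable(tinyWindowTable(), padBp = padBp)
}

writeTempTsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small synthetic cohort shared across tests (built once per run)
.fixtureCache <- new.env()

smallCohort <- function() {
  if (is.null(.fixtureCache$small)) {
    des <- designArray(
      arrayDesignParams(nGenes = 12L, geneLengthRange = c(10000L, 40000L)),
      seed = 303L)
    .fixtureCache$small <- suppressMessages(simulateCohort(
      des$windows, des$probes, cohortSimParams(nSamples = 24L, seed = 303L)))
    .fixtureCache$smallDesign <- des
  }
  .fixtureCache$small
}

smallCalls <- function() {
  if (is.null(.fixtureCache$calls)) {
    co <- smallCohort()
    seg <- segmentCohort(logRatios(co))
    .fixtureCache$segments <- seg
    .fixtureCache$calls <- callAberrations(
      seg, clinical = as.data.frame(clinicalData(co)))
  }
  .fixtureCache$calls
}

smallSegments <- function() {
  smallCalls()
  .fixtureCache$segments
}

# overlap-with-matching-kind helper used by recovery checks
truthMatched <- function(truth, calledMicro) {
  mapply(function(s, g, a, b, k) {
    any(calledMicro$Sample == s & calledMicro$Gene == g &
          calledMicro$Start <= b & calledMicro$Stop >= a &
          calledMicro$Kind == k)
  }, truth$sample_id, truth$gene_symbol, truth$start, truth$end, truth$kind)
}

callMatched <- function(calledMicro, truth) {
  mapply(function(s, g, a, b, k) {
    any(truth$sample_id == s & truth$gene_symbol == g &
          truth$start <= b & truth$end >= a & truth$kind == k)
  }, calledMicro$Sample, calledMicro$Gene, calledMicro$Start,
  calledMicro$Stop, calledMicro$Kind)
}
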