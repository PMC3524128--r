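#' Dichotomize expression about each gene's cohort median
#'
#' Per gene, the median is computed over non-missing samples (midpoint
#' convention for even counts); each value is labelled `"above"`
#' (strictly greater), `"below"` (strictly less) or `"at"` (equal).
#' `"at"` entries are excluded from all downstream counting. Genes with
#' fewer than 3 present values are excluded with a message.
#'
#' @param expr `SummarizedExperiment` with assay `"expr"`, or a numeric
#'   gene x sample matrix.
#' @return A gene x sample character matrix with entries `"above"`,
#'   `"below"`, `"at"` or `NA`.
#' @export
dichotomizeExpression <- function(expr) {
  vals <- if (is(expr, "SummarizedExperiment")) assay(expr, "expr") else expr
  present <- rowSums(!is.na(vals))
  drop <- present < 3L
  if (any(drop))
    message(sprintf("excluded %d gene(s) with fewer than 3 present values",
                    sum(drop)))
  vals <- vals[!drop, , drop = FALSE]
  med <- apply(vals, 1L, stats::median, na.rm = TRUE)
  out <- matrix(NA_character_, nrow(vals), ncol(vals), dimnames = dimnames(vals))
  out[] <- ifelse(is.na(vals), NA_character_,
                  ifelse(vals > med[row(vals)], "above",
                         ifelse(vals < med[row(vals)], "below", "at")))
  out
}

.CLASS_DIRECTION <- c("gross-gain" = "above", "micro-amp" = "above",
                      "gross-loss" = "below", "micro-del" = "below")

#' Per-gene concordance between copy-number status and expression
#'
#' A class-bearing sample is concordant when a gain/amplification is
#' accompanied by above-median expression, or a loss/deletion by
#' below-median expression. For each aberration class, counts the genes
#' whose class-bearing samples are all concordant (100%) and those at
#' least half concordant (>= 50%). Samples whose expression sits exactly
#' at the median are excluded; genes with no usable class-bearing sample
#' do not enter that class's denominator.
#'
#' @param status Gene x sample status matrix (from [callAberrations()]).
#' @param dicho Gene x sample dichotomized matrix
#'   (from [dichotomizeExpression()]).
#' @return A data.frame with one row per class: `class`,
#'   `n_genes_with_class`, `n_100pct`, `n_ge50pct`, `rate_100pct`,
#'   `rate_ge50pct`.
#' @export
geneConcordance <- function(status, dicho) {
  genes <- intersect(rownames(status), rownames(dicho))
  samples <- intersect(colnames(status), colnames(dicho))
  st <- status[genes, samples, drop = FALSE]
  dc <- dicho[genes, samples, drop = FALSE]
  classes <- names(.CLASS_DIRECTION)
  rows <- lapply(classes, function(cl) {
    dir <- .CLASS_DIRECTION[[cl]]
    nWith <- n100 <- n50 <- 0L
    for (g in genes) {
      sel <- st[g, ] == cl & dc[g, ] %in% c("above", "below")
      n <- sum(sel)
      if (n == 0L) next
      conc <- sum(dc[g, sel] == dir)
      nWith <- nWith + 1L
      if (conc == n) n100 <- n100 + 1L
      if (conc >= n / 2) n50 <- n50 + 1L
    }
    data.frame(class = cl, n_genes_with_class = nWith, n_100pct = n100,
               n_ge50pct = n50,
               rate_100pct = if (nWith > 0L) n100 / nWith else NA_real_,
               rate_ge50pct = if (nWith > 0L) n50 / nWith else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled 2x2 contingency table of expression by aberration class
#'
#' Pools (gene, sample) pairs across all genes: rows are above/below the
#' gene's median expression, columns are class present/absent. Pairs at
#' the median (or with missing expression) are excluded.
#'
#' @param status Gene x sample status matrix.
#' @param dicho Gene x sample dichotomized matrix.
#' @param classFilter `"micro-amp"`, `"micro-del"` or `"any-micro"`.
#' @return A 2x2 integer matrix with dimnames
#'   `c("above", "below") x c("present", "absent")`.
#' @export
pooledContingency <- function(status, dicho,
                              classFilter = c("micro-amp", "micro-del", "any-micro")) {
  classFilter <- match.arg(classFilter)
  genes <- intersect(rownames(status), rownames(dicho))
  samples <- intersect(colnames(status), colnames(dicho))
  st <- status[genes, samples, drop = FALSE]
  dc <- dicho[genes, samples, drop = FALSE]
  present <- if (classFilter == "any-micro") {
    st == "micro-amp" | st == "micro-del"
  } else {
    st == classFilter
  }
  above <- !is.na(dc) & dc == "above"
  below <- !is.na(dc) & dc == "below"
  usable <- above | below
  tab <- matrix(c(
    sum(usable & present & above), sum(usable & !present & above),
    sum(usable & present & !above), sum(usable & !present & !above)
  ), nrow = 2L, byrow = TRUE,
  dimnames = list(c("above", "below"), c("present", "absent")))
  storage.mode(tab) <- "integer"
  tab
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood convention: the sum
#' of hypergeometric point probabilities not exceeding that of the
#' observed table (with relative tolerance 1e-7 in the comparison). Any
#' zero margin yields p = 1.
#'
#' @param table A 2x2 matrix of nonnegative integer counts, or the count
#'   `a` when `b`, `c`, `d` are given.
#' @param b,c,d Optional remaining cells (row-major: `a`,`b` top row).
#' @return The two-sided p-value, in (0, 1].
#' @export
fisherExact2x2 <- function(table, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) table <- matrix(c(table, b, c, d), 2L, 2L, byrow = TRUE)
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  x <- as.vector(t(table))
  if (any(x < 0) || any(x != round(x)))
    stop("cells must be nonnegative integers")
  a <- x[1L]; bb <- x[2L]; cc <- x[3L]; dd <- x[4L]
  r1 <- a + bb; c1 <- a + cc; n <- a + bb + cc + dd
  if (r1 == 0L || c1 == 0L || r1 == n || c1 == n) return(1)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p0 <- stats::dhyper(a, c1, n - c1, r1)
  p <- sum(probs[probs <= p0 * (1 + 1e-7)])
  min(1, p)
}

#' One-way ANOVA of expression by aberration status
#'
#' Two-group fixed-effects one-way ANOVA (pooled variance; the square of
#' the pooled-variance t statistic), comparing aberrant versus
#' non-aberrant samples for one gene.
#'
#' @param values Numeric expression values.
#' @param groups Two-level factor/character vector (e.g. `"aberrant"` /
#'   `"non-aberrant"`), same length as `values`.
#' @return A list with `F` and `p` (df 1 and n - 2); both `NA` with a
#'   warning when either group has fewer than 2 non-missing values.
#' @export
anovaByStatus <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) != 2L || any(table(groups) < 2L)) {
    warning("each group needs at least 2 samples; returning NA")
    return(list(F = NA_real_, p = NA_real_))
  }
  ht <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value))
}

#' Per-gene ANOVA across a cohort
#'
#' Runs [anovaByStatus()] for every gene, comparing samples whose status
#' is in `aberrantClasses` against all others.
#'
#' @param expr Expression `SummarizedExperiment` or matrix.
#' @param status Gene x sample status matrix.
#' @param aberrantClasses Statuses counted as aberrant
#'   (default the two micro classes).
#' @return A data.frame `gene`, `n_aberrant`, `n_other`, `F`, `p` for
#'   genes with at least 2 samples per group.
#' @export
perGeneAnova <- function(expr, status,
                         aberrantClasses = c("micro-amp", "micro-del")) {
  vals <- if (is(expr, "SummarizedExperiment")) assay(expr, "expr") else expr
  genes <- intersect(rownames(status), rownames(vals))
  samples <- intersect(colnames(status), colnames(vals))
  rows <- list()
  for (g in genes) {
    ab <- status[g, samples] %in% aberrantClasses
    v <- vals[g, samples]
    ok <- !is.na(v)
    if (sum(ab & ok) < 2L || sum(!ab & ok) < 2L) next
    res <- anovaByStatus(v[ok], ifelse(ab[ok], "aberrant", "non-aberrant"))
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, n_aberrant = sum(ab & ok), n_other = sum(!ab & ok),
      F = res$F, p = res$p, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0), n_aberrant = integer(0),
                      n_other = integer(0), F = numeric(0), p = numeric(0)))
  do.call(rbind, rows)
}
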