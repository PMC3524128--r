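#' Default pipeline configuration
#'
#' Full configuration list for [runPipeline()] with every stage at its
#' default. Block names and fields mirror the parameter constructors
#' ([arrayDesignParams()], [cohortSimParams()], [segmentationParams()],
#' [microDefinition()]).
#'
#' @param seed Integer seed propagated to all stochastic stages.
#' @return A nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(array = list(), cohort = list()),
    segmentation = list(),
    calling = list(),
    position = list(minOverlap = 1L, promoterDefinition = "tss"),
    integrate = list(minPresent = 0.70, minIntensity = 10),
    chance = list(threshold = 0.30, mode = "exact"),
    survive = list(lowerFraction = 0.33),
    io = list()
  )
}

# construct and validate every stage's parameters before any stage runs
.validateConfig <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config must carry a seed")
  cfg <- utils::modifyList(defaultPipelineConfig(config$seed), config)
  # load mode when a probe matrix path is configured; simulate otherwise
  if (is.null(cfg$io$probes)) {
    arrayArgs <- cfg$simulate$array %||% list()
    cohortArgs <- cfg$simulate$cohort %||% list()
    cohortArgs$seed <- cfg$seed
    cfg$.arrayParams <- do.call(arrayDesignParams, arrayArgs)
    cfg$.cohortParams <- do.call(cohortSimParams, cohortArgs)
  } else {
    if (is.null(cfg$io$windows))
      stop("config with io$probes must also provide io$windows")
    if (!is.null(cfg$integrate) && is.null(cfg$io$expression))
      stop("integrate stage enabled but no expression table configured")
    if (!is.null(cfg$survive) && is.null(cfg$io$clinical))
      stop("survive stage enabled but no clinical table configured")
  }
  cfg$.segParams <- do.call(segmentationParams, cfg$segmentation %||% list())
  cfg$.microDef <- do.call(microDefinition, cfg$calling %||% list())
  stopifnot(cfg$survive$lowerFraction > 0, cfg$survive$lowerFraction < 1)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full micro-aberration pipeline
#'
#' Orchestrates simulate (or load) -> segment -> call -> position ->
#' integrate -> chance -> survive with one configuration and one seed.
#' Every stage's parameters are validated before any stage runs; each
#' stage consumes and produces files under `outdir`, so any stage can be
#' rerun from disk. A failing stage leaves a `FAILED` marker naming the
#' stage; a rerun with an identical configuration reproduces identical
#' outputs.
#'
#' @param config A configuration list (see [defaultPipelineConfig()]) or
#'   the path of a YAML file with the same structure.
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config = defaultPipelineConfig(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cfg <- .validateConfig(config)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logPath <- file.path(outdir, "run.log")
  cat("", file = logPath)
  logline <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", file = logPath, sep = "", append = TRUE)
    message(msg)
  }
  outputs <- character(0)
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logline("stage %-10s done in %.2f s", name, proc.time()[["elapsed"]] - t0)
    res
  }

  # --- simulate / load -------------------------------------------------
  env <- new.env()
  stage("simulate", function() {
    if (!is.null(cfg$.arrayParams)) {
      des <- designArray(cfg$.arrayParams, seed = cfg$seed)
      cohort <- simulateCohort(des$windows, des$probes, cfg$.cohortParams)
      writeCohort(cohort, outdir)
      env$windows <- geneWindows(cohort)
      env$lr <- logRatios(cohort)
      env$expr <- expressionData(cohort)
      env$clinical <- as.data.frame(clinicalData(cohort))
      outputs <<- c(outputs, file.path(outdir, c(
        "gene_windows.tsv", "probes_log2.tsv", "expression.tsv",
        "clinical.tsv", "truth.tsv")))
    } else {
      env$windows <- readGeneWindows(cfg$io$windows,
                                     padBp = cfg$io$padBp %||% 5000L)
      env$lr <- readLogRatioMatrix(cfg$io$probes, env$windows)
      if (!is.null(cfg$io$expression))
        env$expr <- readExpressionMatrix(cfg$io$expression)
      if (!is.null(cfg$io$clinical))
        env$clinical <- readClinical(cfg$io$clinical)
    }
    invisible(NULL)
  })

  # --- segment ---------------------------------------------------------
  stage("segment", function() {
    env$segments <- segmentCohort(env$lr, cfg$.segParams)
    outputs <<- c(outputs,
                  writeSegmentsSeg(env$segments, file.path(outdir, "segments.seg")))
  })

  # --- call ------------------------------------------------------------
  stage("call", function() {
    env$calls <- callAberrations(env$segments, cfg$.microDef,
                                 clinical = env$clinical)
    statusDf <- data.frame(gene = rownames(env$calls$status),
                           env$calls$status, check.names = FALSE,
                           stringsAsFactors = FALSE)
    outputs <<- c(outputs,
      .tsv(env$calls$micro, file.path(outdir, "micro_aberrations.tsv")),
      .tsv(statusDf, file.path(outdir, "status_matrix.tsv")))
  })

  # --- position --------------------------------------------------------
  stage("position", function() {
    env$quad <- tallyQuadrants(env$calls$micro, env$windows,
                               minOverlap = cfg$position$minOverlap,
                               promoterDefinition = cfg$position$promoterDefinition)
    qs <- env$quad$quadrants
    extra <- data.frame(
      label = c("promoter", "5'UTR", "5'End-only promoter", "5'End-only 5'UTR"),
      affected = NA_integer_, possible = NA_integer_,
      proportion = c(env$quad$promoter_rate, env$quad$utr5_rate,
                     env$quad$five_prime_only$promoter_rate,
                     env$quad$five_prime_only$utr5_rate),
      stringsAsFactors = FALSE)
    outputs <<- c(outputs,
      .tsv(rbind(qs, extra), file.path(outdir, "quadrant_summary.tsv")),
      .tsv(cbind(env$calls$micro[, c("Sample", "Gene")], env$quad$flags),
           file.path(outdir, "instance_flags.tsv")))
  })

  # --- integrate -------------------------------------------------------
  if (!is.null(cfg$integrate) && !is.null(env$expr)) {
    stage("integrate", function() {
      filt <- applyPresenceFilter(env$expr,
                                  minIntensity = cfg$integrate$minIntensity,
                                  minPresent = cfg$integrate$minPresent)
      dicho <- dichotomizeExpression(filt)
      conc <- geneConcordance(env$calls$status, dicho)
      tabs <- lapply(c("micro-amp", "micro-del", "any-micro"), function(cl) {
        tb <- pooledContingency(env$calls$status, dicho, cl)
        data.frame(class = cl,
                   above_present = tb[1, 1], above_absent = tb[1, 2],
                   below_present = tb[2, 1], below_absent = tb[2, 2],
                   fisher_p = fisherExact2x2(tb), stringsAsFactors = FALSE)
      })
      env$contingency <- do.call(rbind, tabs)
      env$concordance <- conc
      env$anova <- perGeneAnova(filt, env$calls$status)
      outputs <<- c(outputs,
        .tsv(conc, file.path(outdir, "concordance.tsv")),
        .tsv(env$contingency, file.path(outdir, "contingency.tsv")),
        .tsv(env$anova, file.path(outdir, "anova.tsv")))
    })
  }

  # --- chance ----------------------------------------------------------
  stage("chance", function() {
    env$chance <- chanceModelTable(env$lr, env$calls$micro,
                                   threshold = cfg$chance$threshold,
                                   minProbes = cfg$.segParams$minProbes,
                                   maxProbes = env$calls$cutoff,
                                   mode = cfg$chance$mode)
    outputs <<- c(outputs,
                  .tsv(env$chance, file.path(outdir, "chance_model.tsv")))
  })

  # --- survive ---------------------------------------------------------
  if (!is.null(cfg$survive) && !is.null(env$clinical)) {
    stage("survive", function() {
      sv <- survivalByBurden(env$calls$micro, env$clinical,
                             lowerFraction = cfg$survive$lowerFraction)
      kmRows <- list()
      for (ep in names(sv$km)) for (g in names(sv$km[[ep]])) {
        df <- sv$km[[ep]][[g]]
        df$endpoint <- ep; df$group <- g
        kmRows[[length(kmRows) + 1L]] <- df
      }
      lrDf <- data.frame(
        endpoint = names(sv$logrank),
        statistic = vapply(sv$logrank, `[[`, numeric(1), "statistic"),
        p = vapply(sv$logrank, `[[`, numeric(1), "p"),
        row.names = NULL, stringsAsFactors = FALSE)
      env$survival <- sv
      outputs <<- c(outputs,
        .tsv(sv$groups, file.path(outdir, "survival_groups.tsv")),
        .tsv(do.call(rbind, kmRows), file.path(outdir, "km_curves.tsv")),
        .tsv(lrDf, file.path(outdir, "logrank.tsv")))
    })
  }

  manifest <- list(
    package = "microCNA",
    version = as.character(utils::packageVersion("microCNA")),
    seed = cfg$seed,
    outputs = {
      o <- sort(unique(outputs))
      stats::setNames(as.list(unname(tools::md5sum(o))), basename(o))
    }
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Build report tables from a pipeline run
#'
#' Writes four summary TSVs with the semantics of the study's headline
#' tables: micro-aberration burden by subtype, concordance by aberration
#' class, pooled expression contingency tables with Fisher p-values, and
#' the per-gene chance-model table. Sections whose stage outputs are
#' missing are skipped with a message.
#'
#' @param runDir Directory produced by [runPipeline()].
#' @return Character vector of report paths written, invisibly.
#' @export
makeReport <- function(runDir) {
  written <- character(0)
  need <- function(f) {
    p <- file.path(runDir, f)
    if (!file.exists(p)) {
      message(sprintf("skipping report section: missing %s", f))
      return(NULL)
    }
    p
  }
  micro <- need("micro_aberrations.tsv")
  clin <- need("clinical.tsv")
  if (!is.null(micro) && !is.null(clin)) {
    tab1 <- perSubtypeSummary(
      utils::read.delim(micro, stringsAsFactors = FALSE),
      utils::read.delim(clin, stringsAsFactors = FALSE))
    written <- c(written, .tsv(tab1, file.path(runDir, "report_subtype.tsv")))
  }
  conc <- need("concordance.tsv")
  if (!is.null(conc))
    written <- c(written,
      .tsv(utils::read.delim(conc, stringsAsFactors = FALSE, check.names = FALSE),
           file.path(runDir, "report_concordance.tsv")))
  cont <- need("contingency.tsv")
  if (!is.null(cont))
    written <- c(written,
      .tsv(utils::read.delim(cont, stringsAsFactors = FALSE, check.names = FALSE),
           file.path(runDir, "report_contingency.tsv")))
  chance <- need("chance_model.tsv")
  if (!is.null(chance)) {
    ch <- utils::read.delim(chance, stringsAsFactors = FALSE, check.names = FALSE)
    ch$occurrences <- sprintf("%d/%d/%d", ch$observed_all, ch$observed_amp,
                              ch$observed_del)
    written <- c(written,
      .tsv(ch[, c("gene", "occurrences", "expected", "p_display")],
           file.path(runDir, "report_chance.tsv")))
  }
  invisible(written)
}
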