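## End-to-end orchestration: scores -> network -> propagation -> top-k
## validation -> agent prediction, with a machine-readable JSON run report.
##
## Every run also evaluates the raw -log p ordering (the d = 0 arm) next to
## the propagated one, because every headline question about the method is a
## paired comparison against ranking on the association scores alone.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

.fingerprint <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.pipelineDefaults <- function() {
  list(topK = 100, transpose = FALSE, keepUnscored = FALSE,
       rank = list(d = 0.5, epsilon = 1e-5, logBase = 10, pMin = 1e-300,
                   maxIter = 1000))
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: gene-score acquisition, dependency-network
#' acquisition, score propagation (plus the raw-score comparison arm), top-k
#' validation against a disease-gene reference (chi-squared between the two
#' arms, and top-of-list KS enrichment of supported agents' targets), and
#' candidate-agent prediction with clinical-support rates. All intermediate
#' tables and a JSON report are written to the output directory; with a
#' fixed config (including the seed) the report is identical across runs.
#'
#' @param config A named list, or the path of a YAML file holding one.
#'   Fields: \code{outputDir} (required); exactly one of \code{simulate} (a
#'   list of [SimulationConfig()] arguments) or \code{inputs} (paths
#'   \code{scores}, \code{network}, and optionally \code{reference} (GMT)
#'   and \code{drugTargets}); optional \code{rank} (a list of
#'   [RankConfig()] arguments, default \code{d = 0.5},
#'   \code{epsilon = 1e-5}), \code{topK} (default 100), \code{transpose},
#'   \code{keepUnscored}, \code{seed}.
#' @param quiet Suppress per-stage log messages?
#' @return The run report, invisibly also written to
#'   \code{<outputDir>/report.json} (plus a Markdown digest). Main entries:
#'   \code{parameters}, \code{fingerprints}, \code{counts}, and
#'   \code{statistics} with the per-arm overlap, chi-squared, KS and
#'   support-rate results.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  def <- .pipelineDefaults()
  cfg <- utils::modifyList(def, config)
  if (is.null(cfg$outputDir)) stop("config must name an 'outputDir'")
  if (is.null(cfg$simulate) == is.null(cfg$inputs))
    stop("config must hold exactly one of 'simulate' or 'inputs'")
  if (cfg$topK < 1) stop("topK must be at least 1")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  rc <- do.call(RankConfig, cfg$rank)
  inputPaths <- character(0)

  ## -- stage: scores ---------------------------------------------------
  reference <- NULL; drugTargets <- NULL; truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate", {
      sc <- do.call(SimulationConfig, cfg$simulate)
      simulateAll(sc)
    })
    truth <- sim$truth
    scores <- sim$scores; net <- sim$network
    reference <- sim$reference; drugTargets <- sim$drugTargets
    inputPaths <- writeSimulatedData(sim, file.path(cfg$outputDir, "inputs"))
    say("simulate: %d genes (%d planted disease), %d edges, %d agents",
        length(geneIds(scores)), length(truth$diseaseGenes),
        edgeCount(net), length(agents(drugTargets)))
  } else {
    scores <- .stage("scores", {
      if (is.null(cfg$inputs$scores)) stop("inputs$scores is required")
      readGeneScores(cfg$inputs$scores, pMin = rc@pMin)
    })
    say("scores: %d genes read", length(geneIds(scores)))
    net <- .stage("rank", {
      if (is.null(cfg$inputs$network)) stop("inputs$network is required")
      readEdgeList(cfg$inputs$network)
    })
    if (!is.null(cfg$inputs$reference))
      reference <- .stage("validate", readGmt(cfg$inputs$reference))
    if (!is.null(cfg$inputs$drugTargets))
      drugTargets <- .stage("predict", readDrugTargets(cfg$inputs$drugTargets))
    inputPaths <- unlist(cfg$inputs)
  }

  ## -- stage: rank ------------------------------------------------------
  arms <- .stage("rank", {
    scores <- computeInitialScores(scores, rc)
    prop <- geneRank(net, scores, rc, keepUnscored = isTRUE(cfg$keepUnscored),
                     transpose = isTRUE(cfg$transpose))
    raw <- geneRank(net, scores,
                    RankConfig(d = 0, epsilon = rc@epsilon,
                               logBase = rc@logBase, pMin = rc@pMin),
                    keepUnscored = isTRUE(cfg$keepUnscored),
                    transpose = isTRUE(cfg$transpose))
    list(phewasRank = rankGenes(prop), raw = rankGenes(raw), result = prop)
  })
  k <- min(cfg$topK, length(arms$phewasRank))
  tops <- lapply(arms[c("phewasRank", "raw")], topGenes, k = k)
  writeRankedGenes(arms$phewasRank,
                   file.path(cfg$outputDir, "ranked_phewas_rank.tsv"))
  writeRankedGenes(arms$raw, file.path(cfg$outputDir, "ranked_raw.tsv"))
  say("rank: universe %d, %d iterations (residual %.3g), top-%d selected",
      length(arms$phewasRank), arms$result@nIterations,
      arms$result@finalResidual, k)

  ## -- stage: validate --------------------------------------------------
  statistics <- list()
  refGenes <- if (!is.null(reference) && length(reference) > 0)
    unique(unlist(geneSets(reference))) else NULL
  if (!is.null(refGenes)) {
    statistics$overlap <- .stage("validate", lapply(tops, function(g) {
      overlapStats(g, refGenes)
    }))
    statistics$topkChi2 <- .stage("validate", {
      aIn <- statistics$overlap$phewasRank$count
      bIn <- statistics$overlap$raw$count
      tab <- matrix(c(aIn, k - aIn, bIn, k - bIn), 2, byrow = TRUE)
      res <- tryCatch(suppressWarnings(chiSquare2x2(tab)),
                      error = function(e) list(statistic = NA_real_,
                                               p.value = NA_real_,
                                               note = conditionMessage(e)))
      res$table <- NULL
      res
    })
    say("validate: top-%d in-reference %d (propagated) vs %d (raw), p = %s",
        k, statistics$overlap$phewasRank$count, statistics$overlap$raw$count,
        format(statistics$topkChi2$p.value, digits = 3))
  }
  if (!is.null(drugTargets)) {
    supTargets <- unique(drugTargets@targetId[
      drugTargets@support[drugTargets@agentId]])
    statistics$ksTargets <- .stage("validate", lapply(
      arms[c("phewasRank", "raw")], function(rl) {
        tryCatch(ksTopEnrichment(rl, supTargets),
                 error = function(e) list(D = NA_real_, p.value = NA_real_,
                                          note = conditionMessage(e)))
      }))
  }

  ## -- stage: predict ---------------------------------------------------
  if (!is.null(drugTargets)) {
    preds <- .stage("predict", lapply(tops, predictAgents, table = drugTargets))
    utils::write.table(preds$phewasRank,
                       file.path(cfg$outputDir, "agents_phewas_rank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    statistics$support <- lapply(preds, function(p) {
      if (nrow(p) == 0) list(nSupported = 0L, nTotal = 0L, percent = NA_real_)
      else clinicalSupportRate(p)
    })
    statistics$supportChi2 <- tryCatch({
      a <- statistics$support$phewasRank; b <- statistics$support$raw
      res <- suppressWarnings(compareSupport(c(a$nSupported, a$nTotal),
                                             c(b$nSupported, b$nTotal)))
      res$table <- NULL
      res
    }, error = function(e) list(statistic = NA_real_, p.value = NA_real_,
                                note = conditionMessage(e)))
    say("predict: %d agents (%.2f%% supported) vs %d raw (%.2f%%)",
        statistics$support$phewasRank$nTotal,
        statistics$support$phewasRank$percent,
        statistics$support$raw$nTotal, statistics$support$raw$percent)
  }
  if (!is.null(truth)) {
    statistics$recovery <- list(
      aucPhewasRank = rankRecoveryAUC(rankScores(arms$phewasRank),
                                      truth$diseaseGenes),
      aucRaw = rankRecoveryAUC(rankScores(arms$raw), truth$diseaseGenes))
  }

  report <- list(
    tool = "PheWASRank",
    version = as.character(utils::packageVersion("PheWASRank")),
    seed = if (!is.null(cfg$simulate)) {
      do.call(SimulationConfig, cfg$simulate)@seed
    } else cfg$seed,
    parameters = list(d = rc@d, epsilon = rc@epsilon, logBase = rc@logBase,
                      topK = cfg$topK, transpose = isTRUE(cfg$transpose),
                      keepUnscored = isTRUE(cfg$keepUnscored)),
    fingerprints = .fingerprint(inputPaths),
    counts = list(genes = length(geneIds(scores)), edges = edgeCount(net),
                  universe = length(arms$phewasRank), topK = k,
                  iterations = arms$result@nIterations,
                  converged = converged(arms$result)),
    statistics = statistics)
  jsonlite::write_json(report, file.path(cfg$outputDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  .writeSummaryMd(report, file.path(cfg$outputDir, "summary.md"))
  invisible(report)
}

.writeSummaryMd <- function(report, path) {
  fmt <- function(x) if (is.null(x) || length(x) == 0 || is.na(x)) "-" else
    format(x, digits = 4)
  lines <- c("# PheWASRank run summary", "",
             sprintf("- genes: %d, edges: %d, analysis universe: %d",
                     report$counts$genes, report$counts$edges,
                     report$counts$universe),
             sprintf("- d = %g, epsilon = %g, top-k = %d",
                     report$parameters$d, report$parameters$epsilon,
                     report$parameters$topK),
             "", "| statistic | propagated | raw |", "|---|---|---|")
  st <- report$statistics
  if (!is.null(st$overlap))
    lines <- c(lines, sprintf("| top-k in reference | %d (%s%%) | %d (%s%%) |",
                              st$overlap$phewasRank$count,
                              fmt(st$overlap$phewasRank$percent),
                              st$overlap$raw$count,
                              fmt(st$overlap$raw$percent)))
  if (!is.null(st$topkChi2))
    lines <- c(lines, sprintf("| top-k chi-squared p | %s | |",
                              fmt(st$topkChi2$p.value)))
  if (!is.null(st$ksTargets))
    lines <- c(lines, sprintf("| KS target-enrichment p | %s | %s |",
                              fmt(st$ksTargets$phewasRank$p.value),
                              fmt(st$ksTargets$raw$p.value)))
  if (!is.null(st$support))
    lines <- c(lines, sprintf("| supported agents | %d/%d (%s%%) | %d/%d (%s%%) |",
                              st$support$phewasRank$nSupported,
                              st$support$phewasRank$nTotal,
                              fmt(st$support$phewasRank$percent),
                              st$support$raw$nSupported, st$support$raw$nTotal,
                              fmt(st$support$raw$percent)))
  if (!is.null(st$recovery))
    lines <- c(lines, sprintf("| planted-gene AUROC | %s | %s |",
                              fmt(st$recovery$aucPhewasRank),
                              fmt(st$recovery$aucRaw)))
  writeLines(lines, path)
  invisible(path)
}
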