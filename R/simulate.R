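## Seeded generators emulating every input the pipeline consumes, with a
## planted disease-gene truth so each stage has a recoverable signal. Every
## generator is a pure function of (config, seed); stage seeds are derived
## from config@seed by small fixed offsets so the stages are independently
## reproducible.

.stageSeed <- function(config, offset) (config@seed + offset) %% .Machine$integer.max

#' Simulate gene-level association scores with a planted disease subpopulation
#'
#' Planted disease genes draw p-values from Beta(\code{betaA}, 1) — the
#' standard one-parameter enrichment model, stochastically smaller than
#' uniform for \code{betaA < 1} — and null genes from Uniform(0, 1).
#'
#' @param config A [SimulationConfig].
#' @return A list (the synthetic truth) with \code{scores}
#'   (a [GeneScoreTable]), \code{diseaseGenes} (character) and \code{config}.
#' @examples
#' truth <- simulateGeneScores(SimulationConfig(nGenes = 100, seed = 7))
#' length(truth$diseaseGenes)  # 5
#' @export
simulateGeneScores <- function(config = SimulationConfig()) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  ids <- sprintf("G%05d", seq_len(config@nGenes))
  nDisease <- round(config@piDisease * config@nGenes)
  withr::with_seed(.stageSeed(config, 0L), {
    disease <- sort(sample(ids, nDisease))
    p <- stats::runif(config@nGenes)
    isD <- ids %in% disease
    p[isD] <- stats::rbeta(sum(isD), config@betaA, 1)
  })
  p <- pmin(pmax(p, 1e-300), 1)
  list(scores = GeneScoreTable(geneId = ids, pValue = p),
       diseaseGenes = disease, config = config)
}

#' Simulate a directed dependency network by homophilous preferential attachment
#'
#' Nodes are introduced in random order; each new node draws
#' \code{min(mEdges, #existing)} distinct out-neighbours among the nodes
#' already present, with attachment weight proportional to
#' (in-degree + 1) x (\code{homophily} when both endpoints are planted
#' disease genes, else 1). This yields the heavy-tailed in-degree profile of
#' real dependency networks plus, for \code{homophily > 1}, a planted
#' disease module. No self-loops or duplicate edges arise by construction.
#'
#' @param truth Output of [simulateGeneScores()].
#' @param config A [SimulationConfig] (defaults to \code{truth$config}).
#' @return A [DependencyNetwork] over the full simulated gene universe.
#' @export
simulateNetwork <- function(truth, config = truth$config) {
  stopifnot(is(config, "SimulationConfig"))
  ids <- geneIds(truth$scores)
  n <- length(ids)
  if (config@mEdges >= n) stop("mEdges must be smaller than the gene count")
  isD <- ids %in% truth$diseaseGenes
  withr::with_seed(.stageSeed(config, 1L), {
    ord <- sample.int(n)
    indeg <- integer(n)
    fromL <- vector("list", n); toL <- vector("list", n)
    for (t in 2:n) {
      new <- ord[t]
      cand <- ord[seq_len(t - 1)]
      w <- indeg[cand] + 1
      if (isD[new]) w <- w * ifelse(isD[cand], config@homophily, 1)
      k <- min(config@mEdges, t - 1L)
      nbr <- cand[sample.int(length(cand), k, prob = w)]
      fromL[[t]] <- rep.int(new, k); toL[[t]] <- nbr
      indeg[nbr] <- indeg[nbr] + 1L
    }
  })
  DependencyNetwork(from = ids[unlist(fromL)], to = ids[unlist(toL)],
                    nodes = ids)
}

#' Simulate a disease-gene reference database
#'
#' Each planted disease gene enters the reference set with probability
#' \code{dbSensitivity}; each null gene with probability \code{dbFpr}
#' (database contamination).
#'
#' @param truth Output of [simulateGeneScores()].
#' @param config A [SimulationConfig] (defaults to \code{truth$config}).
#' @param setName Name of the emitted reference set.
#' @return A [GeneSetCollection] with one set (empty collection when no gene
#'   is sampled at all).
#' @export
simulateReferenceDb <- function(truth, config = truth$config,
                                setName = "disease_reference") {
  stopifnot(is(config, "SimulationConfig"))
  ids <- geneIds(truth$scores)
  isD <- ids %in% truth$diseaseGenes
  withr::with_seed(.stageSeed(config, 2L), {
    keep <- stats::runif(length(ids)) <
      ifelse(isD, config@dbSensitivity, config@dbFpr)
  })
  if (!any(keep)) return(GeneSetCollection(sets = list()))
  GeneSetCollection(sets = stats::setNames(list(ids[keep]), setName))
}

#' Simulate a drug-target table with clinical-support labels
#'
#' A fraction \code{piSupported} of agents is flagged clinically supported;
#' supported agents draw their \code{targetsPerAgent} distinct targets with
#' sampling weight \code{supportEnrichment} on planted disease genes, while
#' unsupported agents draw uniformly. This makes clinical support an
#' imperfect, disease-linked label, as in curated registries.
#'
#' @param truth Output of [simulateGeneScores()].
#' @param config A [SimulationConfig] (defaults to \code{truth$config}).
#' @return A [DrugTargetTable].
#' @export
simulateDrugTargets <- function(truth, config = truth$config) {
  stopifnot(is(config, "SimulationConfig"))
  ids <- geneIds(truth$scores)
  if (config@targetsPerAgent > length(ids))
    stop("targetsPerAgent exceeds the gene count")
  isD <- ids %in% truth$diseaseGenes
  agents <- sprintf("A%04d", seq_len(config@nAgents))
  withr::with_seed(.stageSeed(config, 3L), {
    supported <- stats::runif(config@nAgents) < config@piSupported
    wSup <- ifelse(isD, config@supportEnrichment, 1)
    tg <- lapply(seq_len(config@nAgents), function(a) {
      w <- if (supported[a]) wSup else rep(1, length(ids))
      ids[sample.int(length(ids), config@targetsPerAgent, prob = w)]
    })
  })
  DrugTargetTable(agentId = rep(agents, each = config@targetsPerAgent),
                  targetId = unlist(tg),
                  supported = rep(supported, each = config@targetsPerAgent))
}

#' Simulate expression and a binary prognosis phenotype
#'
#' A balanced binary phenotype; a chain of planted disease genes carries the
#' signal: the first chain gene is mean-shifted by \code{effect} between
#' phenotype classes, each downstream chain gene is regressed on its upstream
#' neighbour (autoregressive coefficient 0.8) plus Gaussian noise, and all
#' other genes are standard normal noise.
#'
#' @param truth Output of [simulateGeneScores()].
#' @param config A [SimulationConfig] (defaults to \code{truth$config}).
#' @param nSamples Number of samples (>= 16; kept balanced).
#' @param effect Mean shift of the first chain gene between classes.
#' @param chainLength Number of chained disease genes (default 3).
#' @return A \code{SummarizedExperiment}: assay \code{"expr"} (genes x
#'   samples), colData column \code{phenotype} (factor good/poor), and
#'   \code{metadata()$chainGenes} naming the signal chain.
#' @export
simulateExpression <- function(truth, config = truth$config, nSamples = 200,
                               effect = 3, chainLength = 3) {
  stopifnot(is(config, "SimulationConfig"))
  if (nSamples < 16) stop("need at least 16 samples (8 per class)")
  ids <- geneIds(truth$scores)
  half <- nSamples %/% 2
  nSamples <- 2L * half
  z <- rep(c(0, 1), each = half)
  chain <- utils::head(truth$diseaseGenes, chainLength)
  withr::with_seed(.stageSeed(config, 4L), {
    mat <- matrix(stats::rnorm(length(ids) * nSamples), nrow = length(ids),
                  dimnames = list(ids, sprintf("S%03d", seq_len(nSamples))))
    if (length(chain) >= 1)
      mat[chain[1], ] <- effect * z + stats::rnorm(nSamples)
    if (length(chain) > 1)
      for (k in 2:length(chain))
        mat[chain[k], ] <- 0.8 * mat[chain[k - 1], ] +
          0.6 * stats::rnorm(nSamples)
  })
  pheno <- factor(ifelse(z == 1, "poor", "good"), levels = c("good", "poor"))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = mat),
    colData = S4Vectors::DataFrame(phenotype = pheno,
                                   row.names = colnames(mat)))
  S4Vectors::metadata(se)$chainGenes <- chain
  se
}

#' Simulate every pipeline input at once
#'
#' Convenience wrapper calling the individual generators with a shared
#' config; the result feeds [runPipeline()] or can be written to disk with
#' [writeSimulatedData()].
#'
#' @param config A [SimulationConfig].
#' @param expression Also simulate expression + phenotype? (Off by default:
#'   the dependency-network construction stage is optional.)
#' @param nSamples,effect Passed to [simulateExpression()].
#' @return List with \code{truth}, \code{scores}, \code{network},
#'   \code{reference}, \code{drugTargets} and optionally \code{expression}.
#' @export
simulateAll <- function(config = SimulationConfig(), expression = FALSE,
                        nSamples = 200, effect = 3) {
  truth <- simulateGeneScores(config)
  out <- list(truth = truth, scores = truth$scores,
              network = simulateNetwork(truth, config),
              reference = simulateReferenceDb(truth, config),
              drugTargets = simulateDrugTargets(truth, config))
  if (expression)
    out$expression <- simulateExpression(truth, config, nSamples, effect)
  out
}

#' Write a simulated data bundle to a directory
#'
#' Emits scores.tsv, edges.tsv, reference.gmt, drug_targets.tsv and
#' truth.txt (the planted disease genes, one per line), plus expr.tsv and
#' pheno.tsv when expression was simulated.
#'
#' @param sim Output of [simulateAll()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulatedData <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(scores = file.path(dir, "scores.tsv"),
             edges = file.path(dir, "edges.tsv"),
             reference = file.path(dir, "reference.gmt"),
             drugTargets = file.path(dir, "drug_targets.tsv"),
             truth = file.path(dir, "truth.txt"))
  writeGeneScores(sim$scores, paths["scores"])
  writeEdgeList(sim$network, paths["edges"])
  writeGmt(sim$reference, paths["reference"])
  writeDrugTargets(sim$drugTargets, paths["drugTargets"])
  writeLines(sim$truth$diseaseGenes, paths["truth"])
  if (!is.null(sim$expression)) {
    se <- sim$expression
    mat <- SummarizedExperiment::assay(se, 1)
    paths <- c(paths, expr = file.path(dir, "expr.tsv"),
               pheno = file.path(dir, "pheno.tsv"))
    utils::write.table(
      data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
      paths["expr"], sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = colnames(mat),
                 label = as.character(se$phenotype)),
      paths["pheno"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Planted-gene recovery benchmark
#'
#' For each replicate: simulate scores and a dependency network, propagate,
#' and measure how well the propagated ordering and the raw \eqn{-\log p}
#' ordering recover the planted disease genes (AUROC). Replicate r uses
#' \code{seeds[r]} as the simulation seed; everything else comes from
#' \code{baseConfig}.
#'
#' \code{transpose} defaults to \code{TRUE}: the attachment generator records
#' "new gene depends on chosen gene" as an edge new -> chosen (so the stated
#' out-degree-\code{mEdges} construction invariant holds), while the
#' propagation engine sends score from the depended-upon gene to its
#' dependents — the opposite orientation. Flipping at propagation time aligns
#' the flow with the planted homophilous structure; see the methods vignette.
#'
#' @param seeds Integer vector of simulation seeds (one per replicate).
#' @param baseConfig A [SimulationConfig]; its \code{seed} is replaced per
#'   replicate.
#' @param rankConfig A [RankConfig] for the propagation arm.
#' @param transpose Flip edge orientation at propagation time (default TRUE).
#' @return A data.frame with one row per replicate: \code{seed},
#'   \code{aucPropagated}, \code{aucRaw}.
#' @export
recoveryBenchmark <- function(seeds = 1:20, baseConfig = SimulationConfig(),
                              rankConfig = RankConfig(), transpose = TRUE) {
  stopifnot(is(baseConfig, "SimulationConfig"), is(rankConfig, "RankConfig"))
  rows <- lapply(seeds, function(s) {
    cfg <- baseConfig
    cfg@seed <- as.integer(s)
    truth <- simulateGeneScores(cfg)
    net <- simulateNetwork(truth, cfg)
    sc <- computeInitialScores(truth$scores, rankConfig)
    prop <- geneRank(net, sc, rankConfig, transpose = transpose)
    data.frame(seed = as.integer(s),
               aucPropagated = rankRecoveryAUC(rankScores(prop),
                                               truth$diseaseGenes),
               aucRaw = rankRecoveryAUC(initialScores(sc),
                                        truth$diseaseGenes))
  })
  do.call(rbind, rows)
}

#' Area under the ROC curve for recovering a planted gene set
#'
#' Rank-based (Mann-Whitney) AUROC of a score vector against a positive
#' label set: the probability that a random planted gene outscores a random
#' null gene, with ties counted half.
#'
#' @param scores Named numeric vector (higher = more disease-like).
#' @param positives Character vector of positive gene identifiers.
#' @return AUROC in [0, 1].
#' @export
rankRecoveryAUC <- function(scores, positives) {
  stopifnot(!is.null(names(scores)))
  lab <- names(scores) %in% positives
  nPos <- sum(lab); nNeg <- sum(!lab)
  if (nPos == 0 || nNeg == 0)
    stop("need at least one positive and one negative gene")
  r <- rank(scores)
  (sum(r[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
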