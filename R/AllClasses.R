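## Central S4 data containers. All vector slots are parallel and validated;
## accessors (AllGenerics.R / methods below) are the supported interface.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Gene-level association scores
#'
#' Holds per-gene association p-values (e.g. PheWAS-derived) together with the
#' derived initial propagation score \eqn{f = -\log_{b} p}. The \code{f} slot
#' is \code{NA} until filled by [computeInitialScores()].
#'
#' @slot geneId Character vector of unique, case-sensitive gene identifiers.
#' @slot pValue Numeric vector of p-values in (0, 1] (clamped on input).
#' @slot f Numeric vector of non-negative initial scores, or all-\code{NA}
#'   before scoring.
#'
#' @param geneId,pValue,f Slot values; see slot descriptions.
#' @return A \code{GeneScoreTable} object.
#' @examples
#' gs <- GeneScoreTable(c("BRCA2", "ESR1"), c(1e-4, 0.02))
#' pValues(gs)
#' @export GeneScoreTable
#' @exportClass GeneScoreTable
GeneScoreTable <- setClass("GeneScoreTable",
  slots = c(geneId = "character", pValue = "numeric", f = "numeric"))

setMethod("initialize", "GeneScoreTable",
  function(.Object, geneId = character(), pValue = numeric(),
           f = rep(NA_real_, length(geneId)), ...) {
    callNextMethod(.Object, geneId = as.character(geneId),
                   pValue = as.numeric(pValue), f = as.numeric(f), ...)
  })

setValidity("GeneScoreTable", function(object) {
  n <- length(object@geneId)
  if (length(object@pValue) != n || length(object@f) != n)
    return("geneId, pValue and f must have equal length")
  if (anyDuplicated(object@geneId))
    return("gene identifiers must be unique")
  if (n > 0 && (anyNA(object@pValue) ||
                any(object@pValue <= 0) || any(object@pValue > 1)))
    return("p-values must lie in (0, 1]")
  fdef <- !is.na(object@f)
  if (any(fdef) && !all(fdef))
    return("f must be all NA (unscored) or fully defined")
  if (any(fdef) && (any(!is.finite(object@f)) || any(object@f < 0)))
    return("initial scores f must be finite and non-negative")
  TRUE
})

#' Directed gene-dependency network
#'
#' A directed network over a fixed gene universe. An edge \eqn{i \to j}
#' (\eqn{w_{ij} = 1}) means gene \eqn{j}'s phenotype-relevant signal depends
#' on gene \eqn{i}; during propagation node \eqn{i} splits its score equally
#' among its out-neighbours. Self-loops and duplicate edges are removed at
#' construction (self-loops with a warning).
#'
#' @slot nodes Character vector of gene identifiers (the node universe).
#' @slot edgeMat Two-column integer matrix of (from, to) indices into
#'   \code{nodes}.
#'
#' @param from,to Character vectors of edge endpoints (parallel).
#' @param nodes Optional node universe; defaults to the identifiers seen in
#'   \code{from}/\code{to}, in order of first appearance. Isolated nodes are
#'   retained only when listed here.
#' @return A \code{DependencyNetwork} object.
#' @examples
#' net <- DependencyNetwork(from = c("A", "A", "B"), to = c("B", "C", "C"))
#' outDegree(net)
#' @export DependencyNetwork
#' @exportClass DependencyNetwork
DependencyNetwork <- setClass("DependencyNetwork",
  slots = c(nodes = "character", edgeMat = "matrix"))

setMethod("initialize", "DependencyNetwork",
  function(.Object, from = character(), to = character(), nodes = NULL, ...) {
    from <- as.character(from); to <- as.character(to)
    if (length(from) != length(to))
      stop("'from' and 'to' must have equal length")
    if (is.null(nodes)) nodes <- unique(c(rbind(from, to)))
    nodes <- as.character(nodes)
    fi <- match(from, nodes); ti <- match(to, nodes)
    if (anyNA(fi) || anyNA(ti))
      stop("edge endpoints must belong to the node universe")
    loop <- fi == ti
    if (any(loop)) {
      warning(sum(loop), " self-loop(s) dropped: propagation semantics is ",
              "ill-posed for self-dependency")
      fi <- fi[!loop]; ti <- ti[!loop]
    }
    key <- (fi - 1) * length(nodes) + ti
    keep <- !duplicated(key)
    em <- cbind(from = as.integer(fi[keep]), to = as.integer(ti[keep]))
    callNextMethod(.Object, nodes = nodes, edgeMat = em, ...)
  })

setValidity("DependencyNetwork", function(object) {
  em <- object@edgeMat
  n <- length(object@nodes)
  if (ncol(em) != 2) return("edgeMat must have two columns")
  if (anyDuplicated(object@nodes)) return("node identifiers must be unique")
  if (nrow(em) > 0) {
    if (!is.integer(em)) return("edgeMat must be integer")
    if (any(em < 1) || any(em > n)) return("edge index out of range")
    if (any(em[, 1] == em[, 2])) return("self-loops are not allowed")
    if (anyDuplicated((em[, 1] - 1) * n + em[, 2]))
      return("duplicate edges are not allowed")
  }
  TRUE
})

#' Ranked gene list
#'
#' The deterministic ordering of genes by propagation score: scores
#' non-increasing, ranks contiguous from 1, ties broken by gene identifier
#' (C-locale lexicographic, ascending). Usually produced by [rankGenes()].
#'
#' @slot rank Integer ranks 1..K.
#' @slot geneId Character gene identifiers.
#' @slot score Numeric scores, non-increasing with rank.
#'
#' @param rank,geneId,score Slot values.
#' @return A \code{RankedGeneList} object.
#' @export RankedGeneList
#' @exportClass RankedGeneList
RankedGeneList <- setClass("RankedGeneList",
  slots = c(rank = "integer", geneId = "character", score = "numeric"))

setValidity("RankedGeneList", function(object) {
  k <- length(object@rank)
  if (length(object@geneId) != k || length(object@score) != k)
    return("rank, geneId and score must have equal length")
  if (k == 0) return(TRUE)
  if (!identical(object@rank, seq_len(k)))
    return("ranks must be contiguous 1..K")
  if (anyDuplicated(object@geneId)) return("gene identifiers must be unique")
  if (any(!is.finite(object@score))) return("scores must be finite")
  if (any(diff(object@score) > 0)) return("scores must be non-increasing")
  TRUE
})

#' Named collection of gene sets
#'
#' @slot sets Named list; each element a character vector of gene identifiers
#'   (non-empty, unique within a set), names unique.
#'
#' @param sets Slot value.
#' @return A \code{GeneSetCollection} object.
#' @examples
#' GeneSetCollection(list(ref = c("BRCA2", "ESR1")))
#' @export GeneSetCollection
#' @exportClass GeneSetCollection
GeneSetCollection <- setClass("GeneSetCollection", slots = c(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  s <- object@sets
  if (length(s) == 0) return(TRUE)
  if (is.null(names(s)) || any(names(s) == "") || anyDuplicated(names(s)))
    return("set names must be present and unique")
  if (any(lengths(s) == 0)) return("gene sets must be non-empty")
  if (!all(vapply(s, is.character, logical(1))))
    return("gene sets must be character vectors")
  if (any(vapply(s, anyDuplicated, integer(1)) > 0))
    return("genes must be unique within a set")
  TRUE
})

#' Drug-target associations with clinical-support flags
#'
#' Unique (agent, target gene) pairs plus one logical clinical-support flag
#' per agent. When built from per-row flags the agent flag is the OR over its
#' rows.
#'
#' @slot agentId,targetId Parallel character vectors; pairs unique.
#' @slot support Named logical vector, one entry per distinct agent.
#'
#' @param agentId,targetId Parallel character vectors of associations.
#' @param supported Per-row logical (or 0/1) clinical-support flags; collapsed
#'   to one flag per agent by OR.
#' @return A \code{DrugTargetTable} object.
#' @examples
#' dt <- DrugTargetTable(c("tamoxifen", "tamoxifen"), c("ESR1", "ESR2"),
#'                       supported = c(TRUE, TRUE))
#' supportFlags(dt)
#' @export DrugTargetTable
#' @exportClass DrugTargetTable
DrugTargetTable <- setClass("DrugTargetTable",
  slots = c(agentId = "character", targetId = "character",
            support = "logical"))

setMethod("initialize", "DrugTargetTable",
  function(.Object, agentId = character(), targetId = character(),
           supported = logical(), support = NULL, ...) {
    agentId <- as.character(agentId); targetId <- as.character(targetId)
    if (is.null(support)) {
      if (length(supported) != length(agentId))
        stop("'supported' must be parallel to the association rows")
      supported <- as.logical(supported)
      if (anyNA(supported)) stop("support flags must be 0/1 or logical")
      support <- vapply(split(supported, agentId), any, logical(1))
    }
    key <- paste(agentId, targetId, sep = "\r")
    keep <- !duplicated(key)
    callNextMethod(.Object, agentId = agentId[keep], targetId = targetId[keep],
                   support = support, ...)
  })

setValidity("DrugTargetTable", function(object) {
  if (length(object@agentId) != length(object@targetId))
    return("agentId and targetId must have equal length")
  if (anyDuplicated(paste(object@agentId, object@targetId, sep = "\r")))
    return("(agent, target) pairs must be unique")
  ag <- unique(object@agentId)
  if (!all(ag %in% names(object@support)))
    return("every agent must carry a clinical-support flag")
  if (anyNA(object@support)) return("support flags must not be NA")
  TRUE
})

#' Propagation settings
#'
#' @slot d Network weight (damping) in [0, 1); \code{d = 0.5} balances the
#'   association evidence and the network contribution.
#' @slot epsilon Positive convergence threshold on the one-norm of successive
#'   score differences (default \code{1e-5}).
#' @slot maxIter Iteration cap (default 1000).
#' @slot logBase Base for the \eqn{-\log p} initial scores (default 10).
#' @slot pMin Lower clamp for p-values so \eqn{-\log p} stays finite
#'   (default \code{1e-300}).
#'
#' @param d,epsilon,maxIter,logBase,pMin Slot values.
#' @return A \code{RankConfig} object.
#' @examples
#' RankConfig(d = 0.5)
#' @export RankConfig
#' @exportClass RankConfig
RankConfig <- setClass("RankConfig",
  slots = c(d = "numeric", epsilon = "numeric", maxIter = "integer",
            logBase = "numeric", pMin = "numeric"),
  prototype = list(d = 0.5, epsilon = 1e-5, maxIter = 1000L,
                   logBase = 10, pMin = 1e-300))

setMethod("initialize", "RankConfig",
  function(.Object, ..., maxIter = 1000L) {
    callNextMethod(.Object, ..., maxIter = as.integer(maxIter))
  })

setValidity("RankConfig", function(object) {
  if (length(object@d) != 1 || object@d < 0 || object@d >= 1)
    return("d must be a single value in [0, 1)")
  if (object@epsilon <= 0) return("epsilon must be positive")
  if (object@maxIter < 1) return("maxIter must be at least 1")
  if (object@logBase <= 1) return("logBase must exceed 1")
  if (object@pMin <= 0 || object@pMin > 1) return("pMin must lie in (0, 1]")
  TRUE
})

#' Result of the propagation iteration
#'
#' @slot scores Named numeric vector of converged scores \eqn{r_j}.
#' @slot nIterations Number of update sweeps performed.
#' @slot residuals One-norm residual after each sweep (last entry is
#'   \code{finalResidual}).
#' @slot finalResidual One-norm of the last update difference.
#' @slot epsilon The threshold the iteration was run with.
#' @slot converged Whether \code{finalResidual < epsilon} within the cap.
#'
#' @export
#' @exportClass RankResult
RankResult <- setClass("RankResult",
  slots = c(scores = "numeric", nIterations = "integer",
            residuals = "numeric", finalResidual = "numeric",
            epsilon = "numeric", converged = "logical"))

setValidity("RankResult", function(object) {
  if (length(object@scores) > 0 && is.null(names(object@scores)))
    return("scores must be named by gene")
  if (object@converged && !(object@finalResidual < object@epsilon))
    return("converged result must have finalResidual < epsilon")
  TRUE
})

#' Synthetic-data generator settings
#'
#' Defaults describe the benchmark condition used throughout the package: a
#' 2000-gene universe with a 5\% planted disease subpopulation whose p-values
#' follow Beta(0.2, 1), a homophilous (factor 8) preferential-attachment
#' dependency network with 20 out-edges per node, and a 300-agent drug-target
#' table. See the methods vignette for the rationale behind each value.
#'
#' @slot nGenes Number of genes in the simulated universe.
#' @slot piDisease Fraction of planted disease genes, in (0, 1).
#' @slot betaA Beta(a, 1) shape for disease-gene p-values; smaller a means
#'   stronger association signal. Must satisfy 0 < a <= 1.
#' @slot mEdges Out-edges drawn per node during preferential attachment.
#' @slot homophily Multiplier (>= 1) on attachment weight when both endpoints
#'   are disease genes; 1 means no planted network structure.
#' @slot nAgents Number of simulated chemical agents.
#' @slot targetsPerAgent Distinct targets drawn per agent.
#' @slot piSupported Fraction of agents flagged as clinically supported.
#' @slot supportEnrichment Sampling weight (>= 1) on disease genes when a
#'   supported agent draws its targets.
#' @slot dbSensitivity Probability a planted disease gene enters the simulated
#'   reference database.
#' @slot dbFpr Probability a null gene enters the reference database.
#' @slot seed Integer seed; every generator is a pure function of
#'   (config, seed).
#'
#' @param nGenes,piDisease,betaA,mEdges,homophily,nAgents,targetsPerAgent,piSupported,supportEnrichment,dbSensitivity,dbFpr,seed
#'   Slot values.
#' @return A \code{SimulationConfig} object.
#' @examples
#' SimulationConfig(nGenes = 200, seed = 7)
#' @export SimulationConfig
#' @exportClass SimulationConfig
SimulationConfig <- setClass("SimulationConfig",
  slots = c(nGenes = "integer", piDisease = "numeric", betaA = "numeric",
            mEdges = "integer", homophily = "numeric", nAgents = "integer",
            targetsPerAgent = "integer", piSupported = "numeric",
            supportEnrichment = "numeric", dbSensitivity = "numeric",
            dbFpr = "numeric", seed = "integer"),
  prototype = list(nGenes = 2000L, piDisease = 0.05, betaA = 0.2,
                   mEdges = 20L, homophily = 8, nAgents = 300L,
                   targetsPerAgent = 3L, piSupported = 0.2,
                   supportEnrichment = 8, dbSensitivity = 0.8, dbFpr = 0.05,
                   seed = 1L))

setMethod("initialize", "SimulationConfig",
  function(.Object, ..., nGenes = 2000L, mEdges = 20L, nAgents = 300L,
           targetsPerAgent = 3L, seed = 1L) {
    callNextMethod(.Object, ..., nGenes = as.integer(nGenes),
                   mEdges = as.integer(mEdges), nAgents = as.integer(nAgents),
                   targetsPerAgent = as.integer(targetsPerAgent),
                   seed = as.integer(seed))
  })

setValidity("SimulationConfig", function(object) {
  if (object@nGenes < 2) return("nGenes must be at least 2")
  if (object@piDisease <= 0 || object@piDisease >= 1)
    return("piDisease must lie in (0, 1)")
  if (object@betaA <= 0 || object@betaA > 1)
    return("betaA must lie in (0, 1]")
  if (object@mEdges < 1 || object@mEdges >= object@nGenes)
    return("mEdges must be in [1, nGenes)")
  if (object@homophily < 1) return("homophily must be >= 1")
  if (object@nAgents < 1) return("nAgents must be positive")
  if (object@targetsPerAgent < 1 || object@targetsPerAgent > object@nGenes)
    return("targetsPerAgent must be in [1, nGenes]")
  if (object@piSupported < 0 || object@piSupported > 1)
    return("piSupported must lie in [0, 1]")
  if (object@supportEnrichment < 1) return("supportEnrichment must be >= 1")
  if (object@dbSensitivity < 0 || object@dbSensitivity > 1 ||
      object@dbFpr < 0 || object@dbFpr > 1)
    return("dbSensitivity and dbFpr must be probabilities")
  TRUE
})
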