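#' @include AllClasses.R AllGenerics.R
NULL

## ---- GeneScoreTable ----

#' @rdname accessors
#' @aliases geneIds,GeneScoreTable-method
#' @export
setMethod("geneIds", "GeneScoreTable", function(x, ...) x@geneId)

#' @rdname accessors
#' @export
setMethod("pValues", "GeneScoreTable", function(x, ...) {
  stats::setNames(x@pValue, x@geneId)
})

#' @rdname accessors
#' @export
setMethod("initialScores", "GeneScoreTable", function(x, ...) {
  stats::setNames(x@f, x@geneId)
})

setMethod("length", "GeneScoreTable", function(x) length(x@geneId))

setMethod("show", "GeneScoreTable", function(object) {
  cat("GeneScoreTable with", length(object@geneId), "genes\n")
  if (length(object@geneId)) {
    scored <- !anyNA(object@f)
    cat("  p-value range: [", format(min(object@pValue), digits = 3), ", ",
        format(max(object@pValue), digits = 3), "]\n", sep = "")
    cat("  initial scores f:", if (scored) "computed" else "not yet computed",
        "\n")
  }
})

#' @export
#' @method as.data.frame GeneScoreTable
as.data.frame.GeneScoreTable <- function(x, ...) {
  data.frame(gene_id = x@geneId, p_value = x@pValue, f = x@f,
             stringsAsFactors = FALSE)
}

## ---- DependencyNetwork ----

#' @rdname accessors
#' @export
setMethod("nodes", "DependencyNetwork", function(x, ...) x@nodes)

#' @rdname accessors
#' @export
setMethod("edgeCount", "DependencyNetwork", function(x, ...) nrow(x@edgeMat))

#' @rdname accessors
#' @export
setMethod("edgeTable", "DependencyNetwork", function(x, ...) {
  data.frame(from = x@nodes[x@edgeMat[, 1]], to = x@nodes[x@edgeMat[, 2]],
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("outDegree", "DependencyNetwork", function(x, ...) {
  stats::setNames(tabulate(x@edgeMat[, 1], nbins = length(x@nodes)), x@nodes)
})

#' Sparse adjacency matrix of a dependency network
#'
#' @param x A [DependencyNetwork].
#' @param ... Unused.
#' @return A sparse 0/1 \code{dgCMatrix} W with \code{W[i, j] = 1} for every
#'   edge i -> j, dimnames set to the node identifiers.
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "DependencyNetwork", function(x, ...) {
  n <- length(x@nodes)
  Matrix::sparseMatrix(i = x@edgeMat[, 1], j = x@edgeMat[, 2], x = 1,
                       dims = c(n, n), dimnames = list(x@nodes, x@nodes))
})

setMethod("show", "DependencyNetwork", function(object) {
  cat("DependencyNetwork:", length(object@nodes), "nodes,",
      nrow(object@edgeMat), "directed edges\n")
  if (nrow(object@edgeMat)) {
    dg <- tabulate(object@edgeMat[, 1], nbins = length(object@nodes))
    cat("  out-degree: median", stats::median(dg), "max", max(dg),
        sprintf("(%d dangling)\n", sum(dg == 0)))
  }
})

## ---- RankedGeneList ----

#' @rdname accessors
#' @export
setMethod("geneIds", "RankedGeneList", function(x, ...) x@geneId)

#' @rdname accessors
#' @export
setMethod("rankScores", "RankedGeneList", function(x, ...) {
  stats::setNames(x@score, x@geneId)
})

setMethod("length", "RankedGeneList", function(x) length(x@rank))

setMethod("show", "RankedGeneList", function(object) {
  k <- length(object@rank)
  cat("RankedGeneList with", k, "genes\n")
  if (k) {
    top <- utils::head(data.frame(rank = object@rank, gene = object@geneId,
                                  score = signif(object@score, 4)), 5)
    print(top, row.names = FALSE)
    if (k > 5) cat("  ...", k - 5, "more\n")
  }
})

#' @export
#' @method as.data.frame RankedGeneList
as.data.frame.RankedGeneList <- function(x, ...) {
  data.frame(rank = x@rank, gene_id = x@geneId, score = x@score,
             stringsAsFactors = FALSE)
}

## ---- GeneSetCollection ----

#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x, ...) x@sets)

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("names", "GeneSetCollection", function(x) names(x@sets))

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  if (length(object@sets))
    cat("  sizes:", paste(utils::head(lengths(object@sets), 5),
                          collapse = ", "),
        if (length(object@sets) > 5) "..." else "", "\n")
})

setMethod("[[", "GeneSetCollection", function(x, i) x@sets[[i]])

## ---- DrugTargetTable ----

#' @rdname accessors
#' @export
setMethod("agents", "DrugTargetTable", function(x, ...) {
  sort(unique(x@agentId), method = "radix")
})

#' @rdname accessors
#' @export
setMethod("supportFlags", "DrugTargetTable", function(x, ...) x@support)

setMethod("show", "DrugTargetTable", function(object) {
  cat("DrugTargetTable:", length(unique(object@agentId)), "agents,",
      length(object@agentId), "agent-target pairs;",
      sum(object@support), "agents clinically supported\n")
})

#' @export
#' @method as.data.frame DrugTargetTable
as.data.frame.DrugTargetTable <- function(x, ...) {
  data.frame(agent_id = x@agentId, target_gene_id = x@targetId,
             supported = as.integer(x@support[x@agentId]),
             stringsAsFactors = FALSE, row.names = NULL)
}

## ---- RankResult ----

#' @rdname accessors
#' @export
setMethod("rankScores", "RankResult", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setMethod("converged", "RankResult", function(x, ...) x@converged)

setMethod("show", "RankResult", function(object) {
  cat("RankResult:", length(object@scores), "genes;",
      object@nIterations, "iterations; final one-norm residual",
      format(object@finalResidual, digits = 3),
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
})

setMethod("show", "RankConfig", function(object) {
  cat(sprintf(
    "RankConfig: d = %g, epsilon = %g, maxIter = %d, logBase = %g, pMin = %g\n",
    object@d, object@epsilon, object@maxIter, object@logBase, object@pMin))
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:\n")
  for (s in slotNames(object))
    cat(sprintf("  %s = %g\n", s, slot(object, s)))
})
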