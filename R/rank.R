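## Damped propagation of -log p association scores over a directed
## dependency network (a directed GeneRank / personalized-PageRank variant).
##
## Update: r_j <- (1 - d) f_j + d * sum_i w_ij r_i / deg_i, with deg_i the
## out-degree of node i (each node splits its score equally among its
## out-neighbours; dangling nodes contribute nothing). For 0 <= d < 1 the map
## is a contraction in the one-norm, so the fixed point is unique and the
## iteration converges from any start; we start at r = f.

#' Fill the initial scores f = -log(p)
#'
#' Sets the initial propagation score of every gene to the negative logarithm
#' of its association p-value, after clamping p into \code{[pMin, 1]}.
#'
#' @param x A [GeneScoreTable].
#' @param config A [RankConfig] supplying \code{logBase} and \code{pMin}.
#' @return The table with the \code{f} slot filled (all values >= 0).
#' @examples
#' gs <- GeneScoreTable(c("A", "B"), c(0.01, 1))
#' initialScores(computeInitialScores(gs))  # 2, 0
#' @export
computeInitialScores <- function(x, config = RankConfig()) {
  stopifnot(is(x, "GeneScoreTable"), is(config, "RankConfig"))
  p <- pmin(pmax(x@pValue, config@pMin), 1)
  x@f <- pmax(-log(p, base = config@logBase), 0)  # guard -0 at p = 1
  validObject(x)
  x
}

.rowNormalized <- function(W) {
  deg <- Matrix::rowSums(W)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  Matrix::Diagonal(x = inv) %*% W
}

## Restrict network + scores to the analysis universe.
.rankUniverse <- function(net, scores, config, keepUnscored) {
  stopifnot(is(net, "DependencyNetwork"), is(scores, "GeneScoreTable"))
  if (anyNA(scores@f)) scores <- computeInitialScores(scores, config)
  f <- initialScores(scores)
  universe <- if (keepUnscored) nodes(net) else
    intersect(nodes(net), names(f))
  if (length(universe) == 0)
    stop("no genes shared between the score table and the network")
  fv <- stats::setNames(rep(0, length(universe)), universe)
  hit <- intersect(universe, names(f))
  fv[hit] <- f[hit]
  idx <- match(universe, nodes(net))
  em <- net@edgeMat
  keep <- em[, 1] %in% idx & em[, 2] %in% idx
  W <- Matrix::sparseMatrix(i = match(em[keep, 1], idx),
                            j = match(em[keep, 2], idx),
                            x = 1, dims = c(length(universe), length(universe)),
                            dimnames = list(universe, universe))
  list(W = W, f = fv)
}

#' Propagate association scores over a directed dependency network
#'
#' Runs the damped fixed-point iteration
#' \deqn{r_j^{(n)} = (1 - d)\,f_j + d \sum_i \frac{w_{ij}}{\mathrm{deg}_i}
#'   r_i^{(n-1)}}{r_j = (1-d) f_j + d * sum_i w_ij r_i / deg_i}
#' starting from \eqn{r^{(0)} = f}, stopping when the one-norm of the update
#' difference drops below \code{config@epsilon} or after
#' \code{config@maxIter} sweeps. With \code{d = 0} the scores equal \code{f};
#' dangling nodes (out-degree 0) propagate nothing.
#'
#' By default the analysis universe is the intersection of the scored genes
#' and the network nodes, and the network is restricted to it;
#' \code{keepUnscored = TRUE} instead keeps every network node, assigning
#' \code{f = 0} to unscored ones. \code{transpose = TRUE} flips every edge
#' before propagation, for networks whose files use the opposite orientation
#' convention.
#'
#' @param net A [DependencyNetwork].
#' @param scores A [GeneScoreTable]; if its \code{f} slot is unset it is
#'   filled via [computeInitialScores()] with \code{config}.
#' @param config A [RankConfig] (defaults: \code{d = 0.5},
#'   \code{epsilon = 1e-5}, \code{maxIter = 1000}).
#' @param keepUnscored Keep unscored network nodes with \code{f = 0}?
#' @param transpose Flip the edge orientation before propagating?
#' @return A [RankResult].
#' @examples
#' net <- DependencyNetwork(from = c("A", "A", "B"), to = c("B", "C", "C"))
#' gs <- GeneScoreTable(c("A", "B", "C"), c(0.1, 0.5, 0.75))
#' geneRank(net, gs, RankConfig(d = 0.5))
#' @seealso [geneRankClosedForm()] for the exact fixed point,
#'   [rankGenes()] to order the result.
#' @export
geneRank <- function(net, scores, config = RankConfig(),
                     keepUnscored = FALSE, transpose = FALSE) {
  stopifnot(is(config, "RankConfig"))
  u <- .rankUniverse(net, scores, config, keepUnscored)
  W <- if (transpose) Matrix::t(u$W) else u$W
  f <- u$f
  d <- config@d
  Pt <- Matrix::t(.rowNormalized(W))
  r <- f
  residuals <- numeric(0)
  converged <- FALSE
  for (it in seq_len(config@maxIter)) {
    rn <- (1 - d) * f + d * as.numeric(Pt %*% r)
    res <- sum(abs(rn - r))
    residuals <- c(residuals, res)
    r <- rn
    if (res < config@epsilon) { converged <- TRUE; break }
  }
  if (!converged)
    warning("propagation did not converge within maxIter; ",
            "this cannot happen for d < 1 and indicates a defect")
  RankResult(scores = stats::setNames(as.numeric(r), names(f)),
             nIterations = it, residuals = residuals,
             finalResidual = residuals[length(residuals)],
             epsilon = config@epsilon, converged = converged)
}

#' Exact fixed point of the propagation (linear solve)
#'
#' Solves \eqn{(I - d P^\top) r = (1 - d) f} directly, where \eqn{P} is the
#' out-degree-normalized adjacency matrix (rows of dangling nodes all zero).
#' The spectral radius of \eqn{d P^\top} is below 1 for \eqn{d < 1}, so the
#' solution exists and is unique. Primarily a cross-check for [geneRank()].
#'
#' @param net A [DependencyNetwork].
#' @param f Named numeric vector of initial scores covering every node.
#' @param d Damping weight in [0, 1).
#' @param transpose Flip the edge orientation first?
#' @return Named numeric vector of exact scores, in node order.
#' @export
geneRankClosedForm <- function(net, f, d, transpose = FALSE) {
  stopifnot(is(net, "DependencyNetwork"), d >= 0, d < 1)
  nd <- nodes(net)
  if (is.null(names(f)) || !all(nd %in% names(f)))
    stop("'f' must be named and cover every network node")
  f <- f[nd]
  W <- adjacencyMatrix(net)
  if (transpose) W <- Matrix::t(W)
  P <- .rowNormalized(W)
  A <- Matrix::Diagonal(length(nd)) - d * Matrix::t(P)
  r <- Matrix::solve(A, (1 - d) * f)
  stats::setNames(as.numeric(r), nd)
}

#' Order genes by propagation score
#'
#' Sorts genes by score, descending; ties are broken by gene identifier in
#' ascending C-locale (radix) order so output files are reproducible across
#' platforms and locales.
#'
#' @param x A [RankResult] or a named numeric vector of scores.
#' @return A [RankedGeneList]; empty input yields an empty list.
#' @export
rankGenes <- function(x) {
  s <- if (is(x, "RankResult")) rankScores(x) else x
  if (length(s) == 0) return(RankedGeneList())
  stopifnot(!is.null(names(s)), all(is.finite(s)))
  ord <- order(-s, names(s), method = "radix")
  RankedGeneList(rank = seq_along(s), geneId = names(s)[ord],
                 score = as.numeric(s[ord]))
}

#' Select the top-k genes of a ranking
#'
#' @param ranked A [RankedGeneList].
#' @param k Positive integer; if the list is shorter than \code{k}, all genes
#'   are returned.
#' @return Character vector of the first \code{min(k, K)} gene identifiers.
#' @export
topGenes <- function(ranked, k) {
  stopifnot(is(ranked, "RankedGeneList"))
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 1)
    stop("'k' must be a positive integer")
  utils::head(ranked@geneId, k)
}
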