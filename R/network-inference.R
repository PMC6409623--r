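## Optional construction of the directed gene-dependency network from an
## expression matrix and a binary prognosis phenotype.
##
## Semantics: an edge i -> j is drawn when (1) gene j carries significant
## information about the phenotype (permutation test on the plug-in mutual
## information), and (2) conditioning on gene i removes at least a fraction
## tau of that information: [MI(X_j; y) - CMI(X_j; y | X_i)] / MI(X_j; y)
## >= tau. That is, gene j's phenotype signal depends on gene i.

#' Equal-frequency discretization
#'
#' Assigns each value to one of \code{nBins} equal-frequency bins labelled
#' \code{0..nBins-1}. Ties share the bin of their lowest rank (the lower
#' bin). When the vector has fewer distinct values than bins, the output
#' collapses to the distinct-value count with a warning.
#'
#' @param x Numeric vector.
#' @param nBins Number of bins, at least 2.
#' @return Integer vector of bin labels, relabelled to be consecutive from 0.
#' @examples
#' discretizeEqualFreq(1:6, 3)      # 0 0 1 1 2 2
#' discretizeEqualFreq(c(1, 1, 2, 2), 2)  # 0 0 1 1
#' @export
discretizeEqualFreq <- function(x, nBins) {
  stopifnot(is.numeric(x), length(x) > 0, nBins >= 2)
  if (length(unique(x)) < nBins)
    warning("fewer distinct values (", length(unique(x)), ") than bins (",
            nBins, "); bins collapsed")
  r <- rank(x, ties.method = "min")
  b <- as.integer(floor((r - 1) * nBins / length(x)))
  match(b, sort(unique(b))) - 1L
}

## MI from 0-based (or any small-integer) codes, in nats, via tabulate().
.miCodes <- function(a, b) {
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  na <- max(a); nb <- max(b); n <- length(a)
  joint <- tabulate((b - 1L) * na + a, nbins = na * nb)
  pj <- joint[joint > 0] / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  pr <- as.numeric(outer(pa, pb))[joint > 0]
  max(0, sum(pj * log(pj / pr)))
}

#' Plug-in mutual information of two discrete vectors
#'
#' Maximum-likelihood (plug-in) estimate
#' \eqn{\sum_{a,b} \hat p(a,b) \ln \frac{\hat p(a,b)}{\hat p(a)\hat p(b)}}
#' in nats; always non-negative.
#'
#' @param a,b Discrete vectors (integer codes or factors) of equal length.
#' @return Mutual information estimate in nats.
#' @examples
#' mutualInformation(c(0, 0, 1, 1), c(0, 0, 1, 1))  # log(2)
#' @export
mutualInformation <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length")
  .miCodes(a, b)
}

#' Plug-in conditional mutual information I(a; b | c)
#'
#' Computed as \eqn{\sum_c \hat p(c)\, \hat I(a; b \mid C = c)}, each stratum
#' using the plug-in estimator of [mutualInformation()]. Equals
#' \code{mutualInformation(a, b)} when \code{c} is constant, and 0 when
#' \code{a == c}.
#'
#' @param a,b,c Discrete vectors of equal length.
#' @return Conditional mutual information estimate in nats (non-negative).
#' @export
conditionalMutualInformation <- function(a, b, c) {
  n <- length(a)
  if (length(b) != n || length(c) != n)
    stop("'a', 'b' and 'c' must have equal length")
  ci <- as.integer(factor(c))
  total <- 0
  for (lev in unique(ci)) {
    idx <- ci == lev
    total <- total + sum(idx) / n * .miCodes(a[idx], b[idx])
  }
  max(0, total)
}

#' Permutation test of phenotype mutual information
#'
#' Permutation p-values for MI(gene; phenotype) per gene, permuting phenotype
#' labels only (the expression correlation structure is preserved under the
#' null). The same \code{nPerm} label shuffles are reused for every gene.
#' p = (1 + #\{perm MI >= observed\}) / (nPerm + 1).
#'
#' @param disc Integer matrix of discretized expression (genes x samples).
#' @param y Integer phenotype codes (length = samples).
#' @param nPerm Number of permutations.
#' @param seed Integer seed for the shuffles.
#' @return List with \code{mi} (observed MI per gene) and \code{p}
#'   (permutation p-values), both named by gene.
#' @export
miPermutationTest <- function(disc, y, nPerm = 1000, seed = 1L) {
  stopifnot(is.matrix(disc), ncol(disc) == length(y), nPerm >= 1)
  g <- nrow(disc)
  obs <- vapply(seq_len(g), function(j) .miCodes(disc[j, ], y), numeric(1))
  perms <- withr::with_seed(seed, {
    replicate(nPerm, sample.int(length(y)), simplify = FALSE)
  })
  exceed <- integer(g)
  for (pm in perms) {
    yp <- y[pm]
    for (j in seq_len(g))
      if (.miCodes(disc[j, ], yp) >= obs[j]) exceed[j] <- exceed[j] + 1L
  }
  list(mi = stats::setNames(obs, rownames(disc)),
       p = stats::setNames((1 + exceed) / (nPerm + 1), rownames(disc)))
}

.phenoFactor <- function(pheno) {
  y <- factor(pheno)
  if (nlevels(y) != 2)
    stop("phenotype must have exactly two classes (degenerate phenotype)")
  y
}

#' Build a directed gene-dependency network from expression + phenotype
#'
#' For every ordered gene pair (i, j), i != j, the edge i -> j is added when
#' (1) gene j's expression carries phenotype information that is significant
#' at level \code{alpha} under \code{nPerm} phenotype-label permutations, and
#' (2) conditioning on gene i removes at least a fraction \code{tau} of that
#' information (relative drop of MI to conditional MI). Expression values are
#' discretized by equal-frequency binning first; rows with fewer than two
#' distinct values are dropped with a warning.
#'
#' The two-condition rule is this package's concretization of
#' phenotype-anchored dependency; see the methods vignette for its rationale
#' and limitations (notably: no multiplicity control across the O(N^2)
#' pair tests).
#'
#' @param expr Numeric matrix (genes x samples) with rownames, or a
#'   \code{SummarizedExperiment} whose first assay holds expression.
#' @param pheno Binary phenotype: factor/vector of length \code{ncol(expr)}.
#'   For a \code{SummarizedExperiment}, defaults to
#'   \code{colData(expr)[[phenoCol]]}.
#' @param phenoCol Name of the colData column holding the phenotype.
#' @param nBins Equal-frequency bins for expression (default 3).
#' @param alpha Permutation significance level for the marginal MI
#'   (default 0.05).
#' @param tau Minimum relative MI drop in (0, 1] (default 0.5).
#' @param nPerm Number of label permutations (default 1000).
#' @param seed Seed for the permutation shuffles.
#' @return A [DependencyNetwork] over the retained genes.
#' @export
buildDependencyNetwork <- function(expr, pheno = NULL, phenoCol = "phenotype",
                                   nBins = 3, alpha = 0.05, tau = 0.5,
                                   nPerm = 1000, seed = 1L) {
  if (is(expr, "SummarizedExperiment")) {
    if (is.null(pheno))
      pheno <- SummarizedExperiment::colData(expr)[[phenoCol]]
    expr <- SummarizedExperiment::assay(expr, 1)
  }
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (is.null(pheno)) stop("'pheno' is required for matrix input")
  stopifnot(tau > 0, tau <= 1, alpha > 0, alpha < 1)
  y <- .phenoFactor(pheno)
  if (length(y) != ncol(expr))
    stop("phenotype length must equal the number of samples")
  if (min(table(y)) < 8)
    stop("underpowered: need at least 8 samples per phenotype class")
  distinct <- apply(expr, 1, function(v) length(unique(v)))
  if (any(distinct < 2)) {
    warning(sum(distinct < 2), " constant gene row(s) dropped")
    expr <- expr[distinct >= 2, , drop = FALSE]
  }
  genes <- rownames(expr)
  disc <- t(apply(expr, 1, function(v)
    suppressWarnings(discretizeEqualFreq(v, nBins))))
  yi <- as.integer(y)
  pt <- miPermutationTest(disc, yi, nPerm = nPerm, seed = seed)
  sig <- which(pt$p < alpha)
  from <- integer(0); to <- integer(0)
  for (j in sig) {
    mij <- pt$mi[j]
    if (mij <= 0) next
    for (i in seq_along(genes)) {
      if (i == j) next
      cmi <- conditionalMutualInformation(disc[j, ], yi, disc[i, ])
      if ((mij - cmi) / mij >= tau) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  DependencyNetwork(from = genes[from], to = genes[to], nodes = genes)
}
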