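## Validation statistics for a prioritized gene list: 2x2 chi-squared
## enrichment, overlap fractions, one-sided top-of-list KS enrichment of drug
## targets, and hypergeometric over-representation with BH correction.

.as2x2 <- function(x) {
  if (is.matrix(x)) {
    stopifnot(identical(dim(x), c(2L, 2L)))
    return(x)
  }
  stopifnot(is.numeric(x), length(x) == 4)
  matrix(x, nrow = 2, byrow = TRUE)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Uncorrected (no Yates continuity correction) Pearson test with 1 degree of
#' freedom: statistic \eqn{N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))}, two-sided
#' p-value from the chi-squared survival function. Rows are the compared
#' strategies, columns in-reference / not-in-reference (or
#' supported / unsupported).
#'
#' @param x A 2x2 numeric matrix of counts, or a length-4 vector
#'   \code{c(a, b, c, d)} filled row-wise.
#' @return A list with \code{statistic}, \code{p.value}, \code{df} (= 1) and
#'   the \code{table}.
#' @examples
#' chiSquare2x2(c(44, 183, 164, 1351))$p.value  # ~2.1e-4
#' @export
chiSquare2x2 <- function(x) {
  tab <- .as2x2(x)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) <= 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-squared test undefined: a marginal total is zero")
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ht$statistic), p.value = ht$p.value, df = 1L,
       table = tab)
}

#' Overlap of a gene list with a reference set
#'
#' @param genes Character vector (non-empty) of query genes.
#' @param reference Character vector of reference genes.
#' @return List with \code{count} (\code{|genes intersect reference|}) and
#'   \code{percent} (share of \code{genes}, in percent, rounded to 2
#'   decimals).
#' @examples
#' overlapStats(c("A", "B", "C"), c("B", "C", "D"))  # 2, 66.67
#' @export
overlapStats <- function(genes, reference) {
  if (length(genes) == 0) stop("'genes' must be non-empty")
  genes <- unique(genes)
  count <- length(intersect(genes, reference))
  list(count = count, percent = round(100 * count / length(genes), 2))
}

#' Top-of-list enrichment of target genes (two-sample KS on ranks)
#'
#' Tests whether a set of target genes sits nearer the top of a ranked gene
#' list than the remaining genes. The statistic is
#' \eqn{D = \sup_k [F_{\mathrm{targets}}(k) - F_{\mathrm{background}}(k)]}
#' over rank cutoffs \eqn{k}; under \code{alternative = "top"} the p-value is
#' the asymptotic one-sided bound \eqn{\exp(-2 D^2 nm/(n+m))}. D depends on
#' the ordering only, so it is invariant under any strictly monotone
#' transform of the scores. \code{alternative = "two.sided"} delegates to
#' \code{stats::ks.test} on the rank positions.
#'
#' @param ranked A [RankedGeneList].
#' @param targets Character vector of target gene identifiers.
#' @param alternative \code{"top"} (targets enriched at the top; default) or
#'   \code{"two.sided"}.
#' @return List with \code{D}, \code{p.value}, \code{nTargets},
#'   \code{nBackground} and \code{alternative}.
#' @export
ksTopEnrichment <- function(ranked, targets,
                            alternative = c("top", "two.sided")) {
  stopifnot(is(ranked, "RankedGeneList"))
  alternative <- match.arg(alternative)
  inT <- ranked@geneId %in% targets
  m <- sum(inT); nb <- sum(!inT)
  if (m == 0) stop("none of the target genes appear in the ranked list")
  if (nb == 0) stop("no background genes: every ranked gene is a target")
  Ft <- cumsum(inT) / m
  Fb <- cumsum(!inT) / nb
  if (alternative == "top") {
    D <- max(Ft - Fb)
    p <- min(1, exp(-2 * D^2 * m * nb / (m + nb)))
  } else {
    D <- max(abs(Ft - Fb))
    p <- stats::ks.test(which(inT), which(!inT), exact = FALSE)$p.value
  }
  list(D = D, p.value = p, nTargets = m, nBackground = nb,
       alternative = alternative)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to
#' \code{stats::p.adjust(method = "BH")}) after validating the input range.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set (intersected with the universe first), the upper-tail
#' hypergeometric p-value of the overlap with the query, BH-adjusted across
#' the collection.
#'
#' @param query Character vector of query genes, a subset of \code{universe}.
#' @param universe Character vector; the analysis universe (for rank-based
#'   workflows, typically all genes in the ranked list).
#' @param collections A [GeneSetCollection].
#' @param cutoff Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @return A data.frame with one row per set: \code{set_name},
#'   \code{overlap}, \code{set_size}, \code{universe_size},
#'   \code{query_size}, \code{p_raw}, \code{p_adjust}, \code{significant};
#'   ordered by \code{p_raw}.
#' @export
overRepresentation <- function(query, universe, collections, cutoff = 0.05) {
  stopifnot(is(collections, "GeneSetCollection"))
  query <- unique(query); universe <- unique(universe)
  if (!all(query %in% universe))
    stop("'query' must be a subset of 'universe'")
  N <- length(universe); q <- length(query)
  sets <- geneSets(collections)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- if (length(s) == 0) 1 else
      stats::phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               universe_size = N, query_size = q, p_raw = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust <- bhAdjust(out$p_raw)
  out$significant <- out$p_adjust < cutoff
  out[order(out$p_raw, out$set_name, method = "radix"), , drop = FALSE]
}
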