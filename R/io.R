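## Readers/writers for the plain-text formats the pipeline touches.
## Dialect: UTF-8, tab-separated, '#'-prefixed comment lines ignored, optional
## single header row auto-detected by a non-numeric value field. Parsing is
## line-oriented so errors can name the offending physical line.

.readDataLines <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(text = lines[keep], lineno = which(keep))
}

.splitFields <- function(x) strsplit(x, "\t", fixed = TRUE)

.isNumericToken <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}

.parseStop <- function(path, lineno, why) {
  stop(sprintf("%s: line %d: %s", basename(path), lineno, why), call. = FALSE)
}

#' Read gene association scores from a TSV file
#'
#' Expects two tab-separated columns (gene identifier, p-value), with optional
#' \code{#} comment lines and an optional header row (auto-detected by a
#' non-numeric second field). p-values of exactly 0 are clamped up to
#' \code{pMin} so that \eqn{-\log p} stays finite; negative values or values
#' above 1 are rejected.
#'
#' @param path Path to the TSV file.
#' @param pMin Lower clamp applied to p-values (default \code{1e-300}).
#' @return A [GeneScoreTable] (initial scores not yet computed).
#' @seealso [computeInitialScores()], [writeGeneScores()]
#' @export
readGeneScores <- function(path, pMin = 1e-300) {
  stopifnot(pMin > 0, pMin <= 1)
  dl <- .readDataLines(path)
  if (length(dl$text) == 0)
    stop(sprintf("%s: no data rows", basename(path)), call. = FALSE)
  fields <- .splitFields(dl$text)
  first <- 1L
  if (length(fields[[1]]) >= 2 && !.isNumericToken(fields[[1]][2]))
    first <- 2L                       # header row
  if (first > length(fields))
    stop(sprintf("%s: no data rows", basename(path)), call. = FALSE)
  ids <- character(0); ps <- numeric(0)
  for (k in seq(from = first, length.out = length(fields) - first + 1L)) {
    f <- fields[[k]]
    if (length(f) != 2)
      .parseStop(path, dl$lineno[k],
                 sprintf("expected 2 tab-separated fields, got %d", length(f)))
    p <- suppressWarnings(as.numeric(f[2]))
    if (is.na(p))
      .parseStop(path, dl$lineno[k], sprintf("p-value '%s' is not numeric", f[2]))
    if (p < 0 || p > 1)
      .parseStop(path, dl$lineno[k],
                 sprintf("p-value %g outside [0, 1]", p))
    ids <- c(ids, f[1]); ps <- c(ps, p)
  }
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("%s: duplicate gene identifier(s): %s", basename(path),
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  GeneScoreTable(geneId = ids, pValue = pmax(ps, pMin))
}

#' Write gene association scores to TSV
#'
#' @param x A [GeneScoreTable].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneScores <- function(x, path) {
  stopifnot(is(x, "GeneScoreTable"))
  con <- file(path, "w", encoding = "UTF-8"); on.exit(close(con))
  writeLines(c("gene_id\tp_value",
               sprintf("%s\t%.17g", x@geneId, x@pValue)), con)
  invisible(path)
}

#' Read a directed edge list from TSV
#'
#' Two tab-separated columns (source, target). Duplicate edges are collapsed
#' and self-loops are dropped with a warning; out-degrees are derived from the
#' remaining edge set.
#'
#' @param path Path to the edge-list file.
#' @param nodes Optional node universe (to retain isolated nodes).
#' @return A [DependencyNetwork].
#' @export
readEdgeList <- function(path, nodes = NULL) {
  dl <- .readDataLines(path)
  if (length(dl$text) == 0)
    stop(sprintf("%s: no edges found", basename(path)), call. = FALSE)
  fields <- .splitFields(dl$text)
  bad <- which(lengths(fields) != 2)
  if (length(bad))
    .parseStop(path, dl$lineno[bad[1]],
               sprintf("expected 2 tab-separated fields, got %d",
                       length(fields[[bad[1]]])))
  from <- vapply(fields, `[`, character(1), 1)
  to <- vapply(fields, `[`, character(1), 2)
  if (identical(tolower(from[1]), "source") ||
      identical(tolower(from[1]), "from")) {       # header row
    from <- from[-1]; to <- to[-1]
    if (length(from) == 0)
      stop(sprintf("%s: no edges found", basename(path)), call. = FALSE)
  }
  DependencyNetwork(from = from, to = to, nodes = nodes)
}

#' Write a dependency network as a TSV edge list
#'
#' @param x A [DependencyNetwork].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeEdgeList <- function(x, path) {
  stopifnot(is(x, "DependencyNetwork"))
  et <- edgeTable(x)
  con <- file(path, "w", encoding = "UTF-8"); on.exit(close(con))
  writeLines(c("source\ttarget", sprintf("%s\t%s", et$from, et$to)), con)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: per line a set name, a description, then the member genes,
#' all tab-separated. Sets must be non-empty and names unique; duplicate
#' members within a set are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A [GeneSetCollection].
#' @export
readGmt <- function(path) {
  dl <- .readDataLines(path)
  fields <- .splitFields(dl$text)
  sets <- list()
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3)
      .parseStop(path, dl$lineno[k],
                 "GMT line needs a name, a description and at least one gene")
    nm <- f[1]
    if (nm %in% names(sets))
      .parseStop(path, dl$lineno[k], sprintf("duplicate set name '%s'", nm))
    sets[[nm]] <- unique(f[-(1:2)])
  }
  GeneSetCollection(sets = sets)
}

#' Write gene sets in GMT format
#'
#' @param x A [GeneSetCollection].
#' @param path Output path.
#' @param description Optional per-set description column (recycled).
#' @return Invisibly, \code{path}.
#' @export
writeGmt <- function(x, path, description = "na") {
  stopifnot(is(x, "GeneSetCollection"))
  s <- geneSets(x)
  desc <- rep_len(description, length(s))
  con <- file(path, "w", encoding = "UTF-8"); on.exit(close(con))
  writeLines(vapply(seq_along(s), function(i) {
    paste(c(names(s)[i], desc[i], s[[i]]), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

#' Read drug-target associations from TSV
#'
#' Three tab-separated columns: agent identifier, target gene, and a 0/1
#' clinical-support flag. Duplicate (agent, target) pairs are collapsed; an
#' agent's support flag is the OR over all of its rows.
#'
#' @param path Path to the TSV file.
#' @return A [DrugTargetTable].
#' @export
readDrugTargets <- function(path) {
  dl <- .readDataLines(path)
  if (length(dl$text) == 0)
    stop(sprintf("%s: no data rows", basename(path)), call. = FALSE)
  fields <- .splitFields(dl$text)
  first <- 1L
  if (length(fields[[1]]) >= 3 && !.isNumericToken(fields[[1]][3]))
    first <- 2L                       # header row
  if (first > length(fields))
    stop(sprintf("%s: no data rows", basename(path)), call. = FALSE)
  ag <- character(0); tg <- character(0); fl <- logical(0)
  for (k in seq(from = first, length.out = length(fields) - first + 1L)) {
    f <- fields[[k]]
    if (length(f) != 3)
      .parseStop(path, dl$lineno[k],
                 sprintf("expected 3 tab-separated fields, got %d", length(f)))
    if (!f[3] %in% c("0", "1"))
      .parseStop(path, dl$lineno[k],
                 sprintf("support flag '%s' must be 0 or 1", f[3]))
    ag <- c(ag, f[1]); tg <- c(tg, f[2]); fl <- c(fl, f[3] == "1")
  }
  DrugTargetTable(agentId = ag, targetId = tg, supported = fl)
}

#' Write drug-target associations to TSV
#'
#' Each row carries the (OR-collapsed) agent-level support flag.
#'
#' @param x A [DrugTargetTable].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeDrugTargets <- function(x, path) {
  stopifnot(is(x, "DrugTargetTable"))
  df <- as.data.frame(x)
  con <- file(path, "w", encoding = "UTF-8"); on.exit(close(con))
  writeLines(c("agent_id\ttarget_gene_id\tsupported",
               sprintf("%s\t%s\t%d", df$agent_id, df$target_gene_id,
                       df$supported)), con)
  invisible(path)
}

#' Read or write a ranked gene list (rank, gene, score TSV)
#'
#' @param x A [RankedGeneList] (for writing).
#' @param path File path.
#' @return \code{readRankedGenes} returns a [RankedGeneList];
#'   \code{writeRankedGenes} invisibly returns \code{path}.
#' @export
writeRankedGenes <- function(x, path) {
  stopifnot(is(x, "RankedGeneList"))
  con <- file(path, "w", encoding = "UTF-8"); on.exit(close(con))
  writeLines(c("rank\tgene_id\tscore",
               sprintf("%d\t%s\t%.17g", x@rank, x@geneId, x@score)), con)
  invisible(path)
}

#' @rdname writeRankedGenes
#' @export
readRankedGenes <- function(path) {
  dl <- .readDataLines(path)
  if (length(dl$text) == 0)
    stop(sprintf("%s: no data rows", basename(path)), call. = FALSE)
  fields <- .splitFields(dl$text)
  first <- if (!.isNumericToken(fields[[1]][1])) 2L else 1L
  if (first > length(fields)) return(RankedGeneList())
  fields <- fields[seq(first, length(fields))]
  bad <- which(lengths(fields) != 3)
  if (length(bad))
    .parseStop(path, dl$lineno[first + bad[1] - 1L],
               "expected 3 tab-separated fields")
  RankedGeneList(
    rank = as.integer(vapply(fields, `[`, character(1), 1)),
    geneId = vapply(fields, `[`, character(1), 2),
    score = as.numeric(vapply(fields, `[`, character(1), 3)))
}
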