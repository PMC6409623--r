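## Candidate-agent prediction from a prioritized gene set, and the
## clinical-support comparison between two prediction strategies.

#' Predict candidate agents from a gene set
#'
#' An agent is predicted when at least one of its targets lies in the query
#' gene set (the inclusive one-hit rule). Output is ordered by agent
#' identifier (C-locale), so predictions are deterministic.
#'
#' @param geneSet Non-empty character vector of gene identifiers.
#' @param table A [DrugTargetTable].
#' @return A data.frame with one row per predicted agent: \code{agent_id},
#'   \code{n_hit_targets}, \code{hit_targets} (';'-joined, sorted) and
#'   \code{supported} (logical clinical-support flag).
#' @examples
#' dt <- DrugTargetTable(c("D1", "D2"), c("G1", "G2"), supported = c(1, 0))
#' predictAgents("G1", dt)
#' @export
predictAgents <- function(geneSet, table) {
  stopifnot(is(table, "DrugTargetTable"))
  if (length(geneSet) == 0) stop("'geneSet' must be non-empty")
  hit <- table@targetId %in% geneSet
  if (!any(hit))
    return(data.frame(agent_id = character(0), n_hit_targets = integer(0),
                      hit_targets = character(0), supported = logical(0),
                      stringsAsFactors = FALSE))
  byAgent <- split(table@targetId[hit], table@agentId[hit])
  ag <- sort(names(byAgent), method = "radix")
  data.frame(
    agent_id = ag,
    n_hit_targets = lengths(byAgent)[ag],
    hit_targets = vapply(byAgent[ag], function(t)
      paste(sort(t, method = "radix"), collapse = ";"), character(1)),
    supported = unname(table@support[ag]),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Clinical-support rate of a prediction
#'
#' @param predictions Non-empty data.frame from [predictAgents()].
#' @return List with \code{nSupported}, \code{nTotal} and \code{percent}
#'   (100 * supported/total, rounded to 2 decimals).
#' @examples
#' # 32 of 263 supported agents -> 12.17
#' @export
clinicalSupportRate <- function(predictions) {
  if (!is.data.frame(predictions) || nrow(predictions) == 0)
    stop("'predictions' must be a non-empty prediction data.frame")
  ns <- sum(predictions$supported)
  nt <- nrow(predictions)
  list(nSupported = ns, nTotal = nt, percent = round(100 * ns / nt, 2))
}

#' Compare the clinical-support rates of two strategies
#'
#' Builds the 2x2 table (rows: strategies; columns: supported / unsupported
#' agents) and applies the uncorrected Pearson chi-squared test of
#' [chiSquare2x2()].
#'
#' @param a,b Length-2 numeric vectors \code{c(nSupported, nTotal)} for each
#'   strategy.
#' @return The [chiSquare2x2()] result list.
#' @examples
#' compareSupport(c(32, 263), c(4, 127))$p.value  # ~3.94e-3
#' @export
compareSupport <- function(a, b) {
  stopifnot(length(a) == 2, length(b) == 2)
  if (a[2] <= 0 || b[2] <= 0) stop("both totals must be positive")
  if (a[1] > a[2] || b[1] > b[2])
    stop("supported count cannot exceed the total")
  chiSquare2x2(matrix(c(a[1], a[2] - a[1], b[1], b[2] - b[1]),
                      nrow = 2, byrow = TRUE))
}
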