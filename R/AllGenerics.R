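#' @include AllClasses.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the PheWASRank S4 classes.
#'
#' @param x An object of one of the PheWASRank classes.
#' @param ... Further arguments passed to methods.
#' @return The slot contents described on the class pages.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x, ...) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("initialScores", function(x, ...) standardGeneric("initialScores"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("edgeCount", function(x, ...) standardGeneric("edgeCount"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("outDegree", function(x, ...) standardGeneric("outDegree"))

#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x, ...) standardGeneric("adjacencyMatrix"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x, ...) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("agents", function(x, ...) standardGeneric("agents"))

#' @rdname accessors
#' @export
setGeneric("supportFlags", function(x, ...) standardGeneric("supportFlags"))

#' @rdname accessors
#' @export
setGeneric("rankScores", function(x, ...) standardGeneric("rankScores"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x, ...) standardGeneric("converged"))
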