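#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers, so user code never
#' reaches into slots.
#'
#' @param x an object of one of the package classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIDs", function(x) standardGeneric("geneIDs"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))

#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))

#' @rdname accessors
#' @export
setGeneric("logFoldChanges", function(x) standardGeneric("logFoldChanges"))

#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname accessors
#' @export
setGeneric("q2Threshold", function(x) standardGeneric("q2Threshold"))

#' @rdname accessors
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @rdname accessors
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @rdname accessors
#' @export
setGeneric("discordantGenes", function(x) standardGeneric("discordantGenes"))

#' @rdname accessors
#' @export
setGeneric("bioscalars", function(x) standardGeneric("bioscalars"))

#' @rdname accessors
#' @export
setGeneric("couplingLine", function(x) standardGeneric("couplingLine"))

#' @rdname accessors
#' @export
setGeneric("signatureMeans", function(x) standardGeneric("signatureMeans"))

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname accessors
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))
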