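#' @name mbgsa-accessors
#' @title Accessors for mbgsa classes
#' @description Accessor generics for the package's S4 classes: gene
#'   identifiers, ranks, weights, set/background sizes, statistic and
#'   p-value components.
#' @param object an mbgsa S4 object.
#' @return The requested component.
#' @examples
#' gs <- WeightedGeneSet(c("A", "B"), c(2, 2))
#' geneIds(gs)
#' geneWeights(gs)
NULL

#' @rdname mbgsa-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("geneRanks", function(object) standardGeneric("geneRanks"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("geneWeights", function(object) standardGeneric("geneWeights"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("setSize", function(object) standardGeneric("setSize"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("statValue", function(object) standardGeneric("statValue"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("nullMean", function(object) standardGeneric("nullMean"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("nullSd", function(object) standardGeneric("nullSd"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname mbgsa-accessors
#' @export
setGeneric("stdError", function(object) standardGeneric("stdError"))
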