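#' @rdname InteractionNetwork-class
#' @param x an object
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("nodeDegree", function(x) standardGeneric("nodeDegree"))

#' @rdname KernelMatrix-class
#' @param x an object
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname KernelMatrix-class
#' @export
setGeneric("kernelType", function(x) standardGeneric("kernelType"))

#' @rdname KernelMatrix-class
#' @export
setGeneric("unreachableNodes", function(x) standardGeneric("unreachableNodes"))

#' @rdname NetworkDistanceMatrix-class
#' @param x an object
#' @export
setGeneric("associationProb", function(x) standardGeneric("associationProb"))

#' @rdname NetworkDistanceMatrix-class
#' @export
setGeneric("networkDistance", function(x) standardGeneric("networkDistance"))

#' @rdname PhyloDistanceMatrix-class
#' @param x an object
#' @export
setGeneric("phyloRaw", function(x) standardGeneric("phyloRaw"))

#' @rdname PhyloDistanceMatrix-class
#' @export
setGeneric("phyloNorm", function(x) standardGeneric("phyloNorm"))

#' @rdname NullEnsemble-class
#' @param x an object
#' @export
setGeneric("nullValues", function(x) standardGeneric("nullValues"))

#' @rdname DIRPSet-class
#' @param x an object
#' @export
setGeneric("dirpPairs", function(x) standardGeneric("dirpPairs"))

#' @rdname DIRPSet-class
#' @export
setGeneric("dirpSelected", function(x) standardGeneric("dirpSelected"))

#' @rdname ConservationProfile-class
#' @param x an object
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname ComplexStructure-class
#' @param x an object
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname ComplexStructure-class
#' @export
setGeneric("rasChain", function(x) standardGeneric("rasChain"))

#' @rdname InterfaceRegion-class
#' @param x an object
#' @export
setGeneric("interfacePositions",
           function(x) standardGeneric("interfacePositions"))

#' @rdname InterfaceRegion-class
#' @export
setGeneric("deltaSASA", function(x) standardGeneric("deltaSASA"))

#' @rdname MatchTable-class
#' @param x an object
#' @export
setGeneric("matchByComplex", function(x) standardGeneric("matchByComplex"))

#' @rdname MatchTable-class
#' @export
setGeneric("matchByPosition", function(x) standardGeneric("matchByPosition"))
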