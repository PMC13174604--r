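#' @rdname ConstructLibrary-class
#' @param x,object a `ConstructLibrary`
#' @export
setGeneric("constructIds", function(x) standardGeneric("constructIds"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("utrSequences", function(x) standardGeneric("utrSequences"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("constructFamily", function(x) standardGeneric("constructFamily"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("isSpikeIn", function(x) standardGeneric("isSpikeIn"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("acapBarcode", function(x) standardGeneric("acapBarcode"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("gcapBarcode", function(x) standardGeneric("gcapBarcode"))

#' @rdname ConstructLibrary-class
#' @export
setGeneric("commonAdapter", function(x) standardGeneric("commonAdapter"))

#' @rdname designScanningMutants
#' @export
setGeneric("designManifest", function(x) standardGeneric("designManifest"))

#' @rdname SimulationTruth-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname SecondaryStructure-class
#' @export
setGeneric("basePairs", function(x) standardGeneric("basePairs"))

#' @rdname fitSpikeInFactors
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
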