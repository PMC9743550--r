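#' @rdname AbundanceMatrix-class
#' @param x an object.
#' @export
setGeneric("abundances", function(x) standardGeneric("abundances"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("obsIds", function(x) standardGeneric("obsIds"))

#' @rdname AbundanceMatrix-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname DivikTree-class
#' @param x an object.
#' @export
setGeneric("treeConfig", function(x) standardGeneric("treeConfig"))

#' @rdname DivikTree-class
#' @export
setGeneric("rootNode", function(x) standardGeneric("rootNode"))

#' @rdname DivikTree-class
#' @export
setGeneric("treeLeaves", function(x) standardGeneric("treeLeaves"))

#' @rdname DivikTree-class
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))
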