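#' @rdname accessors
#' @export
setGeneric("organismID", function(x) standardGeneric("organismID"))

#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname accessors
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' @rdname accessors
#' @export
setGeneric("clusterEntropies", function(x) standardGeneric("clusterEntropies"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))
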