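#' Accessors for prioNet classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a prioNet S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("diseases", function(object) standardGeneric("diseases"))
#' @rdname accessors
#' @export
setGeneric("similarity", function(object) standardGeneric("similarity"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("members", function(object) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("conductance", function(object) standardGeneric("conductance"))

#' @rdname accessors
#' @export
setMethod("genes", "GeneNetwork", function(object) object@genes)
#' @rdname accessors
#' @export
setMethod("adjacency", "GeneNetwork", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("diseases", "DiseaseSimilarityNetwork", function(object) object@diseases)
#' @rdname accessors
#' @export
setMethod("similarity", "DiseaseSimilarityNetwork", function(object) object@similarity)
#' @rdname accessors
#' @export
setMethod("diseases", "AssociationMatrix", function(object) object@diseases)
#' @rdname accessors
#' @export
setMethod("genes", "AssociationMatrix", function(object) object@genes)
#' @rdname accessors
#' @export
setMethod("scores", "AssociationMatrix", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("members", "Subnetwork", function(object) object@members)
#' @rdname accessors
#' @export
setMethod("conductance", "Subnetwork", function(object) object@conductance)
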