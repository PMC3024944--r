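#' @rdname HitSet-class
#' @param x a \code{HitSet}.
#' @export
setGeneric("readId", function(x) standardGeneric("readId"))

#' @rdname HitSet-class
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname HitSet-class
#' @export
setGeneric("trueHit", function(x) standardGeneric("trueHit"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("nodeRanks", function(x) standardGeneric("nodeRanks"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("nodeParents", function(x) standardGeneric("nodeParents"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("nodeDepths", function(x) standardGeneric("nodeDepths"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("postOrder", function(x) standardGeneric("postOrder"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("subtreeMin", function(x) standardGeneric("subtreeMin"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("leafCounts", function(x) standardGeneric("leafCounts"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("taxRoot", function(x) standardGeneric("taxRoot"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("taxLeaves", function(x) standardGeneric("taxLeaves"))

#' @rdname TaxonomyIndex-accessors
#' @export
setGeneric("isPreprocessed", function(x) standardGeneric("isPreprocessed"))

#' @rdname Assignment-class
#' @param x an \code{Assignment}.
#' @export
setGeneric("bestNodes", function(x) standardGeneric("bestNodes"))

#' @rdname Assignment-class
#' @export
setGeneric("canonicalNode", function(x) standardGeneric("canonicalNode"))

#' @rdname Assignment-class
#' @export
setGeneric("assignmentScore", function(x) standardGeneric("assignmentScore"))

#' @rdname Assignment-class
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
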