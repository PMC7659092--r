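#' @rdname GODag-class
#' @param object,x a `GODag`.
#' @export
setGeneric("goTermIds", function(x) standardGeneric("goTermIds"))

#' @rdname GODag-class
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))

#' @rdname GODag-class
#' @param id a term id.
#' @export
setGeneric("goParents", function(x, id) standardGeneric("goParents"))

#' @rdname GODag-class
#' @export
setGeneric("goChildren", function(x, id) standardGeneric("goChildren"))

#' @rdname AnnotationSet-class
#' @param x an `AnnotationSet`.
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))

#' @rdname AnnotationSet-class
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' @rdname HetNet-class
#' @param x a `HetNet`.
#' @export
setGeneric("netNodes", function(x) standardGeneric("netNodes"))

#' @rdname HetNet-class
#' @export
setGeneric("netEdges", function(x) standardGeneric("netEdges"))

#' @rdname EmbeddingModel-class
#' @param x an `EmbeddingModel`.
#' @export
setGeneric("nodeVectors", function(x) standardGeneric("nodeVectors"))

#' @rdname EmbeddingModel-class
#' @export
setGeneric("relationVectors", function(x) standardGeneric("relationVectors"))

#' @rdname EmbeddingModel-class
#' @export
setGeneric("relationVocabulary",
           function(x) standardGeneric("relationVocabulary"))

#' @rdname HierModel-class
#' @param x a `HierModel` or `EmbeddingModel`.
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' @rdname HierModel-class
#' @export
setGeneric("termVocabulary", function(x) standardGeneric("termVocabulary"))
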