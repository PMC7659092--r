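#' @rdname GODag-class
#' @export
setMethod("goTermIds", "GODag", function(x) x@terms$id)

#' @rdname GODag-class
#' @export
setMethod("goRoots", "GODag", function(x) x@roots)

#' @rdname GODag-class
#' @export
setMethod("goParents", "GODag", function(x, id) {
  if (!id %in% x@terms$id) stop("unknown term '", id, "'")
  data.frame(parent = x@parents[[id]], relation = x@relations[[id]],
             stringsAsFactors = FALSE)
})

#' @rdname GODag-class
#' @export
setMethod("goChildren", "GODag", function(x, id) {
  if (!id %in% x@terms$id) stop("unknown term '", id, "'")
  x@children[[id]]
})

#' @rdname GODag-class
#' @export
setMethod("length", "GODag", function(x) nrow(x@terms))

setMethod("show", "GODag", function(object) {
  ns <- unique(object@terms$namespace)
  cat("GODag with", nrow(object@terms), "terms (",
      paste(ns, collapse = ", "), ")\n")
  cat("  roots:", paste(object@roots, collapse = ", "), "\n")
})

#' @rdname AnnotationSet-class
#' @export
setMethod("annotations", "AnnotationSet", function(x) x@entries)

#' @rdname AnnotationSet-class
#' @export
setMethod("isPropagated", "AnnotationSet", function(x) x@propagated)

#' @rdname AnnotationSet-class
#' @export
setMethod("length", "AnnotationSet", function(x) length(x@entries))

#' @rdname AnnotationSet-class
#' @export
setMethod("names", "AnnotationSet", function(x) names(x@entries))

setMethod("show", "AnnotationSet", function(object) {
  n <- length(object@entries)
  nt <- length(unique(unlist(object@entries, use.names = FALSE)))
  cat("AnnotationSet:", n, "entities,", nt, "distinct terms,",
      if (object@propagated) "propagated" else "unpropagated", "\n")
})

#' @rdname HetNet-class
#' @export
setMethod("netNodes", "HetNet", function(x) x@nodes)

#' @rdname HetNet-class
#' @export
setMethod("netEdges", "HetNet", function(x) x@edges)

setMethod("show", "HetNet", function(object) {
  tn <- table(object@nodes$type)
  te <- table(object@edges$type)
  cat("HetNet:", nrow(object@nodes), "nodes (",
      paste(names(tn), tn, sep = "=", collapse = ", "), "),",
      nrow(object@edges), "edges (",
      paste(names(te), te, sep = "=", collapse = ", "), ")\n")
})

#' @rdname EmbeddingModel-class
#' @export
setMethod("nodeVectors", "EmbeddingModel", function(x) x@nodes)

#' @rdname EmbeddingModel-class
#' @export
setMethod("relationVectors", "EmbeddingModel", function(x) x@relations)

#' @rdname EmbeddingModel-class
#' @export
setMethod("relationVocabulary", "EmbeddingModel",
          function(x) rownames(x@relations))

#' @rdname EmbeddingModel-class
#' @export
setMethod("trainingHistory", "EmbeddingModel", function(x) x@history)

setMethod("show", "EmbeddingModel", function(object) {
  cat("EmbeddingModel:", nrow(object@nodes), "nodes x",
      ncol(object@nodes), "dims,", nrow(object@relations),
      "meta-path relations\n")
  if (length(object@history)) {
    cat("  final epoch loss:",
        format(utils::tail(object@history, 1), digits = 4), "\n")
  }
})

#' @rdname HierModel-class
#' @export
setMethod("termVocabulary", "HierModel", function(x) x@vocabulary)

#' @rdname HierModel-class
#' @export
setMethod("trainingHistory", "HierModel", function(x) x@history)

setMethod("show", "HierModel", function(object) {
  cat("HierModel:", nrow(object@W1), "->", ncol(object@W1),
      "shared units ->", length(object@vocabulary), "GO term heads\n")
  if (nrow(object@history)) {
    cat("  final training loss:",
        format(utils::tail(object@history$loss, 1), digits = 4), "\n")
  }
})
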