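#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib hingo, .registration = TRUE
NULL

#' GODag: the Gene Ontology as a typed directed acyclic graph
#'
#' Holds non-obsolete terms of a single namespace together with their
#' `is_a`/`part_of` parent links. The parent relation must be acyclic and
#' every parent must resolve to a term in the DAG.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`, one row per
#'   term, rownames = `id`.
#' @slot parents named list: term id -> character vector of parent ids.
#' @slot relations named list, parallel to `parents`: the relation
#'   (`"is_a"` or `"part_of"`) of each parent link.
#' @slot children named list: term id -> character vector of child ids
#'   (inverse of `parents`).
#' @slot roots character vector of term ids with no parents.
#' @export
setClass("GODag",
  representation(
    terms = "data.frame",
    parents = "list",
    relations = "list",
    children = "list",
    roots = "character"
  )
)

setValidity("GODag", function(object) {
  ids <- object@terms$id
  if (anyDuplicated(ids)) {
    return("duplicate term ids")
  }
  for (i in ids) {
    ps <- object@parents[[i]]
    if (length(ps) && !all(ps %in% ids)) {
      return(sprintf("term '%s' has an unresolved parent", i))
    }
    if (length(ps) != length(object@relations[[i]])) {
      return(sprintf("term '%s': parents/relations length mismatch", i))
    }
  }
  ok <- tryCatch({
    topoSort(ids, object@parents)
    TRUE
  }, error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) return(ok)
  TRUE
})

#' Construct a GODag
#'
#' @param terms data.frame with columns `id`, `name`, `namespace` (missing
#'   `name`/`namespace` columns are filled in), or a character vector of ids.
#' @param edges data.frame of parent links with columns `child`, `parent`,
#'   `relation` (`"is_a"` or `"part_of"`). May have zero rows.
#' @return a [GODag-class] object.
#' @examples
#' dag <- GODag(c("t1", "t2", "t3"),
#'              data.frame(child = c("t2", "t3"), parent = c("t1", "t2"),
#'                         relation = "is_a"))
#' goRoots(dag)
#' @export
GODag <- function(terms, edges = data.frame(child = character(0),
                                            parent = character(0),
                                            relation = character(0))) {
  if (is.character(terms)) {
    terms <- data.frame(id = terms, stringsAsFactors = FALSE)
  }
  if (is.null(terms$name)) terms$name <- terms$id
  if (is.null(terms$namespace)) terms$namespace <- "biological_process"
  terms <- terms[, c("id", "name", "namespace")]
  rownames(terms) <- terms$id
  if (nrow(edges) && !all(edges$relation %in% c("is_a", "part_of"))) {
    stop("edge relations must be 'is_a' or 'part_of'")
  }
  ids <- terms$id
  parents <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  relations <- parents
  if (nrow(edges)) {
    sp <- split(seq_len(nrow(edges)), edges$child)
    for (ch in names(sp)) {
      idx <- sp[[ch]]
      parents[[ch]] <- as.character(edges$parent[idx])
      relations[[ch]] <- as.character(edges$relation[idx])
    }
  }
  children <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  for (ch in ids) {
    for (p in parents[[ch]]) children[[p]] <- c(children[[p]], ch)
  }
  roots <- ids[vapply(parents[ids], length, integer(1)) == 0L]
  new("GODag", terms = terms, parents = parents, relations = relations,
      children = children, roots = roots)
}

#' AnnotationSet: GO annotations of a set of entities
#'
#' Maps entity ids (proteins or circRNAs) to sets of GO term ids. The
#' `propagated` flag records whether the sets are closed under
#' `is_a`/`part_of` ancestors (the true-path rule).
#'
#' @slot entries named list: entity id -> character vector of term ids.
#' @slot propagated logical scalar.
#' @export
setClass("AnnotationSet",
  representation(entries = "list", propagated = "logical")
)

setValidity("AnnotationSet", function(object) {
  if (length(object@entries) && is.null(names(object@entries))) {
    return("entries must be named by entity id")
  }
  if (length(object@propagated) != 1L) return("propagated must be a scalar")
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param entries named list of character vectors (entity id -> term ids).
#' @param propagated logical: are the sets already ancestor-closed?
#' @return an [AnnotationSet-class].
#' @export
AnnotationSet <- function(entries = list(), propagated = FALSE) {
  entries <- lapply(entries, function(x) sort(unique(as.character(x))))
  new("AnnotationSet", entries = entries, propagated = propagated)
}

#' HetNet: heterogeneous circRNA-protein network
#'
#' Typed undirected network with node types `circRNA`/`protein` and edge
#' types `co_expr` (circRNA-circRNA), `circ_prot` (circRNA-protein) and
#' `ppi` (protein-protein). Each unordered node pair is stored once, with
#' `from < to` lexicographically; self-loops are forbidden and all weights
#' must be finite.
#'
#' @slot nodes data.frame with columns `id`, `type`.
#' @slot edges data.frame with columns `from`, `to`, `type`, `weight`.
#' @export
setClass("HetNet",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("HetNet", function(object) {
  nd <- object@nodes
  ed <- object@edges
  if (anyDuplicated(nd$id)) return("duplicate node ids")
  if (!all(nd$type %in% c("circRNA", "protein"))) {
    return("node types must be 'circRNA' or 'protein'")
  }
  if (nrow(ed)) {
    if (any(ed$from == ed$to)) return("self-loops are not allowed")
    if (!all(c(ed$from, ed$to) %in% nd$id)) {
      return("edge endpoint not in node table")
    }
    if (!all(is.finite(ed$weight))) return("edge weights must be finite")
    key <- paste(ed$from, ed$to)
    if (anyDuplicated(key)) return("duplicate edges for an unordered pair")
    tf <- nd$type[match(ed$from, nd$id)]
    tt <- nd$type[match(ed$to, nd$id)]
    want <- ifelse(tf == "circRNA" & tt == "circRNA", "co_expr",
            ifelse(tf == "protein" & tt == "protein", "ppi", "circ_prot"))
    if (!all(ed$type == want)) {
      return("edge type inconsistent with endpoint node types")
    }
  }
  TRUE
})

#' Construct a HetNet
#'
#' Canonicalizes edge orientation (lexicographic `from < to`) and row order
#' so that networks built from permuted inputs compare identical.
#'
#' @param nodes data.frame with columns `id`, `type`.
#' @param edges data.frame with columns `from`, `to`, `type`, `weight`.
#' @return a [HetNet-class].
#' @export
HetNet <- function(nodes, edges) {
  nodes <- data.frame(id = as.character(nodes$id),
                      type = as.character(nodes$type),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (is.null(edges$weight)) edges$weight <- 1
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- data.frame(from = as.character(edges$from),
                      to = as.character(edges$to),
                      type = as.character(edges$type),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  new("HetNet", nodes = nodes, edges = edges)
}

#' EmbeddingModel: learned node and relation vectors
#'
#' The result of meta-path embedding training: one d-dimensional vector per
#' network node (rownames = node ids) and one per meta-path relation
#' (rownames = relation strings).
#'
#' @slot nodes numeric matrix, N x d, rownames node ids.
#' @slot relations numeric matrix, |Z| x d, rownames relation strings.
#' @slot nodeTypes named character: node id -> node type.
#' @slot f01Method character: `"logistic"` or `"clip"`.
#' @slot history numeric vector of mean per-epoch training losses.
#' @export
setClass("EmbeddingModel",
  representation(nodes = "matrix", relations = "matrix",
                 nodeTypes = "character", f01Method = "character",
                 history = "numeric")
)

setValidity("EmbeddingModel", function(object) {
  if (!all(is.finite(object@nodes))) return("non-finite node vectors")
  if (!all(is.finite(object@relations))) return("non-finite relation vectors")
  if (ncol(object@nodes) != ncol(object@relations)) {
    return("node and relation dimensionality differ")
  }
  if (is.null(rownames(object@nodes))) return("node matrix must be rownamed")
  TRUE
})

#' HierModel: GO-hierarchy-aware multi-label classifier
#'
#' A shared fully connected layer over embedding features feeding one
#' sigmoid head per GO term, followed by a max-merge layer that enforces
#' DAG-consistent scores (a parent's score is the maximum over itself and
#' its descendants).
#'
#' @slot W1,b1 shared-layer weights (d x h) and bias (h).
#' @slot W2,b2 per-term head weights (h x T) and biases (T).
#' @slot vocabulary character vector of term ids, topologically ordered
#'   (parents before children).
#' @slot children named list: vocabulary term -> in-vocabulary children.
#' @slot dropout numeric dropout rate used in training.
#' @slot hyper list of training hyperparameters.
#' @slot history data.frame of per-epoch losses.
#' @export
setClass("HierModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix",
                 b2 = "numeric", vocabulary = "character",
                 children = "list", dropout = "numeric", hyper = "list",
                 history = "data.frame")
)

setValidity("HierModel", function(object) {
  if (ncol(object@W2) != length(object@vocabulary)) {
    return("one head per vocabulary term required")
  }
  kids <- unlist(object@children, use.names = FALSE)
  if (length(kids) && !all(kids %in% object@vocabulary)) {
    return("child map must be restricted to the vocabulary")
  }
  TRUE
})
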