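#' Parse a Gene Ontology OBO file
#'
#' Reads an OBO 1.2/1.4 flat file and returns the non-obsolete terms of one
#' namespace as a [GODag-class]. `alt_id` accessions are remembered so that
#' annotations to alternate ids resolve to the canonical term (see
#' [resolveTermIds()]). Parent links (`is_a` and `relationship: part_of`)
#' pointing outside the retained term set (other namespaces, obsolete terms)
#' are dropped, as is standard for single-namespace DAGs.
#'
#' @param path path to an OBO file.
#' @param namespace namespace to retain; one of `"biological_process"`,
#'   `"molecular_function"`, `"cellular_component"`. Defaults to
#'   biological_process, the namespace in which transferred circRNA
#'   annotations are evaluated.
#' @return a [GODag-class] with an `altIds` attribute (named character
#'   vector: alternate id -> canonical id).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "", "[Term]", "id: T:1", "name: root",
#'   "namespace: biological_process", "", "[Term]", "id: T:2", "name: child",
#'   "namespace: biological_process", "is_a: T:1 ! root"), obo)
#' parseOBO(obo)
#' @export
parseOBO <- function(path, namespace = "biological_process") {
  namespace <- match.arg(namespace, c("biological_process",
                                      "molecular_function",
                                      "cellular_component"))
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  cur <- NULL
  inTerm <- FALSE
  flush <- function(cur, terms) {
    if (!is.null(cur) && !is.null(cur$id)) terms[[cur$id]] <- cur
    terms
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "!")) next
    if (grepl("^\\[.*\\]$", ln)) {
      if (inTerm) terms <- flush(cur, terms)
      inTerm <- identical(ln, "[Term]")
      cur <- list(parents = character(0), relations = character(0),
                  altIds = character(0), obsolete = FALSE)
      next
    }
    if (!grepl("^[A-Za-z_-]+:", ln)) {
      # header lines before the first stanza are key: value too, so any
      # non-matching line is malformed
      stop("malformed OBO stanza at line ", i, ": '", ln, "'")
    }
    if (!inTerm) next
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[A-Za-z_-]+:", "", ln))
    val <- trimws(sub("\\s*!.*$", "", val))  # strip trailing comments
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "alt_id") cur$altIds <- c(cur$altIds, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
      cur$relations <- c(cur$relations, "is_a")
    } else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        cur$parents <- c(cur$parents, parts[2L])
        cur$relations <- c(cur$relations, "part_of")
      }
    }
  }
  if (inTerm) terms <- flush(cur, terms)
  if (!length(terms)) stop("no [Term] stanzas found in ", path)

  keep <- vapply(terms, function(t) {
    !isTRUE(t$obsolete) && identical(t$namespace, namespace)
  }, logical(1))
  terms <- terms[keep]
  if (!length(terms)) stop("no non-obsolete '", namespace, "' terms in ", path)

  ids <- names(terms)
  altIds <- do.call(c, c(list(character(0)), unname(lapply(terms,
    function(t) stats::setNames(rep(t$id, length(t$altIds)), t$altIds)))))

  edges <- do.call(rbind, lapply(terms, function(t) {
    if (!length(t$parents)) return(NULL)
    p <- t$parents
    mapped <- ifelse(p %in% names(altIds), altIds[p], p)
    ok <- mapped %in% ids
    if (!any(ok)) return(NULL)
    data.frame(child = t$id, parent = mapped[ok], relation = t$relations[ok],
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(child = character(0), parent = character(0),
                        relation = character(0))
  }
  meta <- data.frame(
    id = ids,
    name = vapply(terms, function(t) t$name %||% t$id, character(1)),
    namespace = namespace,
    stringsAsFactors = FALSE
  )
  dag <- GODag(meta, edges)
  attr(dag, "altIds") <- altIds
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve term ids through alt_id mapping
#'
#' @param ids character vector of term accessions.
#' @param dag a [GODag-class] from [parseOBO()].
#' @return ids with alternate accessions replaced by canonical ones.
#' @export
resolveTermIds <- function(ids, dag) {
  alt <- attr(dag, "altIds")
  if (is.null(alt) || !length(alt)) return(ids)
  ifelse(ids %in% names(alt), alt[ids], ids)
}

#' Ancestors of a GO term
#'
#' Transitive closure of the parent relation over the requested relation
#' types, excluding the query term itself.
#'
#' @param dag a [GODag-class].
#' @param id a term id present in `dag`.
#' @param relations subset of `c("is_a", "part_of")` to traverse.
#' @return character vector of ancestor term ids (sorted).
#' @export
goAncestors <- function(dag, id, relations = c("is_a", "part_of")) {
  if (!id %in% dag@terms$id) stop("unknown term '", id, "'")
  relations <- match.arg(relations, c("is_a", "part_of"), several.ok = TRUE)
  seen <- character(0)
  frontier <- id
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, function(t) {
      keep <- dag@relations[[t]] %in% relations
      dag@parents[[t]][keep]
    }), use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

## Ancestor closure (including self) for every term, computed once in
## topological order: anc[t] = {t} U anc[parents(t)].
ancestorIndex <- function(dag, relations = c("is_a", "part_of")) {
  ord <- topoSort(dag@terms$id, dag@parents)
  anc <- stats::setNames(vector("list", length(ord)), ord)
  for (t in ord) {
    keep <- dag@relations[[t]] %in% relations
    ps <- dag@parents[[t]][keep]
    anc[[t]] <- unique(c(t, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Propagate annotations by the true-path rule
#'
#' Replaces each entity's term set by its ancestor closure (over `is_a` and
#' `part_of`) union itself. Idempotent. Applied identically to training
#' labels and (inside the evaluation module) to prediction sets.
#'
#' @param ann an [AnnotationSet-class].
#' @param dag a [GODag-class].
#' @param unknown what to do with annotations to terms absent from `dag`:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return a propagated [AnnotationSet-class].
#' @export
propagateAnnotations <- function(ann, dag, unknown = c("drop", "error")) {
  unknown <- match.arg(unknown)
  ids <- dag@terms$id
  allTerms <- unique(unlist(ann@entries, use.names = FALSE))
  missing <- setdiff(allTerms, ids)
  if (length(missing)) {
    if (unknown == "error") {
      stop("annotation to unknown term(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    warning(length(missing), " annotated term(s) absent from the DAG; ",
            "dropped")
  }
  anc <- ancestorIndex(dag)
  entries <- lapply(ann@entries, function(ts) {
    ts <- intersect(ts, ids)
    sort(unique(unlist(anc[ts], use.names = FALSE)))
  })
  AnnotationSet(entries, propagated = TRUE)
}

#' Select trainable GO terms
#'
#' Returns the classifier's output vocabulary: terms annotated (after
#' propagation) to at least `minCount` entities, in deterministic
#' topological order (parents before children). Namespace roots are kept in
#' the DAG but excluded from the vocabulary: a root prediction carries no
#' information and would inflate precision.
#'
#' @param ann a propagated [AnnotationSet-class].
#' @param dag a [GODag-class].
#' @param minCount minimum number of annotated entities (>= 1). The default
#'   of 10 suits genome-scale annotation sets; small synthetic worlds
#'   typically use 1.
#' @return character vector of term ids, parents before children.
#' @export
selectTerms <- function(ann, dag, minCount = 10) {
  if (!isTRUE(ann@propagated)) stop("annotations must be propagated first")
  if (!is.numeric(minCount) || minCount < 1) stop("minCount must be >= 1")
  if (!length(ann@entries)) return(character(0))
  counts <- table(unlist(ann@entries, use.names = FALSE))
  keep <- names(counts)[counts >= minCount]
  keep <- setdiff(intersect(keep, dag@terms$id), dag@roots)
  if (!length(keep)) return(character(0))
  ord <- topoSort(dag@terms$id, dag@parents)
  ord[ord %in% keep]
}
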