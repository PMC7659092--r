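## Plain-text readers and writers for the pipeline's file formats. All
## tables are TSV with a header row.

#' Read a circRNA expression matrix
#'
#' TSV with the circRNA id in the first column and one column per sample.
#'
#' @param path file path.
#' @return numeric matrix, circRNAs x samples.
#' @export
readExpression <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- d[[1L]]
  m
}

#' @rdname readExpression
#' @param expr expression matrix.
#' @export
writeExpression <- function(expr, path) {
  d <- data.frame(id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read / write an edge list
#'
#' 2- or 3-column TSV (`from`, `to`, optional `weight`/score).
#'
#' @param path file path.
#' @return data.frame `from`, `to` (+ `weight` if present).
#' @export
readEdgeList <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("from", "to")
  if (ncol(d) >= 3L) names(d)[3L] <- "weight"
  d
}

#' @rdname readEdgeList
#' @param edges edge data.frame.
#' @export
writeEdgeList <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read / write GAF-like annotations
#'
#' TSV with columns `entity`, `term` and optionally `evidence`; an
#' `evidence` include-list may filter rows.
#'
#' @param path file path.
#' @param evidence optional character vector of evidence codes to keep.
#' @return an unpropagated [AnnotationSet-class].
#' @export
readAnnotations <- function(path, evidence = NULL) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("entity", "term")
  if (!is.null(evidence) && "evidence" %in% names(d)) {
    d <- d[d$evidence %in% evidence, , drop = FALSE]
  }
  AnnotationSet(split(d$term, d$entity))
}

#' @rdname readAnnotations
#' @param ann an [AnnotationSet-class].
#' @export
writeAnnotations <- function(ann, path) {
  ents <- names(ann@entries)
  d <- do.call(rbind, lapply(ents, function(e) {
    if (!length(ann@entries[[e]])) return(NULL)
    data.frame(entity = e, term = ann@entries[[e]], evidence = "IEA")
  }))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a GODag as an OBO 1.2 document
#'
#' @param dag a [GODag-class].
#' @param path output path.
#' @export
writeOBO <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag@terms))) {
    id <- dag@terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", dag@terms$name[i]),
             paste0("namespace: ", dag@terms$namespace[i]))
    ps <- dag@parents[[id]]; rl <- dag@relations[[id]]
    for (j in seq_along(ps)) {
      out <- c(out, if (rl[j] == "is_a") paste0("is_a: ", ps[j])
                    else paste0("relationship: part_of ", ps[j]))
    }
    writeLines(c(out, ""), con)
  }
}

#' Serialize / read a heterogeneous network
#'
#' Typed edge-list TSV: `from`, `from_type`, `to`, `to_type`, `edge_type`,
#' `weight`. Isolated nodes are appended with an empty `to`.
#'
#' @param net a [HetNet-class].
#' @param path file path.
#' @export
writeHetNet <- function(net, path) {
  nd <- net@nodes; ed <- net@edges
  ty <- stats::setNames(nd$type, nd$id)
  d <- data.frame(from = ed$from, from_type = ty[ed$from], to = ed$to,
                  to_type = ty[ed$to], edge_type = ed$type,
                  weight = ed$weight)
  iso <- setdiff(nd$id, c(ed$from, ed$to))
  if (length(iso)) {
    d <- rbind(d, data.frame(from = iso, from_type = ty[iso], to = "",
                             to_type = "", edge_type = "", weight = NA))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeHetNet
#' @export
readHetNet <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ed <- d[d$to != "", , drop = FALSE]
  nodes <- unique(rbind(data.frame(id = d$from, type = d$from_type),
                        data.frame(id = ed$to, type = ed$to_type)))
  HetNet(nodes, data.frame(from = ed$from, to = ed$to, type = ed$edge_type,
                           weight = ed$weight))
}

#' Write / read node embeddings
#'
#' TSV with the node id followed by the d vector components; relation
#' vectors go to a companion `<path>.relations` file.
#'
#' @param model an [EmbeddingModel-class].
#' @param path file path.
#' @export
writeEmbeddings <- function(model, path) {
  d <- data.frame(id = rownames(model@nodes),
                  type = model@nodeTypes[rownames(model@nodes)],
                  model@nodes, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  r <- data.frame(relation = rownames(model@relations), model@relations,
                  check.names = FALSE)
  utils::write.table(r, paste0(path, ".relations"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' @rdname writeEmbeddings
#' @return `readEmbeddings`: a numeric matrix (rownames = node ids) with a
#'   `types` attribute.
#' @export
readEmbeddings <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  m <- as.matrix(d[, -(1:2), drop = FALSE])
  rownames(m) <- d$id
  attr(m, "types") <- stats::setNames(d$type, d$id)
  m
}

#' Write / read a score matrix as long-format TSV
#'
#' Columns `entity`, `term`, `score`.
#'
#' @param scores numeric matrix, entities x terms.
#' @param path file path.
#' @export
writeScores <- function(scores, path) {
  d <- data.frame(entity = rep(rownames(scores), each = ncol(scores)),
                  term = rep(colnames(scores), times = nrow(scores)),
                  score = as.vector(t(scores)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  ents <- unique(d$entity); terms <- unique(d$term)
  m <- matrix(NA_real_, length(ents), length(terms),
              dimnames = list(ents, terms))
  m[cbind(match(d$entity, ents), match(d$term, terms))] <- d$score
  m
}

#' Write a synthetic world to disk
#'
#' Emits every input file the pipeline reads (expression, associations,
#' PPIs, OBO ontology, protein annotations) plus the circRNA ground-truth
#' table, in the plain-text formats of the reader functions.
#'
#' @param world a world from [makeWorld()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             circProt = file.path(dir, "circ_prot.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.tsv"))
  writeExpression(world$expr, paths["expression"])
  writeEdgeList(world$circProt, paths["circProt"])
  writeEdgeList(world$ppi, paths["ppi"])
  writeOBO(world$dag, paths["obo"])
  writeAnnotations(world$annotations, paths["annotations"])
  writeAnnotations(world$truth, paths["truth"])
  invisible(paths)
}
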