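#' Pairwise Pearson correlation of expression profiles
#'
#' Computes the Pearson correlation coefficient (PCC) between every pair of
#' circRNA expression profiles. Rows with zero variance (correlation
#' undefined) are excluded with a message; they may still enter the network
#' through association edges. Values are clipped to \[-1, 1\] against
#' floating-point rounding.
#'
#' @param expr numeric matrix, circRNAs x samples, with rownames. At least
#'   3 samples are required.
#' @return symmetric PCC matrix over the retained rows (diagonal 1).
#' @examples
#' m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(1, 3, 2))
#' pearsonSimilarity(m)
#' @export
pearsonSimilarity <- function(expr) {
  if (!is.matrix(expr)) expr <- as.matrix(expr)
  if (!is.numeric(expr)) stop("expression values must be numeric")
  if (ncol(expr) < 3L) stop("at least 3 samples are required")
  if (is.null(rownames(expr))) stop("expression matrix must have rownames")
  if (anyDuplicated(rownames(expr))) stop("duplicate circRNA ids")
  v <- apply(expr, 1L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance expression row(s) excluded ",
            "from the co-expression layer")
    expr <- expr[v > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2L) stop("fewer than 2 rows with non-zero variance")
  sim <- stats::cor(t(expr))
  sim[sim > 1] <- 1
  sim[sim < -1] <- -1
  diag(sim) <- 1
  sim
}

#' Threshold a PCC matrix into co-expression edges
#'
#' @param sim symmetric PCC matrix (from [pearsonSimilarity()]).
#' @param tau correlation threshold in (0, 1].
#' @param positiveOnly if `TRUE` (default) keep pairs with `PCC >= tau`;
#'   otherwise keep `|PCC| >= tau`.
#' @return data.frame of `co_expr` edges (`from`, `to`, `weight` = PCC),
#'   one row per unordered pair, no self-edges.
#' @export
buildCoexprEdges <- function(sim, tau = 0.8, positiveOnly = TRUE) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]")
  }
  if (!isSymmetric(unname(sim))) stop("sim must be symmetric")
  ids <- rownames(sim)
  keep <- if (positiveOnly) sim >= tau else abs(sim) >= tau
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  data.frame(from = ids[idx[, 1L]], to = ids[idx[, 2L]],
             weight = sim[idx], stringsAsFactors = FALSE)
}

## Collapse duplicate unordered pairs, keeping the maximum weight.
dedupeEdges <- function(edges) {
  if (!nrow(edges)) return(edges)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  if (!nrow(edges)) return(edges)
  key <- paste(edges$from, edges$to)
  edges <- edges[order(key, -edges$weight), , drop = FALSE]
  edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Integrate the global heterogeneous network
#'
#' Merges the three edge layers into one typed network, mirroring the
#' mutual-consistency filtering used when combining association and
#' interaction databases: duplicate entries are collapsed (keeping the
#' maximum score), PPI edges below the confidence cutoff are dropped, PPI
#' edges whose proteins do not occur in the circRNA-protein associations
#' are dropped (unless `retainIsolatedProteins`), and association edges
#' whose protein retains no PPI edge are dropped. The two filters are
#' iterated to a fixed point. STRING-style integer scores (> 1) are
#' normalized to \[0, 1\] by dividing by 1000.
#'
#' @param coexprEdges data.frame `from`, `to`, `weight` (circRNA pairs).
#' @param circProtEdges data.frame `from` (circRNA), `to` (protein),
#'   optional `weight` (default 1).
#' @param ppiEdges data.frame `from`, `to`, `weight` (confidence score).
#' @param ppiCutoff confidence threshold on the normalized score
#'   (default 0.4, the conventional "medium confidence").
#' @param retainIsolatedProteins keep PPI edges between proteins absent
#'   from the associations (default `FALSE`).
#' @return a [HetNet-class].
#' @export
integrateNetwork <- function(coexprEdges, circProtEdges, ppiEdges,
                             ppiCutoff = 0.4,
                             retainIsolatedProteins = FALSE) {
  asEdges <- function(e, default = 1) {
    e <- as.data.frame(e, stringsAsFactors = FALSE)
    names(e)[1:2] <- c("from", "to")
    if (is.null(e$weight)) {
      e$weight <- if (ncol(e) >= 3L && is.numeric(e[[3L]])) e[[3L]] else default
    }
    e$from <- as.character(e$from)
    e$to <- as.character(e$to)
    e[, c("from", "to", "weight")]
  }
  co <- dedupeEdges(asEdges(coexprEdges))
  cp <- dedupeEdges(asEdges(circProtEdges))
  pp <- dedupeEdges(asEdges(ppiEdges))
  if (nrow(pp) && any(pp$weight > 1)) pp$weight <- pp$weight / 1000
  pp <- pp[pp$weight >= ppiCutoff, , drop = FALSE]

  # mutual cross-filtering between associations and interactions
  nDropCP <- 0L; nDropPP <- 0L
  repeat {
    assocProts <- unique(cp$to)
    if (!retainIsolatedProteins) {
      keep <- pp$from %in% assocProts & pp$to %in% assocProts
      nDropPP <- nDropPP + sum(!keep)
      pp <- pp[keep, , drop = FALSE]
    }
    ppiProts <- unique(c(pp$from, pp$to))
    keep <- cp$to %in% ppiProts
    nDropCP <- nDropCP + sum(!keep)
    newCp <- cp[keep, , drop = FALSE]
    if (nrow(newCp) == nrow(cp)) { cp <- newCp; break }
    cp <- newCp
  }
  if (nDropCP + nDropPP > 0L) {
    message("cross-filtering dropped ", nDropCP, " association and ",
            nDropPP, " PPI edge(s)")
  }

  circ <- unique(c(co$from, co$to, cp$from))
  prot <- unique(c(pp$from, pp$to, cp$to))
  both <- intersect(circ, prot)
  if (length(both)) {
    stop("node(s) appear as both circRNA and protein: ",
         paste(utils::head(both, 5), collapse = ", "))
  }
  edges <- rbind(
    if (nrow(co)) cbind(co, type = "co_expr") else NULL,
    if (nrow(cp)) cbind(cp, type = "circ_prot") else NULL,
    if (nrow(pp)) cbind(pp, type = "ppi") else NULL
  )
  if (is.null(edges) || !nrow(edges)) {
    stop("integration produced an empty network")
  }
  nodes <- data.frame(
    id = c(circ, prot),
    type = c(rep("circRNA", length(circ)), rep("protein", length(prot))),
    stringsAsFactors = FALSE
  )
  HetNet(nodes, edges)
}

#' Remove one edge layer from a heterogeneous network
#'
#' Ablation helper: deletes all edges of the given type from an already
#' integrated network, keeping the node set (nodes left without edges stay
#' in the network as isolated nodes). Removing the `ppi` layer yields the
#' "PPI-free" network of the multi-source ablation.
#'
#' @param net a [HetNet-class].
#' @param type edge type to remove (`"co_expr"`, `"circ_prot"` or
#'   `"ppi"`).
#' @return a [HetNet-class].
#' @export
dropEdgeType <- function(net, type) {
  type <- match.arg(type, c("co_expr", "circ_prot", "ppi"))
  HetNet(net@nodes, net@edges[net@edges$type != type, , drop = FALSE])
}

#' Build the heterogeneous network from an expression matrix
#'
#' Convenience wrapper: Pearson similarity, thresholded co-expression
#' edges, then [integrateNetwork()].
#'
#' @param expr circRNA expression matrix (rows = circRNAs).
#' @param circProtEdges,ppiEdges see [integrateNetwork()].
#' @param tau,positiveOnly see [buildCoexprEdges()].
#' @param ppiCutoff,retainIsolatedProteins see [integrateNetwork()].
#' @return a [HetNet-class].
#' @export
buildHetNet <- function(expr, circProtEdges, ppiEdges, tau = 0.8,
                        positiveOnly = TRUE, ppiCutoff = 0.4,
                        retainIsolatedProteins = FALSE) {
  sim <- pearsonSimilarity(expr)
  co <- buildCoexprEdges(sim, tau = tau, positiveOnly = positiveOnly)
  integrateNetwork(co, circProtEdges, ppiEdges, ppiCutoff = ppiCutoff,
                   retainIsolatedProteins = retainIsolatedProteins)
}
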