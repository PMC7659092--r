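#' Configuration of the synthetic planted-partition world
#'
#' Defines a world of functional groups: every group carries one branch of
#' a balanced ontology, its circRNAs share a latent expression profile
#' (plus Gaussian noise), and its circRNA-protein and protein-protein
#' edges are denser within the group (`pIn`) than across (`pOut`). This
#' encodes the two transfer hypotheses the pipeline relies on — similarly
#' expressed circRNAs share function, and circRNAs share function with
#' their associated proteins — with controllable strength.
#'
#' @param nGroups number of functional groups.
#' @param circPerGroup,protPerGroup circRNAs / proteins per group.
#' @param nSamples expression samples (>= 3).
#' @param exprNoiseSd standard deviation of the additive expression noise
#'   (expression is on an arbitrary z-score-like scale; the group latent
#'   profile is standard normal per sample).
#' @param pIn,pOut within- / between-group Bernoulli edge probabilities
#'   (`0 <= pOut < pIn <= 1`).
#' @param dagDepth levels below the ontology root.
#' @param dagBranching children per non-leaf term.
#' @param seed integer seed; the whole world is reproducible from it.
#' @return a validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nGroups = 4, circPerGroup = 20,
                            protPerGroup = 40, nSamples = 10,
                            exprNoiseSd = 0.1, pIn = 0.3, pOut = 0.01,
                            dagDepth = 3, dagBranching = 2, seed = 1L) {
  cfg <- list(nGroups = nGroups, circPerGroup = circPerGroup,
              protPerGroup = protPerGroup, nSamples = nSamples,
              exprNoiseSd = exprNoiseSd, pIn = pIn, pOut = pOut,
              dagDepth = dagDepth, dagBranching = dagBranching,
              seed = as.integer(seed))
  counts <- c("nGroups", "circPerGroup", "protPerGroup", "dagDepth",
              "dagBranching")
  if (any(vapply(cfg[counts], function(x) x < 1, logical(1)))) {
    stop("all counts must be >= 1")
  }
  if (cfg$nSamples < 3) stop("at least 3 samples are required")
  if (!(cfg$pOut >= 0 && cfg$pOut < cfg$pIn && cfg$pIn <= 1)) {
    stop("need 0 <= pOut < pIn <= 1")
  }
  if (cfg$exprNoiseSd < 0) stop("exprNoiseSd must be >= 0")
  nLeaves <- cfg$dagBranching^cfg$dagDepth
  if (cfg$nGroups > nLeaves) {
    stop("more groups (", cfg$nGroups, ") than ontology leaves (",
         nLeaves, ")")
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

## Balanced rooted tree-shaped DAG: dagDepth levels below the root, each
## non-leaf term with dagBranching is_a children.
syntheticDag <- function(depth, branching) {
  ids <- "SYN:0001"
  edges <- NULL
  level <- ids
  counter <- 1L
  for (lv in seq_len(depth)) {
    nxt <- character(0)
    for (p in level) {
      for (b in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("SYN:%04d", counter)
        nxt <- c(nxt, id)
        edges <- rbind(edges, data.frame(child = id, parent = p,
                                         relation = "is_a"))
      }
    }
    ids <- c(ids, nxt)
    level <- nxt
  }
  list(dag = GODag(data.frame(id = ids,
                              name = paste("synthetic term", ids),
                              namespace = "biological_process")[
                     , c("id", "name", "namespace")],
                   edges),
       leaves = level)
}

## Bernoulli bipartite/within edges with group-dependent probability.
plantedEdges <- function(idsA, groupsA, idsB, groupsB, pIn, pOut,
                        bipartite) {
  if (bipartite) {
    pairs <- expand.grid(from = idsA, to = idsB, stringsAsFactors = FALSE)
    same <- groupsA[pairs$from] == groupsB[pairs$to]
  } else {
    idx <- which(upper.tri(diag(length(idsA))), arr.ind = TRUE)
    pairs <- data.frame(from = idsA[idx[, 1L]], to = idsA[idx[, 2L]],
                        stringsAsFactors = FALSE)
    same <- groupsA[pairs$from] == groupsA[pairs$to]
  }
  p <- ifelse(same, pIn, pOut)
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

#' Generate a complete synthetic world
#'
#' Builds, from one seed: a balanced ontology; group-specific leaf
#' annotations for proteins (then propagated); circRNA ground truth equal
#' to each group's propagated branch; group-structured expression profiles
#' (latent group profile plus Gaussian noise, so within-group correlation
#' is high); and planted-partition circRNA-protein and protein-protein
#' edges. circRNA truth is withheld from training — proteins are the only
#' training entities, mirroring the annotation-transfer setting.
#'
#' @param cfg a [syntheticConfig()].
#' @return list of class `"SyntheticWorld"` with elements `expr` (matrix),
#'   `circProt` and `ppi` (edge data.frames; `ppi$weight` is a STRING-style
#'   integer score in 500..999), `dag` ([GODag-class]), `annotations`
#'   (propagated protein [AnnotationSet-class]), `truth` (propagated
#'   circRNA [AnnotationSet-class]), `circGroups`, `protGroups`, `config`.
#' @examples
#' world <- makeWorld(syntheticConfig(nGroups = 2, circPerGroup = 3,
#'   protPerGroup = 4, dagDepth = 2, seed = 7))
#' world$dag
#' @export
makeWorld <- function(cfg = syntheticConfig()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  sd <- syntheticDag(cfg$dagDepth, cfg$dagBranching)
  dag <- sd$dag
  leaves <- sd$leaves
  perGroup <- floor(length(leaves) / cfg$nGroups)
  leafSets <- lapply(seq_len(cfg$nGroups), function(g) {
    leaves[((g - 1L) * perGroup + 1L):(g * perGroup)]
  })

  circ <- sprintf("CIRC%04d", seq_len(cfg$nGroups * cfg$circPerGroup))
  prot <- sprintf("PROT%04d", seq_len(cfg$nGroups * cfg$protPerGroup))
  circGroups <- stats::setNames(rep(seq_len(cfg$nGroups),
                                    each = cfg$circPerGroup), circ)
  protGroups <- stats::setNames(rep(seq_len(cfg$nGroups),
                                    each = cfg$protPerGroup), prot)

  protAnn <- propagateAnnotations(
    AnnotationSet(stats::setNames(lapply(prot, function(p) {
      leafSets[[protGroups[[p]]]]
    }), prot)), dag)
  truth <- propagateAnnotations(
    AnnotationSet(stats::setNames(lapply(circ, function(cc) {
      leafSets[[circGroups[[cc]]]]
    }), circ)), dag)

  latent <- matrix(stats::rnorm(cfg$nGroups * cfg$nSamples),
                   nrow = cfg$nGroups)
  expr <- latent[circGroups, , drop = FALSE] +
    matrix(stats::rnorm(length(circ) * cfg$nSamples, sd = cfg$exprNoiseSd),
           nrow = length(circ))
  dimnames(expr) <- list(circ, sprintf("S%02d", seq_len(cfg$nSamples)))

  circProt <- plantedEdges(circ, circGroups, prot, protGroups,
                           cfg$pIn, cfg$pOut, bipartite = TRUE)
  ppi <- plantedEdges(prot, protGroups, NULL, NULL,
                      cfg$pIn, cfg$pOut, bipartite = FALSE)
  ppi$weight <- sample(500:999, nrow(ppi), replace = TRUE)

  structure(list(expr = expr, circProt = circProt, ppi = ppi, dag = dag,
                 annotations = protAnn, truth = truth,
                 circGroups = circGroups, protGroups = protGroups,
                 groupTerms = leafSets, config = cfg),
            class = "SyntheticWorld")
}

#' @export
print.SyntheticWorld <- function(x, ...) {
  cat("SyntheticWorld:", length(x$circGroups), "circRNAs,",
      length(x$protGroups), "proteins,", x$config$nGroups, "groups,",
      length(x$dag), "ontology terms\n")
  invisible(x)
}

#' Randomize PPI endpoints, preserving edge count
#'
#' Draws the same number of protein-protein entries with endpoints
#' resampled uniformly from the protein set: no self-loops, duplicates
#' removed and topped back up to the original count. Original confidence
#' scores are kept (reassigned to the new pairs). This is the degradation
#' control for the multi-source ablation: a network with as many PPI edges
#' but no biological signal in their placement.
#'
#' @param ppi data.frame `from`, `to` (and optional `weight`).
#' @param proteins character vector of protein ids to sample from;
#'   defaults to the proteins present in `ppi`.
#' @param seed integer seed.
#' @return data.frame with the same number of rows as `ppi`.
#' @export
randomizePPI <- function(ppi, proteins = NULL, seed = 1L) {
  if (!nrow(ppi)) stop("empty PPI edge list")
  if (is.null(proteins)) proteins <- unique(c(ppi$from, ppi$to))
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  nWanted <- nrow(ppi)
  maxPairs <- choose(length(proteins), 2)
  if (nWanted > maxPairs) {
    stop("cannot place ", nWanted, " distinct edges among ",
         length(proteins), " proteins")
  }
  set.seed(seed)
  from <- character(0); to <- character(0)
  while (length(from) < nWanted) {
    m <- nWanted - length(from)
    f <- sample(proteins, 2L * m + 10L, replace = TRUE)
    t <- sample(proteins, 2L * m + 10L, replace = TRUE)
    ok <- f != t
    lo <- pmin(f[ok], t[ok]); hi <- pmax(f[ok], t[ok])
    from <- c(from, lo); to <- c(to, hi)
    keep <- !duplicated(paste(from, to))
    from <- from[keep]; to <- to[keep]
    if (length(from) > nWanted) {
      from <- from[seq_len(nWanted)]
      to <- to[seq_len(nWanted)]
    }
  }
  out <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  if (!is.null(ppi$weight)) out$weight <- ppi$weight
  out
}
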