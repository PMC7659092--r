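## Single-letter node-type codes and the edge type implied by an endpoint
## pair. In this network the edge type is a function of the endpoint types:
## circRNA-circRNA pairs are co_expr, protein-protein pairs ppi, mixed pairs
## circ_prot.
typeCode <- c(circRNA = "C", protein = "P")

edgeTypeBetween <- function(a, b) {
  ifelse(a == "C" & b == "C", "co_expr",
  ifelse(a == "P" & b == "P", "ppi", "circ_prot"))
}

#' Uniform random walks over the heterogeneous network
#'
#' Starts `walksPerNode` truncated random walks at every node, each of at
#' most `walkLength` nodes, moving to a uniformly chosen neighbor at each
#' step (edge weights are stored in the network but transitions are
#' unweighted by default for walk generation). A walk stops early at a
#' neighborless node. Fully reproducible given `seed`.
#'
#' @param net a [HetNet-class].
#' @param walksPerNode number of walks started at each node (>= 1).
#' @param walkLength maximum number of nodes per walk (>= 1).
#' @param seed integer RNG seed.
#' @return list of character vectors of node ids.
#' @export
randomWalks <- function(net, walksPerNode = 10, walkLength = 80, seed = 1L) {
  if (walksPerNode < 1 || walkLength < 1) {
    stop("walksPerNode and walkLength must be >= 1")
  }
  nodes <- net@nodes$id
  if (!length(nodes)) stop("empty network")
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes)
  )
  set.seed(seed)
  walks <- vector("list", length(nodes) * walksPerNode)
  w <- 0L
  for (v in nodes) {
    for (r in seq_len(walksPerNode)) {
      w <- w + 1L
      if (walkLength == 1L) {
        walks[[w]] <- v
      } else {
        # igraph counts transitions, not vertices
        vs <- igraph::random_walk(g, start = v, steps = walkLength - 1L,
                                  stuck = "return")
        walks[[w]] <- igraph::as_ids(vs)
      }
    }
  }
  walks
}

#' Extract positive meta-path training tuples from walks
#'
#' For every walk and every ordered position pair (i, j) with
#' `1 <= j - i <= window`, emits the tuple (node_i, node_j, relation),
#' where the relation is the alternating node-type/edge-type sequence of
#' the traversed segment (e.g. `"C-circ_prot-P-ppi-P"`). The meta-path
#' vocabulary indexes the distinct relation strings (sorted, so the index
#' does not depend on walk order).
#'
#' @param walks list of node-id walks from [randomWalks()].
#' @param net the [HetNet-class] the walks were sampled from.
#' @param window maximum hop distance (>= 1).
#' @return list with `tuples` (data.frame `a`, `b`, `z`, `label` = 1) and
#'   `vocabulary` (character vector of relation strings; `z` indexes it).
#' @export
extractTuples <- function(walks, net, window = 2) {
  if (window < 1) stop("window must be >= 1")
  tmap <- stats::setNames(typeCode[net@nodes$type], net@nodes$id)
  aAll <- character(0); bAll <- character(0); rAll <- character(0)
  per <- lapply(walks, function(wk) {
    n <- length(wk)
    if (n < 2L) return(NULL)
    tv <- tmap[wk]
    res <- vector("list", min(window, n - 1L))
    for (g in seq_len(min(window, n - 1L))) {
      m <- n - g
      # relation string: types and edge types along the g-hop segment
      rel <- tv[seq_len(m)]
      for (s in seq_len(g)) {
        t0 <- tv[seq_len(m) + s - 1L]
        t1 <- tv[seq_len(m) + s]
        rel <- paste0(rel, "-", edgeTypeBetween(t0, t1), "-", t1)
      }
      res[[g]] <- data.frame(a = wk[seq_len(m)], b = wk[seq_len(m) + g],
                             rel = rel, stringsAsFactors = FALSE)
    }
    do.call(rbind, res)
  })
  per <- per[!vapply(per, is.null, logical(1))]
  if (!length(per)) {
    return(list(tuples = data.frame(a = character(0), b = character(0),
                                    z = integer(0), label = integer(0)),
                vocabulary = character(0)))
  }
  all <- do.call(rbind, per)
  vocab <- sort(unique(all$rel))
  list(
    tuples = data.frame(a = all$a, b = all$b,
                        z = match(all$rel, vocab), label = 1L,
                        stringsAsFactors = FALSE),
    vocabulary = vocab
  )
}

#' Negative sampling of training tuples
#'
#' For each positive tuple, draws `ratio` negatives by replacing the target
#' node `b` with a node sampled uniformly from the nodes of `b`'s type.
#' A draw colliding with a known positive (same `a`, `b`, `z`) is resampled
#' up to 10 times and then accepted, the standard negative-sampling
#' tolerance. Reproducible given `seed`.
#'
#' @param positives data.frame of positive tuples (`a`, `b`, `z`).
#' @param ratio negatives per positive (>= 0; 0 returns an empty set).
#' @param net the [HetNet-class].
#' @param seed integer RNG seed.
#' @return data.frame of tuples with `label` = 0.
#' @export
negativeSamples <- function(positives, ratio = 5, net, seed = 1L) {
  if (ratio < 0) stop("ratio must be >= 0")
  empty <- data.frame(a = character(0), b = character(0), z = integer(0),
                      label = integer(0))
  if (ratio == 0 || !nrow(positives)) return(empty)
  set.seed(seed)
  tmap <- stats::setNames(typeCode[net@nodes$type], net@nodes$id)
  byType <- split(net@nodes$id, tmap[net@nodes$id])
  single <- names(byType)[vapply(byType, length, integer(1)) == 1L]
  posKey <- paste(positives$a, positives$z, positives$b)

  a <- rep(positives$a, each = ratio)
  z <- rep(positives$z, each = ratio)
  btype <- tmap[rep(positives$b, each = ratio)]
  n <- length(a)
  b <- character(n)
  for (ty in names(byType)) {
    idx <- which(btype == ty)
    if (length(idx)) {
      pool <- byType[[ty]]
      b[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
  }
  if (any(btype %in% single)) {
    warning("node type(s) with a single node: negatives cannot avoid ",
            "the positive pair")
  }
  resampleable <- !(btype %in% single)
  for (try in seq_len(10L)) {
    bad <- which(resampleable & paste(a, z, b) %in% posKey)
    if (!length(bad)) break
    for (ty in unique(btype[bad])) {
      idx <- bad[btype[bad] == ty]
      pool <- byType[[ty]]
      b[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
    }
  }
  data.frame(a = a, b = b, z = z, label = 0L, stringsAsFactors = FALSE)
}

#' Regularization map onto (0, 1)
#'
#' Constrains the relation vector entries to (0, 1) before they bind with
#' the node vectors. The default is the elementwise logistic map (smooth
#' and differentiable); `"clip"` hard-clips into \[eps, 1 - eps\].
#'
#' @param v numeric vector.
#' @param method `"logistic"` (default) or `"clip"`.
#' @return numeric vector with entries in (0, 1).
#' @export
f01 <- function(v, method = c("logistic", "clip")) {
  method <- match.arg(method)
  if (method == "logistic") sigmoid(v) else pmin(pmax(v, 1e-6), 1 - 1e-6)
}

#' Probability that relation z holds between nodes a and b
#'
#' The embedding scorer: the node vectors of `a` and `b` and the
#' (0,1)-regularized relation vector are combined elementwise (Hadamard
#' product), summed, and squashed:
#' `P(z | a, b) = sigmoid( sum_i W_A[a]_i * W_A[b]_i * f01(W_Z[z])_i )`.
#' The two node lookups share one embedding table, so the score is
#' symmetric in `a` and `b`.
#'
#' @param model an [EmbeddingModel-class].
#' @param a,b node ids (or integer row indices).
#' @param z relation string (or integer row index).
#' @return probability in (0, 1).
#' @export
scoreTuple <- function(model, a, b, z) {
  wa <- model@nodes[a, ]
  wb <- model@nodes[b, ]
  wz <- model@relations[z, ]
  if (length(wa) != length(wz)) stop("dimension mismatch")
  sigmoid(sum(wa * wb * f01(wz, model@f01Method)))
}

#' Per-tuple loss and analytic gradients of the embedding objective
#'
#' The training objective is the log-likelihood
#' `R * log P + (1 - R) * log(1 - P)` with
#' `P = sigmoid(sum(wa * wb * f01(wz)))`; this returns the negated
#' per-tuple loss and its gradients with respect to the three vectors,
#' using the logistic `f01`.
#'
#' @param wa,wb node vectors; `wz` the (unregularized) relation vector.
#' @param label 0 or 1.
#' @return list with `loss`, `prob`, and gradients `ga`, `gb`, `gz`.
#' @export
embeddingGradient <- function(wa, wb, wz, label) {
  fz <- sigmoid(wz)
  s <- sum(wa * wb * fz)
  P <- sigmoid(s)
  g <- P - label  # d(-logF)/ds
  list(
    loss = -(label * log(clipProb(P)) + (1 - label) * log(clipProb(1 - P))),
    prob = P,
    ga = g * wb * fz,
    gb = g * wa * fz,
    gz = g * wa * wb * fz * (1 - fz)
  )
}

#' Train node and relation embeddings by SGD
#'
#' Maximizes `sum_T R log P + (1 - R) log(1 - P)` over the training tuples
#' (implemented as minimizing the negated mean) by stochastic gradient
#' descent over shuffled tuples. The two node inputs share a single
#' embedding table. Weights are initialized uniformly in +/- 0.5/d.
#'
#' @param tuples data.frame `a`, `b`, `z`, `label` (positives plus
#'   negatives).
#' @param vocabulary relation vocabulary (from [extractTuples()]).
#' @param net the [HetNet-class] (defines the node set).
#' @param d embedding dimension (>= 2; 64 is the scale at which such
#'   embeddings are typically run).
#' @param epochs passes over the tuples.
#' @param learningRate SGD step size.
#' @param seed integer seed (initialization and shuffling).
#' @param f01Method relation regularization, `"logistic"` or `"clip"`.
#' @return an [EmbeddingModel-class]; per-epoch mean losses in
#'   `trainingHistory()`.
#' @export
trainEmbeddings <- function(tuples, vocabulary, net, d = 64, epochs = 5,
                            learningRate = 0.025, seed = 1L,
                            f01Method = c("logistic", "clip")) {
  f01Method <- match.arg(f01Method)
  if (d < 2) stop("d must be >= 2")
  if (!nrow(tuples)) stop("no training tuples")
  if (!length(vocabulary)) stop("empty relation vocabulary")
  nodes <- net@nodes$id
  ai <- match(tuples$a, nodes)
  bi <- match(tuples$b, nodes)
  if (anyNA(ai) || anyNA(bi)) stop("tuple node absent from the network")
  if (any(tuples$z < 1L | tuples$z > length(vocabulary))) {
    stop("relation index outside the vocabulary")
  }
  set.seed(seed)
  # node/relation vectors live as d x N columns during training so each
  # SGD touch is one contiguous column
  WA <- matrix(stats::runif(length(nodes) * d, -0.5 / d, 0.5 / d),
               nrow = d, ncol = length(nodes))
  WZ <- matrix(stats::runif(length(vocabulary) * d, -0.5 / d, 0.5 / d),
               nrow = d, ncol = length(vocabulary))
  fit <- hin2vec_sgd(WA, WZ, ai - 1L, bi - 1L, tuples$z - 1L,
                     as.integer(tuples$label), as.integer(epochs),
                     as.numeric(learningRate),
                     deriveSeed(seed, "shuffle"),
                     as.integer(f01Method == "clip"))
  fit$nodes <- t(fit$nodes)
  fit$relations <- t(fit$relations)
  rownames(fit$nodes) <- nodes
  rownames(fit$relations) <- vocabulary
  new("EmbeddingModel", nodes = fit$nodes, relations = fit$relations,
      nodeTypes = stats::setNames(net@nodes$type, nodes),
      f01Method = f01Method, history = as.numeric(fit$loss))
}

#' Learn embeddings from a network in one call
#'
#' Orchestrates [randomWalks()], [extractTuples()], [negativeSamples()] and
#' [trainEmbeddings()] with per-stage seeds derived from `seed`.
#'
#' @param net a [HetNet-class].
#' @param d embedding dimension.
#' @param walksPerNode,walkLength walk corpus size parameters.
#' @param window maximum meta-path hop length.
#' @param negRatio negatives per positive tuple.
#' @param epochs,learningRate,f01Method see [trainEmbeddings()].
#' @param seed global seed.
#' @return an [EmbeddingModel-class] with attribute `walkHash` (md5 of the
#'   walk corpus, for provenance).
#' @export
learnEmbeddings <- function(net, d = 64, walksPerNode = 10, walkLength = 80,
                            window = 2, negRatio = 5, epochs = 5,
                            learningRate = 0.025, seed = 1L,
                            f01Method = "logistic") {
  walks <- randomWalks(net, walksPerNode, walkLength,
                       seed = deriveSeed(seed, "walks"))
  pos <- extractTuples(walks, net, window = window)
  neg <- negativeSamples(pos$tuples, ratio = negRatio, net,
                         seed = deriveSeed(seed, "negatives"))
  tuples <- rbind(pos$tuples, neg)
  model <- trainEmbeddings(tuples, pos$vocabulary, net, d = d,
                           epochs = epochs, learningRate = learningRate,
                           seed = deriveSeed(seed, "embed"),
                           f01Method = f01Method)
  attr(model, "walkHash") <- objectHash(walks)
  model
}

#' Within- versus between-group cosine separation of embeddings
#'
#' Diagnostic for planted structure: the difference between the mean
#' cosine similarity of node pairs in the same group and that of pairs in
#' different groups.
#'
#' @param vectors numeric matrix of node vectors (rownames = node ids).
#' @param groups named vector assigning a group to each node id.
#' @return list with `within`, `between` and `gap`.
#' @export
cosineSeparation <- function(vectors, groups) {
  ids <- intersect(rownames(vectors), names(groups))
  v <- vectors[ids, , drop = FALSE]
  nrm <- sqrt(rowSums(v^2))
  nrm[nrm == 0] <- 1
  v <- v / nrm
  cs <- tcrossprod(v)
  same <- outer(groups[ids], groups[ids], "==")
  ut <- upper.tri(cs)
  list(
    within = mean(cs[ut & same]),
    between = mean(cs[ut & !same]),
    gap = mean(cs[ut & same]) - mean(cs[ut & !same])
  )
}
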