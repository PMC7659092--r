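#' Build the binary label matrix
#'
#' Encodes each training entity's propagated term set as a binary marker
#' vector over the classifier vocabulary: entry (e, t) is 1 iff term t is
#' in entity e's set. Rows are ancestor-consistent by construction because
#' the annotations are propagated and the vocabulary is topologically
#' ordered. Entities with no in-vocabulary term are excluded with a
#' warning.
#'
#' @param ann a propagated [AnnotationSet-class].
#' @param vocabulary term vocabulary from [selectTerms()].
#' @return binary matrix, entities x terms.
#' @export
buildLabelMatrix <- function(ann, vocabulary) {
  if (!isTRUE(ann@propagated)) stop("annotations must be propagated first")
  if (!length(vocabulary)) stop("empty vocabulary")
  ok <- vapply(ann@entries, function(ts) any(ts %in% vocabulary), logical(1))
  if (any(!ok)) {
    warning(sum(!ok), " entit(ies) with no in-vocabulary annotation excluded")
  }
  entries <- ann@entries[ok]
  Y <- matrix(0, nrow = length(entries), ncol = length(vocabulary),
              dimnames = list(names(entries), vocabulary))
  for (e in names(entries)) {
    Y[e, intersect(entries[[e]], vocabulary)] <- 1
  }
  Y
}

## Restriction of the DAG's child map to a vocabulary, plus the vocabulary
## in topological order (parents first). `dag` may be a GODag or an
## explicit named list of in-vocabulary children.
vocabChildren <- function(dag, vocabulary) {
  if (is(dag, "GODag")) {
    if (!all(vocabulary %in% dag@terms$id)) {
      stop("vocabulary term(s) absent from the DAG")
    }
    anc <- ancestorIndex(dag)  # closure including self
    # transitive reduction over the vocabulary: v is a child of t iff t is
    # a strict ancestor of v and no other vocabulary descendant of t lies
    # between them
    kids <- stats::setNames(lapply(vocabulary, function(t) {
      desc <- vocabulary[vapply(vocabulary, function(v) {
        v != t && t %in% anc[[v]]
      }, logical(1))]
      keep <- vapply(desc, function(v) {
        !any(vapply(setdiff(desc, v), function(u) u %in% anc[[v]],
                    logical(1)))
      }, logical(1))
      desc[keep]
    }), vocabulary)
  } else {
    kids <- dag[vocabulary]
    names(kids) <- vocabulary
    kids <- lapply(kids, function(x) intersect(x %||% character(0),
                                               vocabulary))
  }
  parents <- stats::setNames(rep(list(character(0)), length(vocabulary)),
                             vocabulary)
  for (p in vocabulary) {
    for (ch in kids[[p]]) parents[[ch]] <- c(parents[[ch]], p)
  }
  ord <- topoSort(vocabulary, parents)
  list(children = kids, topo = ord)
}

#' Max-merge scores over the GO DAG
#'
#' Enforces hierarchical consistency: each term's score is replaced by the
#' maximum over its own score and the merged scores of its children,
#' computed leaves-first, so a merged parent equals the maximum raw score
#' over itself and all its descendants. Leaves are unchanged. Ties between
#' a term's own score and its best child resolve to the term itself (the
#' value is identical either way).
#'
#' @param scores numeric matrix (entities x terms, colnames = term ids) or
#'   a named numeric vector.
#' @param dag a [GODag-class], or a named list giving each vocabulary
#'   term's in-vocabulary children.
#' @return merged scores, same shape as `scores`.
#' @export
maxMerge <- function(scores, dag) {
  vec <- is.null(dim(scores))
  if (vec) scores <- matrix(scores, nrow = 1,
                            dimnames = list(NULL, names(scores)))
  vocab <- colnames(scores)
  vc <- vocabChildren(dag, vocab)
  M <- scores
  for (t in rev(vc$topo)) {
    ch <- vc$children[[t]]
    if (length(ch)) {
      cm <- M[, ch, drop = FALSE]
      cmax <- do.call(pmax, c(asplit(cm, 2), list(M[, t])))
      M[, t] <- cmax
    }
  }
  if (vec) M[1L, ] else M
}

## Glorot-style uniform initialization.
initUniform <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nrow = nin, ncol = nout)
}

## Forward pass. Returns hidden activations, raw sigmoid scores S, merged
## scores M and the max-merge routing (argsrc: 0 = own raw score, else the
## column index of the child whose merged score won).
hierForward <- function(W1, b1, W2, b2, X, childIdx, revTopoIdx,
                        dropMask = NULL) {
  H <- X %*% W1
  H <- sweep(H, 2L, b1, "+")
  H[H < 0] <- 0
  if (!is.null(dropMask)) H <- H * dropMask
  S <- sigmoid(sweep(H %*% W2, 2L, b2, "+"))
  n <- nrow(S); Tn <- ncol(S)
  M <- S
  argsrc <- matrix(0L, n, Tn)
  for (t in revTopoIdx) {
    ch <- childIdx[[t]]
    if (length(ch)) {
      cm <- M[, ch, drop = FALSE]
      j <- max.col(cm, ties.method = "first")
      cmax <- cm[cbind(seq_len(n), j)]
      sel <- S[, t] >= cmax
      M[, t] <- ifelse(sel, S[, t], cmax)
      argsrc[, t] <- ifelse(sel, 0L, ch[j])
    }
  }
  list(H = H, S = S, M = M, argsrc = argsrc)
}

## Backward pass of mean binary cross-entropy on merged scores.
hierBackward <- function(fw, X, Y, W2, childIdx, topoIdx, dropMask = NULL) {
  n <- nrow(Y); Tn <- ncol(Y)
  Mc <- clipProb(fw$M, 1e-7)
  gM <- (Mc - Y) / (Mc * (1 - Mc)) / (n * Tn)
  # route gradients through the max-merge subgradient, parents first
  acc <- gM
  gS <- matrix(0, n, Tn)
  for (t in topoIdx) {
    self <- fw$argsrc[, t] == 0L
    if (any(self)) gS[self, t] <- gS[self, t] + acc[self, t]
    if (any(!self)) {
      rows <- which(!self)
      idx <- cbind(rows, fw$argsrc[rows, t])
      acc[idx] <- acc[idx] + acc[rows, t]
    }
  }
  dPre2 <- gS * fw$S * (1 - fw$S)
  gW2 <- crossprod(fw$H, dPre2)
  gb2 <- colSums(dPre2)
  dH <- tcrossprod(dPre2, W2)
  if (!is.null(dropMask)) dH <- dH * dropMask
  dH[fw$H <= 0] <- 0
  gW1 <- crossprod(X, dH)
  gb1 <- colSums(dH)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

bceLoss <- function(M, Y) {
  Mc <- clipProb(M, 1e-7)
  -mean(Y * log(Mc) + (1 - Y) * log(1 - Mc))
}

#' Train the hierarchical multi-label classifier
#'
#' Fits a shared fully connected rectifier layer followed by one sigmoid
#' head per GO term and a max-merge layer over the DAG restriction of the
#' vocabulary. The loss is the mean of independent per-term binary
#' cross-entropies on the post-merge scores (the targets are binary marker
#' vectors, so the multi-label reading of "cross entropy" applies), so the
#' merge layer participates in backpropagation through the subgradient of
#' the max. Optimized with RMSProp over shuffled mini-batches; weights are
#' initialized from a uniform distribution. If `validationFraction > 0`, a
#' held-out split drives early stopping on a validation-loss plateau.
#'
#' @param features numeric matrix, entities x d (embedding vectors).
#' @param labels binary label matrix from [buildLabelMatrix()], rows
#'   aligned with `features`.
#' @param dag a [GODag-class] (or explicit child map) restricted to the
#'   label vocabulary.
#' @param hidden shared-layer width.
#' @param batchSize mini-batch size.
#' @param learningRate RMSProp step size.
#' @param dropout dropout rate on the shared layer during training.
#' @param epochs maximum training epochs.
#' @param validationFraction fraction of entities held out for early
#'   stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @param preMergeLoss compute the loss on pre-merge scores instead
#'   (merge then applied only at prediction time).
#' @param seed integer seed (initialization, shuffling, dropout).
#' @return a [HierModel-class].
#' @export
trainHierModel <- function(features, labels, dag, hidden = 256,
                           batchSize = 64, learningRate = 0.01,
                           dropout = 0.2, epochs = 150,
                           validationFraction = 0, patience = 20,
                           preMergeLoss = FALSE, seed = 1L) {
  if (nrow(features) != nrow(labels)) {
    stop("features and labels are misaligned")
  }
  if (!is.null(rownames(features)) && !is.null(rownames(labels)) &&
      !identical(rownames(features), rownames(labels))) {
    stop("features and labels are misaligned (row names differ)")
  }
  vocab <- colnames(labels)
  vc <- vocabChildren(dag, vocab)
  childIdx <- lapply(vc$children, function(ch) match(ch, vocab))
  topoIdx <- match(vc$topo, vocab)
  revTopoIdx <- rev(topoIdx)
  d <- ncol(features); Tn <- length(vocab)

  set.seed(seed)
  W1 <- initUniform(d, hidden); b1 <- rep(0, hidden)
  W2 <- initUniform(hidden, Tn); b2 <- rep(0, Tn)
  cache <- list(W1 = W1 * 0, b1 = b1 * 0, W2 = W2 * 0, b2 = b2 * 0)
  decay <- 0.9; eps <- 1e-8

  n <- nrow(features)
  valIdx <- integer(0)
  if (validationFraction > 0) {
    nVal <- max(1L, floor(n * validationFraction))
    valIdx <- sample.int(n, nVal)
  }
  trainIdx <- setdiff(seq_len(n), valIdx)
  Xtr <- features[trainIdx, , drop = FALSE]
  Ytr <- labels[trainIdx, , drop = FALSE]

  evalLoss <- function(X, Y) {
    fw <- hierForward(W1, b1, W2, b2, X, childIdx, revTopoIdx)
    bceLoss(if (preMergeLoss) fw$S else fw$M, Y)
  }

  hist <- data.frame(epoch = integer(0), loss = numeric(0),
                     valLoss = numeric(0))
  best <- Inf; bestW <- NULL; wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    for (start in seq(1L, nrow(Xtr), by = batchSize)) {
      bi <- ord[start:min(start + batchSize - 1L, nrow(Xtr))]
      X <- Xtr[bi, , drop = FALSE]
      Y <- Ytr[bi, , drop = FALSE]
      mask <- NULL
      if (dropout > 0) {
        mask <- matrix(stats::rbinom(length(bi) * hidden, 1L, 1 - dropout),
                       length(bi), hidden) / (1 - dropout)
      }
      fw <- hierForward(W1, b1, W2, b2, X, childIdx, revTopoIdx, mask)
      if (preMergeLoss) {
        fw$M <- fw$S
        fw$argsrc <- matrix(0L, nrow(fw$S), ncol(fw$S))
      }
      gr <- hierBackward(fw, X, Y, W2, childIdx, topoIdx, mask)
      for (nm in names(gr)) {
        g <- gr[[nm]]
        cache[[nm]] <- decay * cache[[nm]] + (1 - decay) * g^2
        step <- learningRate * g / (sqrt(cache[[nm]]) + eps)
        if (nm == "W1") W1 <- W1 - step
        else if (nm == "b1") b1 <- b1 - step
        else if (nm == "W2") W2 <- W2 - step
        else b2 <- b2 - step
      }
    }
    trLoss <- evalLoss(Xtr, Ytr)
    if (!is.finite(trLoss)) stop("non-finite training loss at epoch ", ep)
    vl <- NA_real_
    if (length(valIdx)) {
      vl <- evalLoss(features[valIdx, , drop = FALSE],
                     labels[valIdx, , drop = FALSE])
      if (vl < best - 1e-6) {
        best <- vl; wait <- 0L
        bestW <- list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
      } else {
        wait <- wait + 1L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, loss = trLoss, valLoss = vl))
    if (length(valIdx) && wait >= patience) break
  }
  if (!is.null(bestW)) {
    W1 <- bestW$W1; b1 <- bestW$b1; W2 <- bestW$W2; b2 <- bestW$b2
  }
  new("HierModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
      vocabulary = vocab, children = vc$children, dropout = dropout,
      hyper = list(hidden = hidden, batchSize = batchSize,
                   learningRate = learningRate, epochs = epochs,
                   preMergeLoss = preMergeLoss, seed = seed),
      history = hist)
}

#' Score entities with a trained hierarchical model
#'
#' Deterministic forward pass (dropout inactive) followed by max-merge, so
#' returned scores are DAG-consistent: a parent's score is at least each
#' child's.
#'
#' @param model a [HierModel-class].
#' @param features numeric matrix, entities x d, rownames = entity ids.
#' @return score matrix in (0, 1), entities x vocabulary.
#' @export
predictScores <- function(model, features) {
  if (ncol(features) != nrow(model@W1)) stop("feature dimension mismatch")
  vocab <- model@vocabulary
  childIdx <- lapply(model@children, function(ch) match(ch, vocab))
  parents <- stats::setNames(rep(list(character(0)), length(vocab)), vocab)
  for (p in vocab) for (ch in model@children[[p]]) {
    parents[[ch]] <- c(parents[[ch]], p)
  }
  revTopoIdx <- rev(match(topoSort(vocab, parents), vocab))
  fw <- hierForward(model@W1, model@b1, model@W2, model@b2, features,
                    childIdx, revTopoIdx)
  dimnames(fw$M) <- list(rownames(features), vocab)
  fw$M
}

#' k-fold cross-validation of the classifier
#'
#' Deterministically partitions the entities into `folds` folds, trains on
#' the complement of each fold and evaluates on the held-out fold,
#' reporting the validation loss and the Fmax of the threshold-swept
#' precision/recall protocol.
#'
#' @param features,labels,dag as in [trainHierModel()].
#' @param folds number of folds (>= 2; 5 is conventional).
#' @param seed fold-assignment and training seed.
#' @param ... further arguments to [trainHierModel()].
#' @return list with `perFold` (data.frame fold/loss/fmax) and `summary`
#'   (means and standard deviations).
#' @export
crossValidate <- function(features, labels, dag, folds = 5, seed = 1L, ...) {
  if (folds < 2) stop("folds must be >= 2")
  n <- nrow(features)
  if (n < folds) stop("need at least `folds` entities")
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), n))
  truth <- AnnotationSet(
    stats::setNames(lapply(seq_len(n), function(i) {
      colnames(labels)[labels[i, ] == 1]
    }), rownames(labels)),
    propagated = TRUE
  )
  if (is(dag, "GODag")) truth <- propagateAnnotations(truth, dag)
  res <- lapply(seq_len(folds), function(f) {
    tr <- which(assign != f); te <- which(assign == f)
    m <- trainHierModel(features[tr, , drop = FALSE],
                        labels[tr, , drop = FALSE], dag,
                        seed = deriveSeed(seed, paste0("fold", f)), ...)
    sc <- predictScores(m, features[te, , drop = FALSE])
    loss <- bceLoss(sc, labels[te, , drop = FALSE])
    fm <- if (is(dag, "GODag")) {
      cv <- evaluationCurve(sc, truth, dag)
      fmax(cv)$fmax
    } else NA_real_
    data.frame(fold = f, loss = loss, fmax = fm)
  })
  perFold <- do.call(rbind, res)
  list(perFold = perFold,
       folds = stats::setNames(lapply(seq_len(folds),
                                      function(f) which(assign == f)),
                               paste0("fold", seq_len(folds))),
       summary = data.frame(
         meanLoss = mean(perFold$loss), sdLoss = stats::sd(perFold$loss),
         meanFmax = mean(perFold$fmax), sdFmax = stats::sd(perFold$fmax)))
}
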