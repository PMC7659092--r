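#' Ancestor-closed prediction set at a threshold
#'
#' Collects the terms scored at or above `k` together with all their
#' `is_a`/`part_of` ancestors, then removes the namespace root (a root
#' prediction is uninformative and would inflate precision).
#'
#' @param scores named numeric vector of term scores in \[0, 1\].
#' @param k threshold in \[0, 1\].
#' @param dag a [GODag-class].
#' @return character vector of term ids (possibly empty).
#' @export
predictionSet <- function(scores, k, dag) {
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1) {
    stop("k must lie in [0, 1]")
  }
  sel <- names(scores)[scores >= k]
  if (!length(sel)) return(character(0))
  anc <- unique(unlist(lapply(sel, goAncestors, dag = dag),
                       use.names = FALSE))
  setdiff(union(sel, anc), dag@roots)
}

#' Per-entity precision and recall
#'
#' `precision = |Pc n V| / |Pc|` (NA when the prediction set is empty: the
#' entity is then not counted in the precision population h(k)),
#' `recall = |Pc n V| / |V|`.
#'
#' @param predicted character vector: the prediction set Pc.
#' @param truth character vector: the verified (ancestor-closed) set V;
#'   must be non-empty.
#' @return named numeric `c(precision = , recall = )`.
#' @export
precisionRecall <- function(predicted, truth) {
  if (!length(truth)) stop("empty truth set")
  hit <- length(intersect(predicted, truth))
  c(precision = if (length(predicted)) hit / length(predicted) else NA_real_,
    recall = hit / length(truth))
}

#' Threshold-swept precision/recall/F curve
#'
#' For each threshold k on the grid, prediction sets are formed per entity
#' ([predictionSet()]); precision is averaged over the h(k) entities with a
#' non-empty prediction set, recall over all N entities (an entity with an
#' empty prediction set contributes recall 0), and F is the harmonic mean.
#' Truth sets are ancestor-closed and root-stripped symmetrically with the
#' predictions; entities whose truth set is empty after root removal are
#' skipped with a warning.
#'
#' @param scores numeric matrix, entities x terms (dimnames required).
#' @param truth a propagated [AnnotationSet-class] of verified terms.
#' @param dag a [GODag-class].
#' @param thresholds grid of thresholds in \[0, 1\]; the default is the
#'   101-point grid 0, 0.01, ..., 1.
#' @return data.frame with columns `k`, `precision`, `recall`, `f`, `h`;
#'   precision (and f) are NA where h(k) = 0. Attribute `N` holds the
#'   number of evaluated entities.
#' @export
evaluationCurve <- function(scores, truth, dag,
                            thresholds = seq(0, 1, by = 0.01)) {
  if (!isTRUE(truth@propagated)) stop("truth annotations must be propagated")
  if (any(thresholds < 0 | thresholds > 1)) {
    stop("thresholds must lie in [0, 1]")
  }
  thresholds <- sort(thresholds)
  ents <- intersect(rownames(scores), names(truth@entries))
  V <- lapply(truth@entries[ents], function(v) setdiff(v, dag@roots))
  empty <- vapply(V, length, integer(1)) == 0L
  if (any(empty)) {
    warning(sum(empty), " entit(ies) with empty verified set skipped")
  }
  ents <- ents[!empty]
  V <- V[!empty]
  N <- length(ents)
  if (!N) stop("no entities with verified annotations to evaluate")

  if (!all(colnames(scores) %in% dag@terms$id)) {
    stop("scored term(s) absent from the DAG")
  }
  # precompute each entity's scored terms with their ancestor closures
  anc <- ancestorIndex(dag)
  rows <- lapply(ents, function(e) {
    s <- scores[e, ]
    s <- s[!is.na(s)]
    list(score = s, closure = lapply(names(s), function(t) {
      setdiff(anc[[t]], dag@roots)
    }))
  })
  names(rows) <- ents

  out <- data.frame(k = thresholds, precision = NA_real_,
                    recall = NA_real_, f = NA_real_, h = NA_integer_)
  for (i in seq_along(thresholds)) {
    k <- thresholds[i]
    prc <- numeric(0)
    rec <- numeric(N)
    for (j in seq_len(N)) {
      r <- rows[[j]]
      on <- r$score >= k
      pc <- if (any(on)) {
        unique(unlist(r$closure[on], use.names = FALSE))
      } else character(0)
      if (length(pc)) {
        hit <- length(intersect(pc, V[[j]]))
        prc <- c(prc, hit / length(pc))
        rec[j] <- hit / length(V[[j]])
      } else {
        rec[j] <- 0
      }
    }
    h <- length(prc)
    out$h[i] <- h
    out$recall[i] <- mean(rec)
    if (h > 0) {
      out$precision[i] <- mean(prc)
      pr <- out$precision[i] + out$recall[i]
      out$f[i] <- if (pr > 0) 2 * out$precision[i] * out$recall[i] / pr else 0
    }
  }
  attr(out, "N") <- N
  out
}

#' Maximum F-measure over the threshold grid
#'
#' @param curve a curve from [evaluationCurve()].
#' @return list with `fmax` and the `threshold` attaining it (ties broken
#'   toward the smaller threshold).
#' @export
fmax <- function(curve) {
  ok <- which(!is.na(curve$f))
  if (!length(ok)) stop("no threshold with a defined F-measure")
  best <- ok[which.max(curve$f[ok])]
  list(fmax = curve$f[best], threshold = curve$k[best])
}

#' Number of correctly annotated entities
#'
#' Counts the entities whose prediction set at threshold `k` shares at
#' least one term with their verified set. By default `k` is the
#' Fmax-optimal threshold of the corresponding curve.
#'
#' @inheritParams evaluationCurve
#' @param k threshold; `NULL` (default) uses the Fmax-optimal one.
#' @return integer count.
#' @export
coverage <- function(scores, truth, dag, k = NULL,
                     thresholds = seq(0, 1, by = 0.01)) {
  if (is.null(k)) {
    k <- fmax(evaluationCurve(scores, truth, dag, thresholds))$threshold
  }
  ents <- intersect(rownames(scores), names(truth@entries))
  n <- 0L
  for (e in ents) {
    v <- setdiff(truth@entries[[e]], dag@roots)
    if (!length(v)) next
    s <- scores[e, ]
    pc <- predictionSet(s[!is.na(s)], k, dag)
    if (length(intersect(pc, v))) n <- n + 1L
  }
  n
}

#' Plot a precision-recall curve
#'
#' @param curve a curve from [evaluationCurve()] (or a list of named
#'   curves to overlay).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the curve(s).
#' @export
plotPRCurve <- function(curve, ...) {
  curves <- if (is.data.frame(curve)) list(curve = curve) else curve
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision", ...)
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    ok <- !is.na(cv$precision)
    graphics::lines(cv$recall[ok], cv$precision[ok], col = i, lwd = 2)
  }
  if (length(curves) > 1L) {
    graphics::legend("topright", legend = names(curves),
                     col = seq_along(curves), lwd = 2, bty = "n")
  }
  invisible(curve)
}
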