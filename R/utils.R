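#' Logistic sigmoid
#'
#' @param x numeric vector.
#' @return `1 / (1 + exp(-x))`, elementwise.
#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage-specific seed from a global seed
#'
#' One global seed deterministically derives per-stage seeds so that each
#' pipeline stage is individually reproducible. The derived value is always a
#' valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483629)
}

## Kahn topological sort, parents before children. `parents` is a named list
## mapping each id to its parent ids (restricted to `ids`). Deterministic:
## ties broken by the lexicographic order of ids. Errors on cycles, naming a
## member of one cycle.
topoSort <- function(ids, parents) {
  ids <- sort(ids)
  indeg <- vapply(ids, function(i) {
    length(intersect(parents[[i]], ids))
  }, integer(1))
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (i in ids) {
    for (p in intersect(parents[[i]], ids)) {
      children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    queue <- sort(queue)
    v <- queue[1L]
    queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(ids)) {
    bad <- setdiff(ids, out)
    stop("cycle detected in parent relation (involves term '", bad[1L], "')")
  }
  out
}

## md5 of an arbitrary R object, via a temporary serialization file.
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

## Clip probabilities away from {0,1} before taking logs.
clipProb <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)
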