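## Shared fixtures: tiny ontologies, networks and brute-force oracles.

chainDag <- function() {
  # t3 is_a t2 is_a t1 (t1 is the root)
  GODag(c("t1", "t2", "t3"),
        data.frame(child = c("t2", "t3"), parent = c("t1", "t2"),
                   relation = "is_a"))
}

diamondDag <- function() {
  # t4 is_a {t2, t3}; t2, t3 is_a t1
  GODag(c("t1", "t2", "t3", "t4"),
        data.frame(child = c("t2", "t3", "t4", "t4"),
                   parent = c("t1", "t1", "t2", "t3"),
                   relation = "is_a"))
}

## Random single-rooted DAG: term i >= 2 draws 1-2 parents among earlier
## terms, so acyclicity holds by construction.
randomDag <- function(nTerms, seed) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(nTerms))
  edges <- do.call(rbind, lapply(seq_len(nTerms)[-1L], function(i) {
    np <- sample.int(min(2L, i - 1L), 1L)
    data.frame(child = ids[i],
               parent = sample(ids[seq_len(i - 1L)], np),
               relation = sample(c("is_a", "part_of"), np, replace = TRUE))
  }))
  GODag(ids, edges)
}

randomAnnotations <- function(dag, nEntities, seed) {
  set.seed(seed)
  ids <- goTermIds(dag)
  AnnotationSet(stats::setNames(lapply(seq_len(nEntities), function(i) {
    sample(ids, sample.int(min(3L, length(ids)), 1L))
  }), sprintf("e%02d", seq_len(nEntities))))
}

## Tiny typed network: 2 circRNAs, 2 proteins, all three edge layers.
tinyNet <- function() {
  HetNet(
    data.frame(id = c("c1", "c2", "p1", "p2"),
               type = c("circRNA", "circRNA", "protein", "protein")),
    data.frame(from = c("c1", "c1", "c2", "p1"),
               to = c("c2", "p1", "p2", "p2"),
               type = c("co_expr", "circ_prot", "circ_prot", "ppi"),
               weight = c(0.9, 1, 1, 0.8))
  )
}

triangleNet <- function() {
  HetNet(data.frame(id = c("a", "b", "c"), type = "protein"),
         data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                    type = "ppi", weight = 1))
}

tinyWorld <- function(seed = 11) {
  makeWorld(syntheticConfig(nGroups = 2, circPerGroup = 5,
                            protPerGroup = 8, nSamples = 6, dagDepth = 2,
                            seed = seed))
}

## Brute-force oracle for max-merge: each term's merged score is the
## maximum raw score over itself and every descendant.
bruteDescendantMax <- function(raw, dag) {
  vocab <- colnames(raw)
  out <- raw
  for (t in vocab) {
    desc <- vocab[vapply(vocab, function(v) {
      v == t || t %in% goAncestors(dag, v)
    }, logical(1))]
    out[, t] <- apply(raw[, desc, drop = FALSE], 1L, max)
  }
  out
}

## Brute-force evaluation curve that materializes every prediction set
## explicitly through predictionSet() and averages per the protocol.
bruteCurve <- function(scores, truth, dag, thresholds) {
  ents <- intersect(rownames(scores), names(annotations(truth)))
  V <- lapply(annotations(truth)[ents],
              function(v) setdiff(v, goRoots(dag)))
  keep <- vapply(V, length, integer(1)) > 0L
  ents <- ents[keep]; V <- V[keep]
  do.call(rbind, lapply(thresholds, function(k) {
    prc <- c(); rec <- c()
    for (e in ents) {
      pc <- predictionSet(scores[e, ], k, dag)
      hit <- length(intersect(pc, V[[e]]))
      if (length(pc)) prc <- c(prc, hit / length(pc))
      rec <- c(rec, if (length(pc)) hit / length(V[[e]]) else 0)
    }
    p <- if (length(prc)) mean(prc) else NA_real_
    r <- mean(rec)
    f <- if (is.na(p)) NA_real_ else if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(k = k, precision = p, recall = r, f = f, h = length(prc))
  }))
}

## OBO snippet used across ontology tests.
writeTestOBO <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}
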