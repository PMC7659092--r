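## Zero-weight model over a given vocabulary/child map, for forward-pass
## contracts.
zeroModel <- function(vocab, children, d = 4, h = 3) {
  new("HierModel", W1 = matrix(0, d, h), b1 = rep(0, h),
      W2 = matrix(0, h, length(vocab)), b2 = rep(0, length(vocab)),
      vocabulary = vocab, children = children, dropout = 0,
      hyper = list(), history = data.frame())
}

test_that("buildLabelMatrix encodes propagated sets over the vocabulary", {
  dag <- chainDag()
  ann <- propagateAnnotations(
    AnnotationSet(list(e1 = "t2", e2 = "t3", e3 = "t1")), dag)
  vocab <- c("t2", "t3")  # root t1 excluded
  expect_warning(Y <- buildLabelMatrix(ann, vocab), "no in-vocabulary")
  expect_equal(Y["e1", ], c(t2 = 1, t3 = 0))
  expect_equal(Y["e2", ], c(t2 = 1, t3 = 1))
  expect_false("e3" %in% rownames(Y))  # only annotated with the root
  expect_error(buildLabelMatrix(AnnotationSet(list(e = "t2")), vocab),
               "propagated")
})

test_that("label rows are ancestor-consistent within the vocabulary", {
  for (seed in 1:3) {
    dag <- randomDag(10, seed)
    ann <- propagateAnnotations(randomAnnotations(dag, 8, seed), dag)
    vocab <- selectTerms(ann, dag, minCount = 1)
    Y <- suppressWarnings(buildLabelMatrix(ann, vocab))
    for (e in rownames(Y)) {
      on <- colnames(Y)[Y[e, ] == 1]
      for (t in on) {
        expect_true(all(intersect(goAncestors(dag, t), vocab) %in% on))
      }
    }
  }
})

test_that("zero-weight forward pass scores 0.5 everywhere", {
  m <- zeroModel(c("t2", "t3"), list(t2 = "t3", t3 = character(0)))
  X <- matrix(rnorm(8), 2, 4, dimnames = list(c("e1", "e2"), NULL))
  S <- predictScores(m, X)
  expect_equal(dim(S), c(2L, 2L))
  expect_true(all(S == 0.5))
  # eval-mode forward is deterministic (dropout inactive)
  expect_identical(S, predictScores(m, X))
  expect_error(predictScores(m, X[, 1:2]), "dimension")
})

test_that("maxMerge propagates child maxima up the DAG", {
  # chain: t2 below t1
  ch <- list(t1 = "t2", t2 = character(0))
  expect_equal(maxMerge(c(t1 = 0.2, t2 = 0.7), ch),
               c(t1 = 0.7, t2 = 0.7))
  ch3 <- list(p = c("c1", "c2"), c1 = character(0), c2 = character(0))
  expect_equal(maxMerge(c(p = 0.9, c1 = 0.1, c2 = 0.3), ch3),
               c(p = 0.9, c1 = 0.1, c2 = 0.3))
  # diamond via a GODag
  raw <- c(t1 = 0.1, t2 = 0.5, t3 = 0.2, t4 = 0.8)
  expect_equal(maxMerge(raw, diamondDag()),
               c(t1 = 0.8, t2 = 0.8, t3 = 0.8, t4 = 0.8))
})

test_that("maxMerge is idempotent and equals the descendant-max oracle", {
  for (seed in 1:20) {
    dag <- randomDag(sample(5:20, 1), seed)
    vocab <- setdiff(goTermIds(dag), goRoots(dag))
    raw <- matrix(runif(3 * length(vocab)), 3, length(vocab),
                  dimnames = list(paste0("e", 1:3), vocab))
    merged <- maxMerge(raw, dag)
    expect_identical(maxMerge(merged, dag), merged)
    expect_equal(merged, bruteDescendantMax(raw, dag))
  }
})

test_that("training separates a two-group fixture to low loss", {
  # 6-term DAG: root with two branches of two leaves each
  dag <- GODag(c("rt", "a", "b", "a1", "a2", "b1"),
               data.frame(child = c("a", "b", "a1", "a2", "b1"),
                          parent = c("rt", "rt", "a", "a", "b"),
                          relation = "is_a"))
  set.seed(1)
  n <- 40; d <- 16
  grp <- rep(1:2, each = n / 2)
  centers <- matrix(rnorm(2 * d, sd = 2), 2, d)
  X <- centers[grp, ] + matrix(rnorm(n * d, sd = 0.3), n, d)
  rownames(X) <- sprintf("p%02d", 1:n)
  ann <- propagateAnnotations(AnnotationSet(stats::setNames(lapply(grp,
    function(g) if (g == 1) c("a1", "a2") else "b1"), rownames(X))), dag)
  vocab <- selectTerms(ann, dag, minCount = 1)
  Y <- buildLabelMatrix(ann, vocab)
  m <- trainHierModel(X, Y, dag, hidden = 32, epochs = 200, seed = 1)
  expect_lt(utils::tail(trainingHistory(m)$loss, 1), 0.1)
  # and the predictions are hierarchically consistent
  S <- predictScores(m, X)
  expect_true(all(S[, "a"] >= S[, "a1"] & S[, "a"] >= S[, "a2"]))
  expect_true(all(S[, "b"] >= S[, "b1"]))
})

test_that("a zero learning rate leaves the weights unchanged", {
  dag <- chainDag()
  X <- matrix(rnorm(12), 3, 4, dimnames = list(paste0("e", 1:3), NULL))
  Y <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2,
              dimnames = list(rownames(X), c("t2", "t3")))
  m0 <- trainHierModel(X, Y, dag, hidden = 5, epochs = 0, dropout = 0,
                       seed = 9)
  m1 <- trainHierModel(X, Y, dag, hidden = 5, epochs = 3, dropout = 0,
                       learningRate = 0, seed = 9)
  expect_identical(m0@W1, m1@W1)
  expect_identical(m0@W2, m1@W2)
})

test_that("training detects misaligned inputs", {
  dag <- chainDag()
  X <- matrix(rnorm(12), 3, 4)
  Y <- matrix(1, 2, 2, dimnames = list(NULL, c("t2", "t3")))
  expect_error(trainHierModel(X, Y, dag), "misaligned")
})

test_that("entity order does not materially change the converged loss", {
  dag <- chainDag()
  set.seed(2)
  X <- matrix(rnorm(30 * 6), 30, 6, dimnames = list(sprintf("e%02d", 1:30),
                                                    NULL))
  Y <- matrix(rbinom(60, 1, 0.5), 30, 2,
              dimnames = list(rownames(X), c("t2", "t3")))
  Y[, "t2"] <- pmax(Y[, "t2"], Y[, "t3"])  # ancestor-consistent
  m1 <- trainHierModel(X, Y, dag, hidden = 16, epochs = 80, dropout = 0,
                       seed = 4)
  prm <- sample(30)
  m2 <- trainHierModel(X[prm, ], Y[prm, ], dag, hidden = 16, epochs = 80,
                       dropout = 0, seed = 4)
  l1 <- utils::tail(trainingHistory(m1)$loss, 1)
  l2 <- utils::tail(trainingHistory(m2)$loss, 1)
  expect_lt(abs(l1 - l2) / l1, 0.10)
})

test_that("cross-validation partitions entities deterministically", {
  dag <- chainDag()
  set.seed(3)
  X <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(sprintf("e%03d", 1:100), NULL))
  Y <- cbind(t2 = 1, t3 = rbinom(100, 1, 0.5))
  rownames(Y) <- rownames(X)
  cv <- crossValidate(X, Y, dag, folds = 5, seed = 1, hidden = 4,
                      epochs = 3, dropout = 0)
  sizes <- vapply(cv$folds, length, integer(1))
  expect_equal(unname(sizes), rep(20L, 5L))
  expect_equal(sort(unname(unlist(cv$folds))), 1:100)
  cv2 <- crossValidate(X, Y, dag, folds = 5, seed = 1, hidden = 4,
                       epochs = 3, dropout = 0)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(nrow(cv$perFold), 5L)
  expect_true(all(is.finite(cv$perFold$loss)))
  # remainder handling and the folds guard
  cv3 <- crossValidate(X[1:3, ], Y[1:3, ], dag, folds = 2, seed = 1,
                       hidden = 4, epochs = 2, dropout = 0)
  expect_setequal(vapply(cv3$folds, length, integer(1)), c(2L, 1L))
  expect_error(crossValidate(X, Y, dag, folds = 1), "folds")
})
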