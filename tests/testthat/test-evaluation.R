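## Two-entity worked example used throughout: a 3-term ontology (root r,
## leaves t1, t2), entity j1 predicts both leaves but is verified only for
## t1; entity j2 predicts nothing above threshold and is verified for t2.
workedExample <- function() {
  dag <- GODag(c("r", "t1", "t2"),
               data.frame(child = c("t1", "t2"), parent = "r",
                          relation = "is_a"))
  scores <- rbind(j1 = c(t1 = 0.9, t2 = 0.9), j2 = c(t1 = 0, t2 = 0.1))
  truth <- propagateAnnotations(
    AnnotationSet(list(j1 = "t1", j2 = "t2")), dag)
  list(dag = dag, scores = scores, truth = truth)
}

test_that("predictionSet closes under ancestors and drops the root", {
  dag <- chainDag()
  expect_setequal(predictionSet(c(t3 = 0.9), 0.5, dag), c("t3", "t2"))
  expect_setequal(predictionSet(c(t2 = 0.2, t3 = 0.9), 0, dag),
                  c("t2", "t3"))
  expect_identical(predictionSet(c(t2 = 0.2, t3 = 0.3), 0.5, dag),
                   character(0))
  expect_error(predictionSet(c(t3 = 0.9), 1.5, dag), "\\[0, 1\\]")
  expect_error(predictionSet(c(t3 = 0.9), -0.1, dag), "\\[0, 1\\]")
})

test_that("prediction sets are ancestor-closed for random score vectors", {
  for (seed in 1:10) {
    dag <- randomDag(12, seed)
    set.seed(seed + 500)
    terms <- setdiff(goTermIds(dag), goRoots(dag))
    sc <- stats::setNames(runif(length(terms)), terms)
    for (k in c(0, 0.3, 0.7, 1)) {
      pc <- predictionSet(sc, k, dag)
      expect_false(any(goRoots(dag) %in% pc))
      for (t in pc) {
        expect_true(all(setdiff(goAncestors(dag, t), goRoots(dag)) %in% pc))
      }
    }
  }
})

test_that("per-entity precision and recall count term overlaps", {
  expect_equal(precisionRecall(c("t1", "t2"), "t1"),
               c(precision = 0.5, recall = 1))
  expect_equal(precisionRecall(c("t1", "t2"), c("t1", "t2")),
               c(precision = 1, recall = 1))
  expect_equal(precisionRecall(c("a", "b", "c"), c("x", "y")),
               c(precision = 0, recall = 0))
  expect_true(is.na(precisionRecall(character(0), "t1")["precision"]))
  expect_error(precisionRecall("t1", character(0)), "empty truth")
})

test_that("the worked two-entity example evaluates to 0.5 exactly", {
  ex <- workedExample()
  curve <- evaluationCurve(ex$scores, ex$truth, ex$dag, thresholds = 0.5)
  expect_identical(curve$h, 1L)     # only j1 predicts anything
  expect_identical(curve$precision, 0.5)
  expect_identical(curve$recall, 0.5)
  expect_identical(curve$f, 0.5)
  expect_identical(attr(curve, "N"), 2L)
  expect_identical(fmax(curve)$fmax, 0.5)
})

test_that("curves have one row per threshold and honor the grid", {
  ex <- workedExample()
  curve <- evaluationCurve(ex$scores, ex$truth, ex$dag,
                           thresholds = c(0, 0.5, 1))
  expect_equal(nrow(curve), 3L)
  expect_equal(curve$k, c(0, 0.5, 1))
  expect_error(
    evaluationCurve(ex$scores, ex$truth, ex$dag, thresholds = c(-0.1, 0.5)),
    "\\[0, 1\\]")
})

test_that("perfect predictions give unit precision, recall and coverage", {
  dag <- chainDag()
  truth <- propagateAnnotations(
    AnnotationSet(list(e1 = "t3", e2 = "t2")), dag)
  scores <- rbind(e1 = c(t2 = 1, t3 = 1), e2 = c(t2 = 1, t3 = 0))
  curve <- evaluationCurve(scores, truth, dag, thresholds = c(0.5, 1))
  expect_equal(curve$precision, c(1, 1))
  expect_equal(curve$recall, c(1, 1))
  expect_equal(curve$f, c(1, 1))
  expect_equal(coverage(scores, truth, dag, k = 0.5), 2L)
})

test_that("fmax takes the grid maximum, ties toward the smaller k", {
  curve <- data.frame(k = c(0.1, 0.2, 0.3), precision = NA, recall = NA,
                      f = c(0.3, 0.5, 0.4), h = 1L)
  expect_equal(fmax(curve), list(fmax = 0.5, threshold = 0.2))
  flat <- data.frame(k = c(0.1, 0.2, 0.3), precision = NA, recall = NA,
                     f = 0.4, h = 1L)
  expect_equal(fmax(flat)$threshold, 0.1)
  none <- data.frame(k = 0.5, precision = NA, recall = NA, f = NA_real_,
                     h = 0L)
  expect_error(fmax(none), "no threshold")
})

test_that("coverage counts entities with at least one correct term", {
  ex <- workedExample()
  expect_equal(coverage(ex$scores, ex$truth, ex$dag, k = 0.5), 1L)
  zero <- ex$scores * 0
  expect_equal(coverage(zero, ex$truth, ex$dag, k = 0.5), 0L)
})

test_that("recall is non-increasing in the threshold", {
  grid <- seq(0, 1, by = 0.01)
  for (seed in 1:5) {
    dag <- randomDag(10, seed)
    terms <- setdiff(goTermIds(dag), goRoots(dag))
    set.seed(seed + 900)
    scores <- matrix(runif(6 * length(terms)), 6,
                     dimnames = list(paste0("e", 1:6), terms))
    truth <- propagateAnnotations(randomAnnotations(dag, 6, seed + 40), dag)
    names(truth@entries) <- paste0("e", seq_along(truth@entries))
    curve <- evaluationCurve(scores, truth, dag, thresholds = grid)
    expect_true(all(diff(curve$recall) <= 1e-12))
    ok <- !is.na(curve$f)
    expect_true(all(fmax(curve)$fmax >= curve$f[ok]))
  }
})

test_that("the curve matches a brute-force per-entity re-implementation", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  for (seed in 1:5) {
    dag <- randomDag(15, seed + 20)
    terms <- setdiff(goTermIds(dag), goRoots(dag))
    set.seed(seed)
    scores <- matrix(runif(10 * length(terms)), 10,
                     dimnames = list(paste0("e", 1:10), terms))
    truth <- propagateAnnotations(randomAnnotations(dag, 10, seed + 60),
                                  dag)
    names(truth@entries) <- paste0("e", seq_along(truth@entries))
    got <- suppressWarnings(
      evaluationCurve(scores, truth, dag, thresholds = grid))
    want <- bruteCurve(scores, truth, dag, grid)
    expect_equal(got$precision, want$precision)
    expect_equal(got$recall, want$recall)
    expect_equal(got$f, want$f)
    expect_equal(got$h, want$h)
  }
})

test_that("adding a correct high-confidence term never lowers recall", {
  grid <- seq(0, 1, by = 0.05)
  for (seed in 1:3) {
    dag <- randomDag(10, seed + 7)
    terms <- setdiff(goTermIds(dag), goRoots(dag))
    set.seed(seed)
    scores <- matrix(runif(4 * length(terms)), 4,
                     dimnames = list(paste0("e", 1:4), terms))
    truth <- propagateAnnotations(randomAnnotations(dag, 4, seed + 80), dag)
    names(truth@entries) <- paste0("e", seq_along(truth@entries))
    base <- suppressWarnings(
      evaluationCurve(scores, truth, dag, thresholds = grid))
    # promote one verified term of e1 to score 1.0
    v <- intersect(annotations(truth)$e1, terms)
    if (!length(v)) next
    scores2 <- scores
    scores2["e1", v[1L]] <- 1
    up <- suppressWarnings(
      evaluationCurve(scores2, truth, dag, thresholds = grid))
    expect_true(all(up$recall - base$recall >= -1e-12))
  }
})

test_that("entities with empty verified sets are skipped with a warning", {
  dag <- chainDag()
  truth <- AnnotationSet(list(e1 = c("t1", "t2"), e2 = "t1"),
                         propagated = TRUE)  # e2 only has the root
  scores <- rbind(e1 = c(t2 = 0.9, t3 = 0.1), e2 = c(t2 = 0.5, t3 = 0.5))
  expect_warning(curve <- evaluationCurve(scores, truth, dag,
                                          thresholds = 0.5),
                 "skipped")
  expect_identical(attr(curve, "N"), 1L)
})
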