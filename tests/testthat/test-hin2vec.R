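test_that("random walks respect counts, length and adjacency", {
  net <- triangleNet()
  walks <- randomWalks(net, walksPerNode = 2, walkLength = 4, seed = 1)
  expect_length(walks, 6L)
  ed <- netEdges(net)
  key <- c(paste(ed$from, ed$to), paste(ed$to, ed$from))
  for (w in walks) {
    expect_length(w, 4L)
    steps <- paste(w[-length(w)], w[-1L])
    expect_true(all(steps %in% key))
  }
  # every node starts exactly walksPerNode walks
  starts <- vapply(walks, `[`, character(1), 1L)
  expect_equal(as.integer(table(starts)[c("a", "b", "c")]), c(2L, 2L, 2L))
})

test_that("walks truncate at isolated nodes and bounce on a path", {
  net <- HetNet(data.frame(id = c("a", "b", "iso"), type = "protein"),
                data.frame(from = "a", to = "b", type = "ppi", weight = 1))
  walks <- randomWalks(net, walksPerNode = 3, walkLength = 5, seed = 2)
  isoWalks <- walks[vapply(walks, `[`, character(1), 1L) == "iso"]
  expect_length(isoWalks, 3L)
  for (w in isoWalks) expect_identical(w, "iso")
  # on a 2-node path the only trajectory alternates endpoints
  aw <- walks[vapply(walks, `[`, character(1), 1L) == "a"]
  for (w in aw) expect_identical(w, c("a", "b", "a", "b", "a"))
  expect_error(randomWalks(net, walksPerNode = 0, walkLength = 5), ">= 1")
  expect_error(randomWalks(net, walksPerNode = 1, walkLength = 0), ">= 1")
})

test_that("walks are reproducible given the seed", {
  net <- triangleNet()
  w1 <- randomWalks(net, 4, 10, seed = 7)
  w2 <- randomWalks(net, 4, 10, seed = 7)
  w3 <- randomWalks(net, 4, 10, seed = 8)
  expect_identical(w1, w2)
  expect_false(identical(w1, w3))
})

test_that("tuple extraction enumerates windowed pairs with meta-paths", {
  net <- tinyNet()
  walk <- list(c("c1", "p1", "c2"))
  out <- extractTuples(walk, net, window = 2)
  expect_equal(nrow(out$tuples), 3L)
  rel <- out$vocabulary[out$tuples$z]
  got <- data.frame(a = out$tuples$a, b = out$tuples$b, rel = rel)
  expect_true(all(c("C-circ_prot-P", "P-circ_prot-C",
                    "C-circ_prot-P-circ_prot-C") %in% rel))
  expect_identical(got$b[got$rel == "C-circ_prot-P-circ_prot-C"], "c2")
  # window 1 drops the 2-hop pair
  out1 <- extractTuples(walk, net, window = 1)
  expect_equal(nrow(out1$tuples), 2L)
  expect_error(extractTuples(walk, net, window = 0), ">= 1")
})

test_that("homogeneous walks collapse to per-length relation classes", {
  net <- triangleNet()
  out <- extractTuples(list(c("a", "b", "c", "a")), net, window = 2)
  expect_setequal(out$vocabulary, c("P-ppi-P", "P-ppi-P-ppi-P"))
})

test_that("negative sampling preserves (a, z) and the requested ratio", {
  net <- triangleNet()
  walks <- randomWalks(net, 3, 6, seed = 1)
  pos <- extractTuples(walks, net, window = 2)
  neg <- negativeSamples(pos$tuples, ratio = 5, net, seed = 2)
  expect_equal(nrow(neg), 5L * nrow(pos$tuples))
  expect_true(all(neg$label == 0L))
  expect_identical(neg$a, rep(pos$tuples$a, each = 5L))
  expect_identical(neg$z, rep(pos$tuples$z, each = 5L))
  expect_true(all(neg$b %in% netNodes(net)$id))
  expect_equal(nrow(negativeSamples(pos$tuples, ratio = 0, net)), 0L)
})

test_that("negative sampling warns when a node type cannot be resampled", {
  # a single protein: corrupting the protein endpoint can only return it
  net <- HetNet(data.frame(id = c("c1", "p1"),
                           type = c("circRNA", "protein")),
                data.frame(from = "c1", to = "p1", type = "circ_prot",
                           weight = 1))
  pos <- extractTuples(randomWalks(net, 1, 3, seed = 1), net, window = 1)
  expect_warning(neg <- negativeSamples(pos$tuples, 2, net, seed = 1),
                 "single node")
  expect_equal(nrow(neg), 2L * nrow(pos$tuples))
})

test_that("f01 maps into (0,1) with the documented fixed points", {
  expect_equal(f01(c(0, 0)), c(0.5, 0.5))
  set.seed(1)
  v <- rnorm(50, sd = 10)
  expect_true(all(f01(v) > 0 & f01(v) < 1))
  expect_true(all(f01(v, "clip") > 0 & f01(v, "clip") < 1))
  expect_gt(f01(30), 1 - 1e-8)   # upper asymptote
  expect_true(all(diff(f01(sort(v))) >= 0))  # monotone
})

test_that("scoreTuple reproduces the binding arithmetic", {
  # f01(z) = (0.5, 0.5) <=> z = 0; sum(1*1*0.5 + 1*1*0.5) = 1
  m <- new("EmbeddingModel",
           nodes = matrix(c(1, 1, 1, 1, 0, 0), 3, 2, byrow = TRUE,
                          dimnames = list(c("a", "b", "zero"), NULL)),
           relations = matrix(0, 1, 2, dimnames = list("r", NULL)),
           nodeTypes = c(a = "protein", b = "protein", zero = "protein"),
           f01Method = "logistic", history = numeric(0))
  expect_equal(scoreTuple(m, "a", "b", "r"), 1 / (1 + exp(-1)),
               tolerance = 1e-9)
  expect_equal(scoreTuple(m, "a", "b", "r"), 0.731059, tolerance = 1e-6)
  expect_equal(scoreTuple(m, "zero", "b", "r"), 0.5)
  # exchanging a and b leaves the score unchanged (tied node table)
  expect_identical(scoreTuple(m, "a", "b", "r"), scoreTuple(m, "b", "a", "r"))
  # negating one node vector reflects the probability around 0.5
  m2 <- m
  m2@nodes["b", ] <- -m2@nodes["b", ]
  expect_equal(scoreTuple(m2, "a", "b", "r"),
               1 - scoreTuple(m, "a", "b", "r"), tolerance = 1e-12)
})

test_that("per-tuple loss matches the objective at P = 0.5", {
  g1 <- embeddingGradient(c(1, 1), c(1, 1), c(-20, -20), label = 1)
  expect_equal(g1$prob, 0.5, tolerance = 1e-6)
  expect_equal(g1$loss, -log(0.5), tolerance = 1e-4)
  g0 <- embeddingGradient(c(1, 1), c(1, 1), c(-20, -20), label = 0)
  expect_equal(g0$loss, g1$loss, tolerance = 1e-6)  # symmetry at 0.5
})

test_that("analytic gradients match central finite differences", {
  h <- 1e-5
  numGrad <- function(f, x) {
    vapply(seq_along(x), function(i) {
      e <- rep(0, length(x)); e[i] <- h
      (f(x + e) - f(x - e)) / (2 * h)
    }, numeric(1))
  }
  relErr <- function(a, b) sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), 1e-10)
  set.seed(42)
  for (i in 1:20) {
    wa <- rnorm(5); wb <- rnorm(5); wz <- rnorm(5)
    R <- i %% 2L
    g <- embeddingGradient(wa, wb, wz, R)
    lossAt <- function(wa, wb, wz) embeddingGradient(wa, wb, wz, R)$loss
    expect_lt(relErr(g$ga, numGrad(function(x) lossAt(x, wb, wz), wa)),
              1e-4)
    expect_lt(relErr(g$gb, numGrad(function(x) lossAt(wa, x, wz), wb)),
              1e-4)
    expect_lt(relErr(g$gz, numGrad(function(x) lossAt(wa, wb, x), wz)),
              1e-4)
  }
})

test_that("embedding training descends and is deterministic", {
  set.seed(5)
  # sparse 20-node fixture (Bernoulli 0.25 edges)
  ids <- sprintf("n%02d", 1:20)
  prs <- which(upper.tri(diag(20)), arr.ind = TRUE)
  keep <- runif(nrow(prs)) < 0.25
  net <- HetNet(data.frame(id = ids, type = "protein"),
                data.frame(from = ids[prs[keep, 1]],
                           to = ids[prs[keep, 2]],
                           type = "ppi", weight = 1))
  walks <- randomWalks(net, 5, 10, seed = 1)
  pos <- extractTuples(walks, net, window = 2)
  neg <- negativeSamples(pos$tuples, 5, net, seed = 1)
  tuples <- rbind(pos$tuples, neg)
  m1 <- trainEmbeddings(tuples, pos$vocabulary, net, d = 8, epochs = 5,
                        learningRate = 0.05, seed = 1)
  loss <- trainingHistory(m1)
  expect_length(loss, 5L)
  expect_true(all(diff(loss) <= 0))  # mean epoch loss non-increasing
  m2 <- trainEmbeddings(tuples, pos$vocabulary, net, d = 8, epochs = 5,
                        learningRate = 0.05, seed = 1)
  expect_identical(nodeVectors(m1), nodeVectors(m2))
  expect_identical(relationVectors(m1), relationVectors(m2))
  expect_true(all(is.finite(nodeVectors(m1))))
})

test_that("planted two-block structure separates in embedding space", {
  set.seed(5)
  ids <- sprintf("n%02d", 1:20)
  prs <- which(upper.tri(diag(20)), arr.ind = TRUE)
  blk <- (prs[, 1] <= 10) == (prs[, 2] <= 10)
  keep <- blk & runif(nrow(prs)) < 0.8 | !blk & runif(nrow(prs)) < 0.05
  ed <- data.frame(from = ids[prs[keep, 1]], to = ids[prs[keep, 2]],
                   type = "ppi", weight = 1)
  net <- HetNet(data.frame(id = ids, type = "protein"), ed)
  emb <- learnEmbeddings(net, d = 16, walksPerNode = 10, walkLength = 20,
                         epochs = 10, seed = 1)
  groups <- stats::setNames(rep(1:2, each = 10), ids)
  cs <- cosineSeparation(nodeVectors(emb), groups)
  expect_gte(cs$gap, 0.1)
})

test_that("full embedding stage is reproducible from one seed", {
  net <- tinyNet()
  e1 <- learnEmbeddings(net, d = 4, walksPerNode = 2, walkLength = 5,
                        epochs = 2, seed = 3)
  e2 <- learnEmbeddings(net, d = 4, walksPerNode = 2, walkLength = 5,
                        epochs = 2, seed = 3)
  expect_identical(nodeVectors(e1), nodeVectors(e2))
  expect_identical(attr(e1, "walkHash"), attr(e2, "walkHash"))
})
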