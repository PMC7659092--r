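#' Pipeline hyperparameters
#'
#' All tunables of the five pipeline stages with their defaults: network
#' sparsification (`tau`, `ppiCutoff`), embedding (`d`, `walksPerNode`,
#' `walkLength`, `window`, `negRatio`, `embedEpochs`,
#' `embedLearningRate`), classifier (`hidden`, `batchSize`,
#' `learningRate`, `dropout`, `epochs`, `validationFraction`,
#' `minCount`) and evaluation (`thresholds`).
#'
#' @param ... overrides of the defaults.
#' @return named list of parameters.
#' @export
pipelineParams <- function(...) {
  p <- list(
    tau = 0.8, positiveOnly = TRUE, ppiCutoff = 0.4,
    retainIsolatedProteins = FALSE,
    d = 64, walksPerNode = 10, walkLength = 80, window = 2, negRatio = 5,
    embedEpochs = 5, embedLearningRate = 0.025, f01Method = "logistic",
    hidden = 256, batchSize = 64, learningRate = 0.01, dropout = 0.2,
    epochs = 150, validationFraction = 0, patience = 20, minCount = 10,
    thresholds = seq(0, 1, by = 0.01)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  }
  p[names(over)] <- over
  p
}

stageRun <- function(stage, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

## An input element may be an in-memory object or a file path.
resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the full annotation pipeline
#'
#' Orchestrates the five stages — ontology preparation, heterogeneous
#' network construction, embedding learning, classifier training on
#' protein annotations, circRNA scoring — and, when ground truth is
#' supplied, threshold-swept evaluation. Each stage logs its wall time;
#' a stage failure halts with the stage name. One global seed derives
#' per-stage seeds, so any stage is individually reproducible.
#'
#' @param inputs either a `"SyntheticWorld"` from [makeWorld()] or a named
#'   list with elements `expr`, `circProt`, `ppi`, `dag`, `annotations`
#'   and optionally `truth`; each element may be an in-memory object or a
#'   file path in the package's text formats. A prebuilt [HetNet-class]
#'   may be supplied as element `net` instead of the three network
#'   inputs (used e.g. for edge-layer ablations).
#' @param params a [pipelineParams()] list.
#' @param seed global integer seed.
#' @param outDir if non-NULL, all intermediate artifacts, a
#'   `report.json` (summary metrics + md5 content hashes) and the
#'   serialized configuration are written there.
#' @return list with `net`, `embedding`, `model`, `scores` (circRNA x
#'   term), `vocabulary`, and when truth was given `curve`, `fmax`,
#'   `threshold`, `coverage`; plus `seed`, `params`, `hashes`.
#' @export
runPipeline <- function(inputs, params = pipelineParams(), seed = 1L,
                        outDir = NULL) {
  if (inherits(inputs, "SyntheticWorld")) {
    inputs <- list(expr = inputs$expr, circProt = inputs$circProt,
                   ppi = inputs$ppi, dag = inputs$dag,
                   annotations = inputs$annotations, truth = inputs$truth)
  }
  onto <- stageRun("ontology", {
    dag <- resolveInput(inputs$dag, parseOBO)
    if (!is(dag, "GODag")) stop("input 'dag' is not a GODag or OBO path")
    a <- resolveInput(inputs$annotations, readAnnotations)
    if (!isTRUE(a@propagated)) a <- propagateAnnotations(a, dag)
    vocab <- selectTerms(a, dag, minCount = params$minCount)
    if (!length(vocab)) stop("empty term vocabulary")
    list(dag = dag, ann = a, vocab = vocab)
  })
  dag <- onto$dag; ann <- onto$ann; vocab <- onto$vocab

  net <- stageRun("network", {
    if (!is.null(inputs$net)) {
      inputs$net
    } else {
      buildHetNet(
        resolveInput(inputs$expr, readExpression),
        resolveInput(inputs$circProt, readEdgeList),
        resolveInput(inputs$ppi, readEdgeList),
        tau = params$tau, positiveOnly = params$positiveOnly,
        ppiCutoff = params$ppiCutoff,
        retainIsolatedProteins = params$retainIsolatedProteins)
    }
  })

  embedding <- stageRun("embedding", learnEmbeddings(
    net, d = params$d, walksPerNode = params$walksPerNode,
    walkLength = params$walkLength, window = params$window,
    negRatio = params$negRatio, epochs = params$embedEpochs,
    learningRate = params$embedLearningRate,
    seed = deriveSeed(seed, "embedding"), f01Method = params$f01Method))

  model <- stageRun("classifier", {
    prots <- intersect(names(ann@entries),
                       net@nodes$id[net@nodes$type == "protein"])
    if (!length(prots)) stop("no annotated proteins in the network")
    labels <- buildLabelMatrix(
      AnnotationSet(ann@entries[prots], propagated = TRUE), vocab)
    feats <- nodeVectors(embedding)[rownames(labels), , drop = FALSE]
    trainHierModel(feats, labels, dag, hidden = params$hidden,
                   batchSize = params$batchSize,
                   learningRate = params$learningRate,
                   dropout = params$dropout, epochs = params$epochs,
                   validationFraction = params$validationFraction,
                   patience = params$patience,
                   seed = deriveSeed(seed, "classifier"))
  })

  scores <- stageRun("predict", {
    circ <- net@nodes$id[net@nodes$type == "circRNA"]
    predictScores(model, nodeVectors(embedding)[circ, , drop = FALSE])
  })

  result <- list(net = net, embedding = embedding, model = model,
                 scores = scores, vocabulary = vocab, seed = seed,
                 params = params)
  if (!is.null(inputs$truth)) {
    ev <- stageRun("evaluate", {
      tr <- resolveInput(inputs$truth, readAnnotations)
      if (!isTRUE(tr@propagated)) tr <- propagateAnnotations(tr, dag)
      curve <- evaluationCurve(scores, tr, dag,
                               thresholds = params$thresholds)
      fm <- fmax(curve)
      list(curve = curve, fmax = fm$fmax, threshold = fm$threshold,
           coverage = coverage(scores, tr, dag, k = fm$threshold),
           truth = tr)
    })
    result <- c(result, ev)
  }
  result$hashes <- c(
    walks = attr(embedding, "walkHash"),
    network = objectHash(net@edges),
    embeddings = objectHash(embedding@nodes),
    scores = objectHash(scores)
  )
  if (!is.null(outDir)) {
    writePipelineOutputs(result, dag, outDir)
  }
  result
}

writePipelineOutputs <- function(result, dag, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeHetNet(result$net, file.path(outDir, "network.tsv"))
  writeEmbeddings(result$embedding, file.path(outDir, "embeddings.tsv"))
  writeScores(result$scores, file.path(outDir, "scores.tsv"))
  writeLines(result$vocabulary, file.path(outDir, "vocabulary.txt"))
  report <- list(seed = result$seed,
                 nodes = nrow(result$net@nodes),
                 edges = nrow(result$net@edges),
                 vocabularySize = length(result$vocabulary),
                 hashes = as.list(result$hashes))
  if (!is.null(result$curve)) {
    utils::write.table(result$curve, file.path(outDir, "curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    grDevices::png(file.path(outDir, "pr_curve.png"), width = 600,
                   height = 600)
    plotPRCurve(result$curve, main = "Precision-recall")
    grDevices::dev.off()
    report$fmax <- result$fmax
    report$threshold <- result$threshold
    report$coverage <- result$coverage
  }
  p <- result$params
  p$thresholds <- NULL
  yaml::write_yaml(p, file.path(outDir, "params.yaml"))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}

#' Read a pipeline configuration file
#'
#' YAML with blocks `inputs` (paths: `expr`, `circ_prot`, `ppi`, `obo`,
#' `annotations`, optional `truth`), `params` (any [pipelineParams()]
#' name) and scalars `seed`, `out_dir`.
#'
#' @param path YAML file path.
#' @return list with `inputs`, `params`, `seed`, `outDir` ready for
#'   [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  inputs <- list(expr = cfg$inputs$expr, circProt = cfg$inputs$circ_prot,
                 ppi = cfg$inputs$ppi, dag = cfg$inputs$obo,
                 annotations = cfg$inputs$annotations,
                 truth = cfg$inputs$truth)
  params <- do.call(pipelineParams, cfg$params %||% list())
  list(inputs = inputs, params = params, seed = cfg$seed %||% 1L,
       outDir = cfg$out_dir)
}
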