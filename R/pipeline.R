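# End-to-end orchestration: simulate (or load) -> normalize -> DE per
# contrast -> enrichment -> networks (gene-act, co-expression,
# dif-degree, K-core) -> Venn categorisation, all written under one
# output directory with a manifest. Identical config + seed reproduce
# identical analysis outputs (the manifest additionally records
# wall-clock time).

#' Assemble and validate a pipeline configuration
#'
#' Either `simulationParams` (self-contained synthetic run) or the
#' three input paths (`matrixPath` + `designPath`, `gmtPath`,
#' `relationsPath`) must be supplied.
#'
#' @param outdir output directory (created if absent).
#' @param simulationParams a [SimulationParams-class] for self-contained
#'   runs, or `NULL`.
#' @param matrixPath,designPath,gmtPath,relationsPath input files for
#'   runs on real data.
#' @param pMax,fdrMax,minFold DE and enrichment thresholds.
#' @param rMin co-expression correlation gate.
#' @param coreDegreeBaseline,coreDegreeTreatment strict core-gene
#'   thresholds for the genotype baseline comparison and the treatment
#'   comparisons.
#' @param normalize `"quantile"` or `"none"`.
#' @param seed master seed for the simulation stage; `NULL` (default)
#'   keeps the seed carried by `simulationParams`, an integer
#'   overrides it.
#' @return A validated config list of class `"stellnetConfig"`.
#' @export
pipelineConfig <- function(outdir,
                           simulationParams = NULL,
                           matrixPath = NULL, designPath = NULL,
                           gmtPath = NULL, relationsPath = NULL,
                           pMax = 0.05, fdrMax = 0.05, minFold = 1.5,
                           rMin = 0.8,
                           coreDegreeBaseline = 5L,
                           coreDegreeTreatment = 3L,
                           normalize = c("quantile", "none"),
                           seed = NULL) {
  normalize <- match.arg(normalize)
  if (pMax <= 0 || pMax > 1) stop("pMax must be in (0, 1]")
  if (fdrMax <= 0 || fdrMax > 1) stop("fdrMax must be in (0, 1]")
  if (minFold <= 1) stop("minFold must be > 1")
  if (rMin < 0 || rMin > 1) stop("rMin must be in [0, 1]")
  selfContained <- !is.null(simulationParams)
  if (!selfContained) {
    paths <- c(matrixPath, designPath, gmtPath, relationsPath)
    if (length(paths) != 4L)
      stop("supply either simulationParams or all four input paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  } else {
    validObject(simulationParams)
    if (!is.null(seed)) simulationParams@seed <- as.integer(seed)
    seed <- simulationParams@seed
  }
  if (is.null(seed)) seed <- NA_integer_  # data runs draw nothing
  structure(list(outdir = outdir, simulationParams = simulationParams,
                 matrixPath = matrixPath, designPath = designPath,
                 gmtPath = gmtPath, relationsPath = relationsPath,
                 pMax = pMax, fdrMax = fdrMax, minFold = minFold,
                 rMin = rMin,
                 coreDegreeBaseline = as.integer(coreDegreeBaseline),
                 coreDegreeTreatment = as.integer(coreDegreeTreatment),
                 normalize = normalize, seed = as.integer(seed)),
            class = "stellnetConfig")
}

# co-expression case/control sample pairings per contrast
coexPairing <- function(contrast) switch(contrast,
  `1Nvs2N` = c("JS1.PBS", "JS2.PBS"),
  `1LvsN` = c("JS1.LPS", "JS1.PBS"),
  `1HvsN` = c("JS1.HMGB1", "JS1.PBS"),
  `2LvsN` = c("JS2.LPS", "JS2.PBS"),
  `2HvsN` = c("JS2.HMGB1", "JS2.PBS"),
  stop("unknown contrast: ", contrast))

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> normalize -> per-contrast moderated-t DE
#' screen -> signed enrichment -> gene-act and co-expression networks
#' with differential-degree and K-core hub calls -> four-set Venn
#' partition and TLR4 category integration, writing every stage's
#' output under `config$outdir` (TSV tables, SIF-like networks, JSON
#' summaries) together with a run manifest.
#'
#' @param config a config list from [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results: `experiment`,
#'   `truth` (synthetic runs), `de` (per-contrast tables), `deSets`,
#'   `enrichment`, `networks`, `degreeReports`, `vennRegions`,
#'   `categories`, `categoryResults`, `summary`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "stellnetConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, paste0(...))
  log <- function(...) message("[stellnet] ", ...)

  truth <- NULL
  if (!is.null(config$simulationParams)) {
    log("simulating synthetic dataset (seed ", config$seed, ")")
    sim <- simulateHscData(config$simulationParams)
    experiment <- sim$experiment
    gs <- simulateGeneSets(config$simulationParams, sim$truth,
                           rownames(experiment))
    collection <- gs$collection
    truth <- gs$truth
    relTable <- simulateRelations(config$simulationParams, truth,
                                  rownames(experiment))
    writeExpressionMatrix(exprs(experiment), out("expression.tsv"))
    writeDesign(experiment, out("design.tsv"))
    writeGMT(collection, out("gene_sets.gmt"))
    writeRelations(relTable, out("relations.tsv"))
    writeGroundTruth(truth, out("ground_truth.json"))
  } else {
    log("loading inputs")
    experiment <- readHscExperiment(config$matrixPath, config$designPath)
    collection <- readGMT(config$gmtPath, universe = rownames(experiment))
    relTable <- readRelations(config$relationsPath)
  }

  if (config$normalize == "quantile") {
    log("quantile normalization")
    experiment <- quantileNormalize(experiment)
    writeExpressionMatrix(exprs(experiment), out("expression.normalized.tsv"))
  }

  contrasts <- names(CONTRAST_CELLS)
  de <- list(); deSets <- list()
  for (ct in contrasts) {
    log("DE screen: ", ct, " (P < ", config$pMax, ", fold > ",
        config$minFold, ")")
    de[[ct]] <- runContrast(experiment, ct, pMax = config$pMax,
                            minFold = config$minFold)
    deSets[[ct]] <- selectDEGenes(de[[ct]], config$pMax, config$minFold)
    writeDETable(de[[ct]], out("de_", ct, ".tsv"))
  }

  enrichmentTables <- list()
  for (ct in contrasts) for (dir in c("up", "down")) {
    genes <- deSets[[ct]][[dir]]
    if (!length(genes)) { log("no ", dir, " genes in ", ct); next }
    enr <- enrichGeneSets(genes, dir, collection, config$pMax,
                          config$fdrMax)
    enrichmentTables[[paste(ct, dir, sep = ".")]] <- enr
    writeDETable(enr, out("enrichment_", ct, "_", dir, ".tsv"))
  }

  networksOut <- list(); degreeReports <- list()
  for (ct in contrasts) {
    genes <- union(deSets[[ct]]$up, deSets[[ct]]$down)
    if (!length(genes)) next
    dirs <- c(setNames(rep("up", length(deSets[[ct]]$up)), deSets[[ct]]$up),
              setNames(rep("down", length(deSets[[ct]]$down)),
                       deSets[[ct]]$down))
    minDeg <- if (ct == "1Nvs2N") config$coreDegreeBaseline
              else config$coreDegreeTreatment
    act <- induceGeneActNet(genes, dirs, relTable)
    writeNetwork(act, out("actnet_", ct))
    pair <- coexPairing(ct)
    coexCase <- suppressWarnings(buildCoexpressionNet(
      experiment, cellSamples(experiment, pair[1]), genes,
      rMin = config$rMin, pMax = config$pMax))
    coexCtrl <- suppressWarnings(buildCoexpressionNet(
      experiment, cellSamples(experiment, pair[2]), genes,
      rMin = config$rMin, pMax = config$pMax))
    difRep <- differentialDegree(coexCase, coexCtrl, minDeg)
    core <- kCore(coexCase, minDeg)
    writeNetwork(coexCase, out("coexnet_", ct, "_case"))
    writeNetwork(coexCtrl, out("coexnet_", ct, "_control"))
    writeDETable(difRep, out("difdegree_", ct, ".tsv"))
    writeNetwork(core, out("kcore_", ct))
    networksOut[[ct]] <- list(actnet = act, coex_case = coexCase,
                              coex_control = coexCtrl, kcore = core,
                              act_core_genes = selectCoreGenes(act, minDeg))
    degreeReports[[ct]] <- difRep
  }

  log("Venn partition and TLR4 categories")
  vennSets <- lapply(deSets[c("1LvsN", "2LvsN", "1HvsN", "2HvsN")],
                     function(x) union(x$up, x$down))
  regions <- vennPartition(vennSets)
  categories <- tlr4Categories(deSets[c("1LvsN", "2LvsN", "1HvsN", "2HvsN")])
  categoryResults <- integrateCategories(
    categories, collection, relTable,
    minDegree = config$coreDegreeBaseline,
    pMax = config$pMax, fdrMax = config$fdrMax)
  for (cat in names(categoryResults)) {
    writeDETable(categoryResults[[cat]]$enrichment,
                 out("category_", cat, "_enrichment.tsv"))
    writeNetwork(categoryResults[[cat]]$network, out("category_", cat))
    writeLines(sort(union(categories[[cat]]$up, categories[[cat]]$down)),
               out("category_", cat, "_genes.txt"))
  }

  summary <- list(
    n_genes = nrow(experiment), n_samples = ncol(experiment),
    n_de_by_contrast = lapply(deSets, function(x)
      list(up = length(x$up), down = length(x$down))),
    venn_region_sizes = lapply(regions, length),
    category_counts = lapply(categories, function(x)
      list(up = length(x$up), down = length(x$down))),
    core_genes = lapply(degreeReports, function(r)
      r$gene[r$is_core]))
  jsonlite::write_json(summary, out("venn_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package = "stellnet",
    version = as.character(utils::packageVersion("stellnet")),
    seed = config$seed,
    thresholds = config[c("pMax", "fdrMax", "minFold", "rMin",
                          "coreDegreeBaseline", "coreDegreeTreatment")],
    normalize = config$normalize,
    self_contained = !is.null(config$simulationParams),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(experiment = experiment, truth = truth, de = de,
                 deSets = deSets, enrichment = enrichmentTables,
                 networks = networksOut, degreeReports = degreeReports,
                 vennRegions = regions, categories = categories,
                 categoryResults = categoryResults, summary = summary))
}
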