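# Seeded synthetic data emulating the 2 cell line x 3 treatment screen.
# Every random draw happens inside withSeed() on a stage-specific stream
# derived from the master seed, so adding a stage never perturbs another
# stage's draws and equal (params, seed) gives bit-identical output.

stageSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

simGeneIds <- function(n) sprintf("G%05d", seq_len(n))

# alternating planted direction: odd index within its block is up
plantSign <- function(i) ifelse(i %% 2L == 1L, 1, -1)

#' Generate a synthetic two-genotype, three-treatment expression dataset
#'
#' Simulates log2 intensities for the full design (JS1/JS2 x
#' PBS/LPS/HMGB1 x replicates) with planted genotype main effects,
#' TLR4-dependent treatment effects confined to JS1 (LPS-specific,
#' HMGB1-specific and shared responders), and hub-anchored latent-factor
#' co-expression modules active in a single design cell. Returns the
#' expression object together with the planted [GroundTruth-class].
#'
#' Planted blocks occupy consecutive gene indices (genotype, then
#' LPS-specific, HMGB1-specific, shared, then module genes); effect
#' directions alternate up/down with index parity. Module members are
#' generated as `baseline + loading x latent + noise` in the module's
#' design cell only, with hub loading 1 and member loadings uniform on
#' [0.6, 1], so within-module Pearson correlations are high in that cell
#' and centred at zero elsewhere.
#'
#' @param params a [SimulationParams-class] object.
#' @return `list(experiment = HscExperiment, truth = GroundTruth)`.
#' @examples
#' sim <- simulateHscData(SimulationParams(nGenes = 300, seed = 7))
#' sim$experiment
#' @export
simulateHscData <- function(params) {
  validObject(params)
  p <- params
  genes <- simGeneIds(p@nGenes)
  cells <- designCells()
  reps <- p@replicatesPerCell
  design <- data.frame(
    sample_id = as.vector(vapply(cells, function(cl)
      paste0(cl, "_R", seq_len(reps)), character(reps))),
    cell_line = rep(sub("\\..*$", "", cells), each = reps),
    treatment = rep(sub("^.*\\.", "", cells), each = reps),
    replicate = rep(seq_len(reps), times = length(cells)),
    stringsAsFactors = FALSE)
  cellOf <- paste(design$cell_line, design$treatment, sep = ".")

  # consecutive planted blocks
  take <- function(from, n) if (n > 0) seq(from, length.out = n) else integer()
  iGeno   <- take(1L, p@nGenotypeDe)
  iLps    <- take(p@nGenotypeDe + 1L, p@nLpsSpecific)
  iHmgb1  <- take(p@nGenotypeDe + p@nLpsSpecific + 1L, p@nHmgb1Specific)
  iShared <- take(p@nGenotypeDe + p@nLpsSpecific + p@nHmgb1Specific + 1L,
                  p@nSharedResponders)
  modStart <- p@nGenotypeDe + p@nLpsSpecific + p@nHmgb1Specific +
    p@nSharedResponders + 1L
  iModules <- lapply(seq_len(p@nModules), function(m)
    take(modStart + (m - 1L) * p@moduleSize, p@moduleSize))

  mat <- withSeed(stageSeed(p@seed, "expression"), {
    baseline <- runif(p@nGenes, p@baselineRange[1], p@baselineRange[2])
    mu <- matrix(baseline, nrow = p@nGenes, ncol = nrow(design))
    js1 <- design$cell_line == "JS1"
    addEffect <- function(mu, idx, colsel) {
      if (length(idx))
        mu[idx, colsel] <- mu[idx, colsel] +
          plantSign(seq_along(idx)) * p@effectSizeLog2
      mu
    }
    mu <- addEffect(mu, iGeno, js1)
    mu <- addEffect(mu, iLps, cellOf == "JS1.LPS")
    mu <- addEffect(mu, iHmgb1, cellOf == "JS1.HMGB1")
    mu <- addEffect(mu, iShared, cellOf %in% c("JS1.LPS", "JS1.HMGB1"))
    noise <- matrix(rnorm(length(mu), 0, p@noiseSd), nrow = nrow(mu))
    for (m in seq_len(p@nModules)) {
      idx <- iModules[[m]]
      colsel <- which(cellOf == p@moduleCells[m])
      z <- rnorm(length(colsel))
      # standardize the realized draws to an exact scale: with few
      # replicates the sample variance of raw normal draws is such a
      # noisy multiple of latentFactorSd^2 that the planted correlation
      # structure would vary wildly from seed to seed
      z <- (z - mean(z)) / sd(z) * p@latentFactorSd
      if (anyNA(z)) z <- numeric(length(colsel))
      loadings <- c(1, runif(length(idx) - 1L, 0.6, 1))
      mu[idx, colsel] <- mu[idx, colsel] + outer(loadings, z)
      # the hub's observed profile carries the latent factor itself:
      # members = baseline + loading x hub latent + noise, hub noise-free
      # within the module's design cell so it anchors the module
      noise[idx[1], colsel] <- 0
    }
    mu + noise
  })
  dimnames(mat) <- list(genes, design$sample_id)

  dirSplit <- function(idx) list(
    up = genes[idx[plantSign(seq_along(idx)) > 0]],
    down = genes[idx[plantSign(seq_along(idx)) < 0]])
  empty <- list(up = character(), down = character())
  joinSets <- function(a, b) list(up = c(a$up, b$up), down = c(a$down, b$down))
  deGenes <- list(
    `1LvsN` = joinSets(dirSplit(iLps), dirSplit(iShared)),
    `2LvsN` = empty,
    `1HvsN` = joinSets(dirSplit(iHmgb1), dirSplit(iShared)),
    `2HvsN` = empty,
    `1Nvs2N` = dirSplit(iGeno))

  moduleMembers <- setNames(lapply(iModules, function(i) genes[i]),
                            if (p@nModules) paste0("M", seq_len(p@nModules))
                            else character())
  hubGenes <- list()
  for (m in seq_len(p@nModules)) {
    cell <- p@moduleCells[m]
    hubGenes[[cell]] <- c(hubGenes[[cell]], genes[iModules[[m]][1]])
  }
  vennCategory <- c(
    setNames(rep("tlr4_lps_specific", length(iLps)), genes[iLps]),
    setNames(rep("tlr4_hmgb1_specific", length(iHmgb1)), genes[iHmgb1]),
    setNames(rep("tlr4_common", length(iShared)), genes[iShared]))

  truth <- new("GroundTruth", deGenes = deGenes, hubGenes = hubGenes,
               moduleMembers = moduleMembers, enrichedSets = character(),
               vennCategory = vennCategory)
  list(experiment = HscExperiment(mat, design), truth = truth)
}

#' Generate a synthetic gene-set collection with planted enrichment
#'
#' Produces `nGeneSets` sets over the simulated gene universe. The first
#' `nEnrichedSets` draw a fraction `enrichedSetOverlap` of their members
#' from the planted treatment-responsive pool (genes DE in the JS1 LPS
#' or HMGB1 contrasts) and are flagged in the returned truth; the rest
#' are drawn uniformly from the universe.
#'
#' @param params a [SimulationParams-class].
#' @param truth the [GroundTruth-class] from [simulateHscData()].
#' @param geneUniverse character vector of all simulated genes.
#' @return `list(collection = GeneSetCollection, truth = GroundTruth)`
#'   with `truth@enrichedSets` filled in.
#' @export
simulateGeneSets <- function(params, truth, geneUniverse) {
  p <- params
  if (p@enrichedSetOverlap < 0 || p@enrichedSetOverlap > 1)
    stop("enrichedSetOverlap must be in [0, 1]")
  pool <- unique(unlist(truth@deGenes[c("1LvsN", "1HvsN")], use.names = FALSE))
  if (!all(pool %in% geneUniverse))
    stop("ground-truth genes must lie in the gene universe")
  ids <- if (p@nGeneSets) sprintf("SET%04d", seq_len(p@nGeneSets)) else character()
  enriched <- head(ids, p@nEnrichedSets)
  sets <- withSeed(stageSeed(p@seed, "genesets"), {
    lapply(seq_len(p@nGeneSets), function(i) {
      if (i <= p@nEnrichedSets) {
        nIn <- min(round(p@enrichedSetOverlap * p@setSize), length(pool))
        inside <- if (nIn) sample(pool, nIn) else character()
        outside <- sample(setdiff(geneUniverse, inside), p@setSize - nIn)
        c(inside, outside)
      } else sample(geneUniverse, p@setSize)
    })
  })
  names(sets) <- ids
  desc <- setNames(rep("synthetic background set", length(ids)), ids)
  desc[enriched] <- "synthetic enriched set"
  truth@enrichedSets <- enriched
  list(collection = GeneSetCollection(sets, geneUniverse, desc),
       truth = truth)
}

#' Generate a synthetic typed relation table
#'
#' Background activation/inhibition/compound relations are sampled at
#' density `relationDensity` over all unordered gene pairs; each planted
#' module hub is additionally wired to `hubRelationDegree` partners
#' drawn from the planted DE genes, so gene-act-network degree
#' centrality has a recoverable signal.
#'
#' @inheritParams simulateGeneSets
#' @return A [RelationTable-class].
#' @export
simulateRelations <- function(params, truth, geneUniverse) {
  p <- params
  n <- length(geneUniverse)
  nPairs <- n * (n - 1) / 2
  nBg <- round(p@relationDensity * nPairs)
  dePool <- unique(unlist(truth@deGenes, use.names = FALSE))
  hubs <- unlist(truth@hubGenes, use.names = FALSE)
  withSeed(stageSeed(p@seed, "relations"), {
    edges <- data.frame(source = character(), relation_type = character(),
                        target = character(), stringsAsFactors = FALSE)
    if (nBg > 0) {
      # sample unordered pairs by linear index into the strict upper triangle
      k <- sample(nPairs, min(nBg, nPairs))
      i <- ceiling((sqrt(8 * k + 1) - 1) / 2) + 1  # row of pair k
      j <- k - (i - 1) * (i - 2) / 2
      edges <- data.frame(source = geneUniverse[j],
                          relation_type = sample(RELATION_TYPES, length(k),
                                                 replace = TRUE),
                          target = geneUniverse[i],
                          stringsAsFactors = FALSE)
    }
    if (p@hubRelationDegree > 0 && length(hubs)) {
      for (h in hubs) {
        partners <- sample(setdiff(dePool, h),
                           min(p@hubRelationDegree, length(dePool) - 1L))
        edges <- rbind(edges, data.frame(
          source = h, relation_type = "activation", target = partners,
          stringsAsFactors = FALSE))
      }
    }
    if (nrow(edges))
      edges <- edges[!duplicated(edgeKey(edges$source, edges$target)), ,
                     drop = FALSE]
    RelationTable(edges)
  })
}
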