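smallParams <- function(...) {
  args <- utils::modifyList(list(
    nGenes = 400L, replicatesPerCell = 4L, nGenotypeDe = 20L,
    nLpsSpecific = 20L, nHmgb1Specific = 20L, nSharedResponders = 10L,
    nModules = 1L, moduleSize = 11L, nGeneSets = 10L, nEnrichedSets = 1L,
    setSize = 10L, seed = 3L), list(...))
  do.call(SimulationParams, args)
}

test_that("generator is bit-identical under one seed and differs across seeds", {
  a <- simulateHscData(smallParams())
  b <- simulateHscData(smallParams())
  c <- simulateHscData(smallParams(seed = 4L))
  expect_identical(exprs(a$experiment), exprs(b$experiment))
  expect_identical(a$truth@deGenes, b$truth@deGenes)
  expect_false(identical(exprs(a$experiment), exprs(c$experiment)))
  gsa <- simulateGeneSets(smallParams(), a$truth, rownames(a$experiment))
  gsb <- simulateGeneSets(smallParams(), b$truth, rownames(b$experiment))
  expect_identical(geneSets(gsa$collection), geneSets(gsb$collection))
  ra <- simulateRelations(smallParams(), a$truth, rownames(a$experiment))
  rb <- simulateRelations(smallParams(), b$truth, rownames(b$experiment))
  expect_identical(relations(ra), relations(rb))
})

test_that("with no effects and no noise every gene is flat at its baseline", {
  p <- SimulationParams(nGenes = 50L, replicatesPerCell = 3L, noiseSd = 0,
                        nGenotypeDe = 0L, nLpsSpecific = 0L,
                        nHmgb1Specific = 0L, nSharedResponders = 0L,
                        nModules = 0L, seed = 1L)
  sim <- simulateHscData(p)
  m <- exprs(sim$experiment)
  expect_true(all(apply(m, 1, function(r) diff(range(r)) == 0)))
})

test_that("noise-free planted effects equal the stated group-mean shifts exactly", {
  p <- SimulationParams(nGenes = 200L, replicatesPerCell = 3L, noiseSd = 0,
                        nGenotypeDe = 0L, nLpsSpecific = 50L,
                        nHmgb1Specific = 0L, nSharedResponders = 0L,
                        nModules = 0L, effectSizeLog2 = 1, seed = 2L)
  sim <- simulateHscData(p)
  m <- exprs(sim$experiment)
  e <- sim$experiment
  d1 <- rowMeans(m[, cellSamples(e, "JS1.LPS")]) -
    rowMeans(m[, cellSamples(e, "JS1.PBS")])
  d2 <- rowMeans(m[, cellSamples(e, "JS2.LPS")]) -
    rowMeans(m[, cellSamples(e, "JS2.PBS")])
  planted <- c(sim$truth@deGenes[["1LvsN"]]$up, sim$truth@deGenes[["1LvsN"]]$down)
  expect_equal(sort(abs(d1[planted])), rep(1, 50), ignore_attr = TRUE)
  expect_equal(unname(d1[sim$truth@deGenes[["1LvsN"]]$up]),
               rep(1, length(sim$truth@deGenes[["1LvsN"]]$up)))
  expect_equal(unname(d1[sim$truth@deGenes[["1LvsN"]]$down]),
               rep(-1, length(sim$truth@deGenes[["1LvsN"]]$down)))
  expect_equal(unname(d2[planted]), rep(0, 50))
  unplanted <- setdiff(rownames(m), planted)
  expect_equal(unname(d1[unplanted]), rep(0, length(unplanted)))
})

test_that("invalid simulation parameters are rejected", {
  expect_error(SimulationParams(nGenes = 10L, nGenotypeDe = 100L),
               "exceed")
  expect_error(SimulationParams(replicatesPerCell = 1L), ">= 2")
  expect_error(SimulationParams(enrichedSetOverlap = 1.2), "\\[0, 1\\]")
})

test_that("ground truth genes exist in the matrix and hubs sit in modules", {
  sim <- simulateHscData(smallParams())
  genes <- rownames(sim$experiment)
  expect_true(all(unlist(sim$truth@deGenes) %in% genes))
  expect_true(all(unlist(sim$truth@moduleMembers) %in% genes))
  expect_true(all(unlist(sim$truth@hubGenes) %in%
                    unlist(sim$truth@moduleMembers)))
  expect_true(all(names(sim$truth@vennCategory) %in% genes))
})

test_that("module members correlate strongly in their design cell and not elsewhere", {
  meds_in <- c(); meds_out <- c()
  for (seed in 1:3) {
    p <- SimulationParams(nGenes = 300L, replicatesPerCell = 8L,
                          nGenotypeDe = 0L, nLpsSpecific = 0L,
                          nHmgb1Specific = 0L, nSharedResponders = 0L,
                          nModules = 1L, moduleSize = 20L,
                          moduleCells = "JS1.PBS",
                          latentFactorSd = 2, seed = seed)
    sim <- simulateHscData(p)
    mem <- sim$truth@moduleMembers$M1
    e <- sim$experiment
    rIn <- cor(t(exprs(e)[mem, cellSamples(e, "JS1.PBS")]))
    rOut <- cor(t(exprs(e)[mem, cellSamples(e, "JS2.HMGB1")]))
    meds_in <- c(meds_in, median(abs(rIn[upper.tri(rIn)])))
    meds_out <- c(meds_out, median(rOut[upper.tri(rOut)]))
  }
  expect_true(all(meds_in > 0.8))
  expect_true(all(abs(meds_out) < 0.3))
})

test_that("full overlap forces enriched sets inside the planted DE pool", {
  p <- smallParams(enrichedSetOverlap = 1)
  sim <- simulateHscData(p)
  gs <- simulateGeneSets(p, sim$truth, rownames(sim$experiment))
  pool <- unique(unlist(sim$truth@deGenes[c("1LvsN", "1HvsN")]))
  for (id in gs$truth@enrichedSets)
    expect_true(all(geneSets(gs$collection)[[id]] %in% pool))
})

test_that("zero gene sets yields an empty collection with an intact universe", {
  p <- smallParams(nGeneSets = 0L, nEnrichedSets = 0L)
  sim <- simulateHscData(p)
  gs <- simulateGeneSets(p, sim$truth, rownames(sim$experiment))
  expect_length(gs$collection, 0)
  expect_identical(universe(gs$collection), rownames(sim$experiment))
})

test_that("planted hubs are wired to the requested number of DE partners", {
  p <- smallParams(relationDensity = 0, hubRelationDegree = 10L)
  sim <- simulateHscData(p)
  rel <- simulateRelations(p, sim$truth, rownames(sim$experiment))
  hub <- unlist(sim$truth@hubGenes)[1]
  dePool <- unique(unlist(sim$truth@deGenes))
  e <- relations(rel)
  partners <- unique(c(e$target[e$source == hub], e$source[e$target == hub]))
  expect_length(partners, 10)
  expect_true(all(partners %in% dePool))
  # induced act-net over hub + all DE genes recovers that degree
  net <- induceGeneActNet(c(hub, dePool), relationTable = rel)
  expect_equal(unname(nodeDegrees(net)[hub]), 10)
})

test_that("a zero-edge parameterization yields an empty relation table", {
  p <- smallParams(relationDensity = 0, hubRelationDegree = 0L)
  sim <- simulateHscData(p)
  rel <- simulateRelations(p, sim$truth, rownames(sim$experiment))
  expect_equal(length(rel), 0)
})

test_that("background relation density matches its closed-form expected degree", {
  # expected induced degree of a gene among a fixed subset of size s is
  # approximately d * (s - 1); averaged over seeds and genes
  d <- 0.02; nG <- 200L
  degs <- c()
  for (seed in 1:5) {
    p <- SimulationParams(nGenes = nG, nGenotypeDe = 50L, nLpsSpecific = 0L,
                          nHmgb1Specific = 0L, nSharedResponders = 0L,
                          nModules = 0L, relationDensity = d,
                          hubRelationDegree = 0L, seed = seed)
    sim <- simulateHscData(p)
    genes <- rownames(sim$experiment)
    sub <- genes[1:50]
    net <- induceGeneActNet(sub, relationTable =
                              simulateRelations(p, sim$truth, genes),
                            keepIsolated = TRUE)
    degs <- c(degs, mean(nodeDegrees(net)))
  }
  expect_equal(mean(degs), d * 49, tolerance = 0.15)
})
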