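test_that("act-net induction keeps only edges internal to the gene list", {
  rel <- RelationTable(data.frame(
    source = c("A", "B", "C"),
    relation_type = c("activation", "inhibition", "activation"),
    target = c("B", "C", "D")))
  net <- induceGeneActNet(c("A", "B", "C"), relationTable = rel)
  expect_setequal(networkNodes(net)$gene, c("A", "B", "C"))
  expect_equal(nrow(networkEdges(net)), 2)
  deg <- nodeDegrees(net)
  expect_equal(unname(deg[c("A", "B", "C")]), c(1L, 2L, 1L))
  # empty relation table gives an empty network
  empty <- induceGeneActNet(c("A", "B"), relationTable = RelationTable())
  expect_equal(nrow(networkNodes(empty)), 0)
})

test_that("isolated genes are dropped unless kept, and directions annotate nodes", {
  rel <- RelationTable(data.frame(source = "A", relation_type = "compound",
                                  target = "B"))
  net <- induceGeneActNet(c("A", "B", "Z"), c(A = "up", Z = "down"), rel)
  expect_setequal(networkNodes(net)$gene, c("A", "B"))
  kept <- induceGeneActNet(c("A", "B", "Z"), c(A = "up", Z = "down"), rel,
                           keepIsolated = TRUE)
  nn <- networkNodes(kept)
  expect_equal(nn$degree[nn$gene == "Z"], 0L)
  expect_equal(nn$de_direction[nn$gene == "A"], "up")
  expect_equal(nn$de_direction[nn$gene == "B"], "none")
})

test_that("parallel relations between one pair collapse for degree counting", {
  rel <- RelationTable(data.frame(
    source = c("A", "B"), relation_type = c("activation", "inhibition"),
    target = c("B", "A")))
  net <- induceGeneActNet(c("A", "B"), relationTable = rel)
  expect_equal(unname(nodeDegrees(net)), c(1L, 1L))
})

test_that("core-gene selection is a strict degree threshold, sorted by degree", {
  star <- RelationTable(data.frame(
    source = "hub", relation_type = "activation",
    target = paste0("leaf", 1:6)))
  net <- induceGeneActNet(c("hub", paste0("leaf", 1:6)),
                          relationTable = star)
  expect_identical(selectCoreGenes(net, 5), "hub")
  expect_identical(selectCoreGenes(net, 6), character(0))
  expect_setequal(selectCoreGenes(net, 0),
                  c("hub", paste0("leaf", 1:6)))
  set.seed(9)
  for (i in 1:10) {
    e <- randomGraphEdges(20, 0.2)
    net <- edgeListNetwork(e)
    thr <- sample(0:4, 1)
    deg <- table(factor(c(e$from, e$to),
                        levels = networkNodes(net)$gene))
    expect_setequal(selectCoreGenes(net, thr),
                    names(deg)[deg > thr])
  }
})

test_that("co-expression edges match a brute-force cor.test double loop", {
  for (seed in 1:3) {
    m <- randomExprMatrix(20, 16, seed)
    net <- buildCoexpressionNet(m, colnames(m), rMin = 0.3, pMax = 0.2)
    oracle <- bruteCoexEdges(m, rMin = 0.3, pMax = 0.2)
    got <- networkEdges(net)
    expect_equal(nrow(got), nrow(oracle))
    key <- function(d) sort(paste(pmin(d$from, d$to), pmax(d$from, d$to)))
    expect_identical(key(got), key(oracle))
    # r and p agree with cor.test values
    if (nrow(got)) {
      i <- which.max(abs(got$r))
      ct <- cor.test(m[got$from[i], ], m[got$to[i], ])
      expect_equal(got$r[i], unname(ct$estimate), tolerance = 1e-10)
      expect_equal(got$p[i], ct$p.value, tolerance = 1e-8)
    }
  }
})

test_that("identical expression vectors give an r = 1 edge; constants are dropped", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), flat = c(5, 5, 5, 5))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(net <- buildCoexpressionNet(m, colnames(m), rMin = 0.8,
                                             pMax = 0.05),
                 "constant")
  e <- networkEdges(net)
  expect_equal(nrow(e), 1)
  expect_equal(e$r, 1)
  expect_false("flat" %in% networkNodes(net)$gene)
  expect_error(buildCoexpressionNet(m, paste0("s", 1:2)), "3 samples")
})

test_that("raising the correlation gate never adds edges", {
  m <- randomExprMatrix(15, 10, 4)
  loose <- networkEdges(buildCoexpressionNet(m, colnames(m), rMin = 0.2,
                                             pMax = 0.5))
  tight <- networkEdges(buildCoexpressionNet(m, colnames(m), rMin = 0.6,
                                             pMax = 0.5))
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("differential degree subtracts control from case with absence as zero", {
  ec <- data.frame(from = c("A", "A", "A", "A", "A", "A", "A"),
                   to = paste0("x", 1:7))
  netCase <- edgeListNetwork(ec)
  netCtrl <- edgeListNetwork(data.frame(from = "B", to = "x1"))
  rep <- differentialDegree(netCase, netCtrl, minDif = 5)
  expect_equal(rep$dif_degree[rep$gene == "A"], 7)
  expect_true(rep$is_core[rep$gene == "A"])
  expect_equal(rep$degree_case[rep$gene == "B"], 0)
  expect_equal(rep$dif_degree[rep$gene == "B"], -1)
  # identical networks give all-zero differences and no cores
  same <- differentialDegree(netCase, netCase, minDif = 0)
  expect_true(all(same$dif_degree == 0))
  expect_false(any(same$is_core))
  # absolute-value mode can flag control-only hubs
  repAbs <- differentialDegree(netCtrl, netCase, minDif = 5,
                               absolute = TRUE)
  expect_true(repAbs$is_core[repAbs$gene == "A"])
})

test_that("differential degree matches brute-force subtraction on random pairs", {
  set.seed(77)
  for (i in 1:10) {
    e1 <- randomGraphEdges(15, 0.25); e2 <- randomGraphEdges(15, 0.25)
    n1 <- edgeListNetwork(e1); n2 <- edgeListNetwork(e2)
    rep <- differentialDegree(n1, n2, minDif = 2)
    for (g in rep$gene) {
      d1 <- sum(e1$from == g) + sum(e1$to == g)
      d2 <- sum(e2$from == g) + sum(e2$to == g)
      row <- rep[rep$gene == g, ]
      expect_equal(row$dif_degree, d1 - d2)
      expect_equal(row$is_core, (d1 - d2) > 2)
    }
  }
})

test_that("K-core reproduces clique behaviour and the k = 0 identity", {
  tri <- edgeListNetwork(data.frame(from = c("A", "B", "C"),
                                    to = c("B", "C", "A")))
  expect_setequal(networkNodes(kCore(tri, 2))$gene, c("A", "B", "C"))
  expect_equal(nrow(networkNodes(kCore(tri, 3))), 0)
  expect_identical(kCore(tri, 0), tri)
})

test_that("K-core agrees with graph coreness and is nested and maximal", {
  skip_if_not_installed("igraph")
  set.seed(55)
  for (i in 1:100) {
    e <- randomGraphEdges(sample(10:50, 1), runif(1, 0.05, 0.3))
    if (!nrow(e)) next
    net <- edgeListNetwork(e)
    ig <- igraph::graph_from_data_frame(e, directed = FALSE,
                                        vertices = networkNodes(net)$gene)
    core <- igraph::coreness(ig)
    for (k in 1:3) {
      sub <- kCore(net, k)
      expect_setequal(networkNodes(sub)$gene, names(core)[core >= k])
      # every surviving node meets the condition inside the subnetwork
      if (nrow(networkNodes(sub)))
        expect_true(all(networkNodes(sub)$degree >= k))
    }
    expect_true(all(networkNodes(kCore(net, 2))$gene %in%
                      networkNodes(kCore(net, 1))$gene))
  }
})

test_that("on planted case-only modules the hub leads the dif-degree ranking", {
  nSeeds <- 10
  hits <- 0
  for (seed in seq_len(nSeeds)) {
    p <- SimulationParams(nGenes = 500L, nGenotypeDe = 0L,
                          nLpsSpecific = 0L, nHmgb1Specific = 0L,
                          nSharedResponders = 0L, nModules = 1L,
                          moduleSize = 31L, moduleCells = "JS1.PBS",
                          seed = seed)
    sim <- simulateHscData(p)
    e <- sim$experiment
    genes <- c(sim$truth@moduleMembers$M1, rownames(e)[100:199])
    case <- suppressWarnings(buildCoexpressionNet(
      e, cellSamples(e, "JS1.PBS"), unique(genes)))
    ctrl <- suppressWarnings(buildCoexpressionNet(
      e, cellSamples(e, "JS2.PBS"), unique(genes)))
    rep <- differentialDegree(case, ctrl, minDif = 5)
    hub <- sim$truth@hubGenes[["JS1.PBS"]]
    hits <- hits + (hub %in% rep$gene[1:5])
  }
  expect_gte(hits / nSeeds, 0.9)
})
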