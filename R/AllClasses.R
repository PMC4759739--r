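#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importMethodsFrom SummarizedExperiment assay assayNames colData "assay<-"
#' @importFrom stats cor df median p.adjust phyper pt quantile rchisq rnorm
#'   runif sd setNames var
#' @importFrom utils read.delim write.table head
NULL

CELL_LINES <- c("JS1", "JS2")
TREATMENTS <- c("PBS", "LPS", "HMGB1")

#' Design cell labels of the two-genotype, three-treatment layout
#'
#' The six design cells are the Cartesian product of cell line (JS1 =
#' TLR4 wild type, JS2 = TLR4 null) and treatment (PBS vehicle, LPS,
#' HMGB1), labelled `"JS1.PBS"`, `"JS1.LPS"`, ... in a fixed order.
#'
#' @return Character vector of the six design-cell labels.
#' @export
designCells <- function() {
  as.vector(outer(TREATMENTS, CELL_LINES, function(t, c) paste(c, t, sep = ".")))
}

# ---------------------------------------------------------------------------
# HscExperiment: genes x samples log2 intensities + design annotations
# ---------------------------------------------------------------------------

#' HscExperiment: expression matrix with the two-genotype design
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] that
#' requires a single `"exprs"` assay of finite log2 intensities and a
#' `colData` carrying `cell_line` (JS1/JS2), `treatment` (PBS/LPS/HMGB1)
#' and `replicate` columns — the layout every downstream statistical
#' stage consumes.
#'
#' @slot .Data inherited SummarizedExperiment contents.
#' @export
setClass("HscExperiment", contains = "SummarizedExperiment")

setValidity("HscExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (any(!is.finite(x)))
      msg <- c(msg, "assay 'exprs' contains non-finite values")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("cell_line", "treatment", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks column(s): ", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (!all(cd$cell_line %in% CELL_LINES))
      msg <- c(msg, "cell_line values must be JS1 or JS2")
    if (!all(cd$treatment %in% TREATMENTS))
      msg <- c(msg, "treatment values must be PBS, LPS or HMGB1")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct an HscExperiment
#'
#' @param exprs numeric matrix of log2 intensities, genes in rows (rownames
#'   = gene ids), samples in columns (colnames = sample ids).
#' @param design data.frame with columns `sample_id`, `cell_line`,
#'   `treatment`, `replicate`; rows are matched to `colnames(exprs)`.
#' @return An [HscExperiment-class] object.
#' @examples
#' d <- data.frame(sample_id = c("a", "b"), cell_line = "JS1",
#'                 treatment = c("PBS", "LPS"), replicate = 1L)
#' m <- matrix(rnorm(4), 2, 2, dimnames = list(c("g1", "g2"), c("a", "b")))
#' HscExperiment(m, d)
#' @export
HscExperiment <- function(exprs, design) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)), !is.null(colnames(exprs)))
  if (!all(colnames(exprs) %in% design$sample_id))
    stop("every sample in the matrix must appear in the design table")
  design <- design[match(colnames(exprs), design$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(cell_line = design$cell_line,
                             treatment = design$treatment,
                             replicate = as.integer(design$replicate),
                             row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("HscExperiment", se)
}

#' @describeIn HscExperiment log2 intensity matrix accessor.
#' @param object an HscExperiment.
#' @export
exprs <- function(object) SummarizedExperiment::assay(object, "exprs")

#' Sample ids belonging to one design cell
#'
#' @param object an [HscExperiment-class].
#' @param cell design-cell label, e.g. `"JS1.LPS"` (see [designCells()]).
#' @return character vector of sample ids.
#' @export
cellSamples <- function(object, cell) {
  parts <- strsplit(cell, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L || !parts[1] %in% CELL_LINES || !parts[2] %in% TREATMENTS)
    stop("unknown design cell: ", cell)
  cd <- SummarizedExperiment::colData(object)
  rownames(cd)[cd$cell_line == parts[1] & cd$treatment == parts[2]]
}

# ---------------------------------------------------------------------------
# SimulationParams
# ---------------------------------------------------------------------------

#' Parameters of the synthetic study-design generator
#'
#' Defaults emulate a two cell line x three treatment microarray screen:
#' planted genotype main effects, genotype-by-treatment interaction
#' effects (LPS-specific, HMGB1-specific and shared responders confined
#' to the TLR4-intact line), hub-anchored co-expression modules present
#' in a single design cell, and gene sets enriched for planted
#' responders.
#'
#' @slot nGenes number of genes on the simulated array.
#' @slot replicatesPerCell biological replicates per design cell (>= 2).
#' @slot baselineRange log2 intensity range for baseline gene means.
#' @slot noiseSd residual Gaussian noise SD, log2 units.
#' @slot nGenotypeDe genes with a JS1-vs-JS2 baseline offset.
#' @slot nLpsSpecific genes shifted only in (JS1, LPS).
#' @slot nHmgb1Specific genes shifted only in (JS1, HMGB1).
#' @slot nSharedResponders genes shifted in both JS1 treated cells.
#' @slot effectSizeLog2 magnitude of every planted shift (sign alternates
#'   with gene index so both directions are exercised).
#' @slot nModules number of planted co-expression modules.
#' @slot moduleSize members per module including its hub.
#' @slot moduleCells design cell carrying each module (recycled).
#' @slot latentFactorSd SD of the per-module latent factor (the hub's
#'   own expression fluctuation; default 0.5, twice the noise SD, the
#'   regime in which member-member correlations straddle the default
#'   co-expression gate while hub links sit above it, making the hub a
#'   recoverable degree hub).
#' @slot nGeneSets total number of gene sets generated.
#' @slot nEnrichedSets how many of them are planted as enriched.
#' @slot setSize members per gene set.
#' @slot enrichedSetOverlap fraction of an enriched set drawn from the
#'   planted treatment-responsive pool.
#' @slot relationDensity background density of the typed relation table.
#' @slot hubRelationDegree relation partners wired to each planted hub.
#' @slot seed master RNG seed.
#' @export
setClass("SimulationParams", representation(
  nGenes = "integer", replicatesPerCell = "integer",
  baselineRange = "numeric", noiseSd = "numeric",
  nGenotypeDe = "integer", nLpsSpecific = "integer",
  nHmgb1Specific = "integer", nSharedResponders = "integer",
  effectSizeLog2 = "numeric",
  nModules = "integer", moduleSize = "integer", moduleCells = "character",
  latentFactorSd = "numeric",
  nGeneSets = "integer", nEnrichedSets = "integer", setSize = "integer",
  enrichedSetOverlap = "numeric",
  relationDensity = "numeric", hubRelationDegree = "integer",
  seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  planted <- object@nGenotypeDe + object@nLpsSpecific +
    object@nHmgb1Specific + object@nSharedResponders +
    object@nModules * object@moduleSize
  if (planted > object@nGenes)
    msg <- c(msg, "planted gene counts exceed nGenes")
  if (object@replicatesPerCell < 2L)
    msg <- c(msg, "replicatesPerCell must be >= 2")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@latentFactorSd < 0) msg <- c(msg, "latentFactorSd must be >= 0")
  if (object@enrichedSetOverlap < 0 || object@enrichedSetOverlap > 1)
    msg <- c(msg, "enrichedSetOverlap must be in [0, 1]")
  if (length(object@baselineRange) != 2L ||
      diff(object@baselineRange) < 0)
    msg <- c(msg, "baselineRange must be an increasing length-2 interval")
  if (object@nEnrichedSets > object@nGeneSets)
    msg <- c(msg, "nEnrichedSets cannot exceed nGeneSets")
  if (!all(object@moduleCells %in% designCells()))
    msg <- c(msg, "moduleCells must be design-cell labels")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationParams-class
#' @param nGenes,replicatesPerCell,baselineRange,noiseSd,nGenotypeDe,nLpsSpecific,nHmgb1Specific,nSharedResponders,effectSizeLog2,nModules,moduleSize,moduleCells,latentFactorSd,nGeneSets,nEnrichedSets,setSize,enrichedSetOverlap,relationDensity,hubRelationDegree,seed see slot documentation.
#' @return A validated `SimulationParams` object.
#' @examples
#' SimulationParams(nGenes = 500, seed = 1)
#' @export
SimulationParams <- function(nGenes = 2000L, replicatesPerCell = 8L,
                             baselineRange = c(4, 14), noiseSd = 0.25,
                             nGenotypeDe = 100L, nLpsSpecific = 80L,
                             nHmgb1Specific = 80L, nSharedResponders = 60L,
                             effectSizeLog2 = 1.0,
                             nModules = 2L, moduleSize = 31L,
                             moduleCells = c("JS1.PBS", "JS1.LPS"),
                             latentFactorSd = 0.5,
                             nGeneSets = 52L, nEnrichedSets = 2L,
                             setSize = 20L, enrichedSetOverlap = 0.8,
                             relationDensity = 0.001,
                             hubRelationDegree = 10L,
                             seed = 1L) {
  new("SimulationParams",
      nGenes = as.integer(nGenes),
      replicatesPerCell = as.integer(replicatesPerCell),
      baselineRange = as.numeric(baselineRange), noiseSd = noiseSd,
      nGenotypeDe = as.integer(nGenotypeDe),
      nLpsSpecific = as.integer(nLpsSpecific),
      nHmgb1Specific = as.integer(nHmgb1Specific),
      nSharedResponders = as.integer(nSharedResponders),
      effectSizeLog2 = effectSizeLog2,
      nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
      moduleCells = rep_len(moduleCells, max(1L, as.integer(nModules))),
      latentFactorSd = latentFactorSd,
      nGeneSets = as.integer(nGeneSets),
      nEnrichedSets = as.integer(nEnrichedSets),
      setSize = as.integer(setSize),
      enrichedSetOverlap = enrichedSetOverlap,
      relationDensity = relationDensity,
      hubRelationDegree = as.integer(hubRelationDegree),
      seed = as.integer(seed))
}

# ---------------------------------------------------------------------------
# GroundTruth
# ---------------------------------------------------------------------------

#' Planted truth of a synthetic dataset
#'
#' Records what the generator planted so recovery can be scored:
#' per-contrast up/down DE gene sets, module hubs per design cell,
#' module memberships, planted-enriched gene-set ids, and the Venn
#' category each treatment-responsive gene belongs to.
#'
#' @slot deGenes named list, one element per contrast label, each a
#'   `list(up=, down=)` of gene ids.
#' @slot hubGenes named list mapping design cell to its hub genes.
#' @slot moduleMembers named list mapping module id to member genes.
#' @slot enrichedSets character vector of planted-enriched set ids.
#' @slot vennCategory named character vector, gene -> category label
#'   (`tlr4_lps_specific`, `tlr4_hmgb1_specific`, `tlr4_common`).
#' @export
setClass("GroundTruth", representation(
  deGenes = "list", hubGenes = "list", moduleMembers = "list",
  enrichedSets = "character", vennCategory = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  for (ct in names(object@deGenes)) {
    el <- object@deGenes[[ct]]
    if (!all(c("up", "down") %in% names(el)))
      msg <- c(msg, paste0("contrast ", ct, " lacks up/down components"))
    else if (length(intersect(el$up, el$down)))
      msg <- c(msg, paste0("contrast ", ct, ": up and down sets overlap"))
  }
  hubs <- unlist(object@hubGenes, use.names = FALSE)
  if (length(hubs) && !all(hubs %in% unlist(object@moduleMembers, use.names = FALSE)))
    msg <- c(msg, "every hub gene must be a member of some module")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ModerationFit
# ---------------------------------------------------------------------------

#' Empirical-Bayes variance-moderation fit
#'
#' The inverse-chi-square prior on gene-wise residual variances estimated
#' by the method of moments on log variances: prior degrees of freedom
#' `d0` (`Inf` means complete pooling to the prior variance), prior
#' variance `s0sq` (log2-units squared), and the per-gene residual
#' degrees of freedom and variances the fit was computed from.
#'
#' @slot d0 prior degrees of freedom (non-negative, possibly `Inf`; 0
#'   disables shrinkage entirely).
#' @slot s0sq prior variance.
#' @slot dg residual degrees of freedom per gene (common to all genes in
#'   a two-group fit).
#' @slot s2g named numeric vector of gene-wise pooled residual variances.
#' @export
setClass("ModerationFit", representation(
  d0 = "numeric", s0sq = "numeric", dg = "numeric", s2g = "numeric"))

setValidity("ModerationFit", function(object) {
  msg <- character()
  if (!(object@d0 >= 0)) msg <- c(msg, "d0 must be >= 0")
  if (!(object@s0sq > 0)) msg <- c(msg, "s0sq must be > 0")
  if (any(object@s2g < 0)) msg <- c(msg, "residual variances must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# GeneSetCollection
# ---------------------------------------------------------------------------

#' A named collection of gene sets over a declared universe
#'
#' GMT-backed container used for GO-style and pathway-style
#' over-representation alike. Members are restricted to the universe at
#' construction; empty sets are rejected.
#'
#' @slot universe character vector of all genes under consideration.
#' @slot sets named list of character vectors (set members).
#' @slot descriptions named character vector, one free-text description
#'   per set.
#' @export
setClass("GeneSetCollection", representation(
  universe = "character", sets = "list", descriptions = "character"))

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (anyDuplicated(names(object@sets)))
    msg <- c(msg, "set ids must be unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "empty gene sets are not allowed")
  if (length(object@sets) &&
      !all(unlist(object@sets, use.names = FALSE) %in% object@universe))
    msg <- c(msg, "set members must lie in the universe")
  if (length(object@sets) &&
      !identical(sort(names(object@sets)), sort(names(object@descriptions))))
    msg <- c(msg, "descriptions must be named like the sets")
  if (anyDuplicated(object@universe))
    msg <- c(msg, "universe genes must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets named list of character vectors of gene ids.
#' @param universe gene universe; members outside it are dropped, and
#'   sets emptied by the restriction are removed.
#' @param descriptions optional named character vector of descriptions.
#' @return A `GeneSetCollection`.
#' @examples
#' GeneSetCollection(list(S1 = c("g1", "g2")), universe = paste0("g", 1:5))
#' @export
GeneSetCollection <- function(sets, universe, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)) || length(sets) == 0L)
  sets <- lapply(sets, function(s) unique(intersect(s, universe)))
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(sets)), names(sets))
  else descriptions <- descriptions[names(sets)]
  new("GeneSetCollection", universe = unique(universe), sets = sets,
      descriptions = descriptions)
}

#' @describeIn GeneSetCollection number of sets.
#' @param x a GeneSetCollection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Accessors for GeneSetCollection
#'
#' @param object a [GeneSetCollection-class].
#' @return `geneSets()` the named list of member vectors; `universe()`
#'   the gene universe; `setDescriptions()` the description vector.
#' @export
geneSets <- function(object) object@sets

#' @rdname geneSets
#' @export
universe <- function(object) object@universe

#' @rdname geneSets
#' @export
setDescriptions <- function(object) object@descriptions

# ---------------------------------------------------------------------------
# RelationTable
# ---------------------------------------------------------------------------

RELATION_TYPES <- c("activation", "inhibition", "compound")

#' Typed gene-gene relation table
#'
#' Curated relations of the kind a pathway database provides: activation
#' (arrow), inhibition (blunt arrow) and compound (shared-compound)
#' edges between genes. Self-relations are rejected unless explicitly
#' allowed.
#'
#' @slot edges data.frame with columns `source`, `relation_type`,
#'   `target`.
#' @export
setClass("RelationTable", representation(edges = "data.frame"))

setValidity("RelationTable", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("source", "relation_type", "target") %in% colnames(e)))
    msg <- c(msg, "edges need columns source, relation_type, target")
  else {
    if (!all(e$relation_type %in% RELATION_TYPES))
      msg <- c(msg, paste0("relation_type must be one of: ",
                           paste(RELATION_TYPES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname RelationTable-class
#' @param edges data.frame with columns `source`, `relation_type`
#'   (activation/inhibition/compound) and `target`.
#' @param allowSelf keep self-relations? Default drops them with a
#'   warning.
#' @return A `RelationTable`.
#' @export
RelationTable <- function(edges = data.frame(source = character(),
                                             relation_type = character(),
                                             target = character()),
                          allowSelf = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) && !allowSelf) {
    self <- edges$source == edges$target
    if (any(self)) {
      warning(sum(self), " self-relation(s) dropped")
      edges <- edges[!self, , drop = FALSE]
    }
  }
  rownames(edges) <- NULL
  new("RelationTable", edges = edges)
}

#' @describeIn RelationTable the edge data.frame.
#' @param object a RelationTable.
#' @export
relations <- function(object) object@edges

#' @describeIn RelationTable number of relations.
#' @param x a RelationTable.
#' @export
setMethod("length", "RelationTable", function(x) nrow(x@edges))

# ---------------------------------------------------------------------------
# GeneNetwork
# ---------------------------------------------------------------------------

#' Gene network shared by gene-act-nets and co-expression nets
#'
#' Nodes carry a DE direction and their degree; edges carry either a
#' relation type (gene-act-net) or a Pearson correlation and its P value
#' (co-expression net). Co-expression edges are undirected and
#' deduplicated; degree counts each distinct partner once (parallel
#' typed edges between a pair collapse to one for degree purposes).
#'
#' @slot nodes data.frame with columns `gene`, `de_direction`, `degree`.
#' @slot edges data.frame with columns `from`, `to`, `type`, `r`, `p`
#'   (unused attributes are `NA`).
#' @slot directed logical; `TRUE` for gene-act-nets.
#' @export
setClass("GeneNetwork", representation(
  nodes = "data.frame", edges = "data.frame", directed = "logical"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  n <- object@nodes; e <- object@edges
  if (!all(c("gene", "de_direction", "degree") %in% colnames(n)))
    msg <- c(msg, "nodes need columns gene, de_direction, degree")
  if (!all(c("from", "to", "type", "r", "p") %in% colnames(e)))
    msg <- c(msg, "edges need columns from, to, type, r, p")
  if (nrow(e) && nrow(n) && !all(c(e$from, e$to) %in% n$gene))
    msg <- c(msg, "edge endpoints must be nodes")
  if (nrow(n) && anyDuplicated(n$gene))
    msg <- c(msg, "node genes must be unique")
  if (length(msg)) msg else TRUE
})

edgeKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Construct a GeneNetwork from node and edge tables
#'
#' Normalizes the edge table to the canonical columns (`from`, `to`,
#' `type`, `r`, `p`), collapses parallel edges between the same
#' unordered node pair, and recomputes node degrees as the number of
#' distinct partners.
#'
#' @param nodes data.frame with at least a `gene` column; a
#'   `de_direction` column defaults to `"none"`.
#' @param edges data.frame with `from` and `to` columns; `type`, `r`,
#'   `p` are filled in when absent.
#' @param directed logical scalar recorded on the network.
#' @return A [GeneNetwork-class].
#' @export
newGeneNetwork <- function(nodes, edges, directed) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"de_direction" %in% colnames(nodes))
    nodes$de_direction <- rep("none", nrow(nodes))
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  for (col in c("from", "to", "type")) if (!col %in% colnames(edges))
    edges[[col]] <- character(nrow(edges))
  for (col in c("r", "p")) if (!col %in% colnames(edges))
    edges[[col]] <- rep(NA_real_, nrow(edges))
  edges <- edges[, c("from", "to", "type", "r", "p"), drop = FALSE]
  # unordered deduplication: one edge per node pair for degree purposes
  if (nrow(edges)) edges <- edges[!duplicated(edgeKey(edges$from, edges$to)), , drop = FALSE]
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$gene))
  nodes$degree <- as.integer(deg[nodes$gene])
  rownames(nodes) <- NULL; rownames(edges) <- NULL
  new("GeneNetwork", nodes = nodes, edges = edges, directed = directed)
}

#' Accessors for GeneNetwork
#'
#' @param object a [GeneNetwork-class].
#' @return `networkNodes()` the node data.frame; `networkEdges()` the
#'   edge data.frame; `nodeDegrees()` a named integer vector of degrees.
#' @export
networkNodes <- function(object) object@nodes

#' @rdname networkNodes
#' @export
networkEdges <- function(object) object@edges

#' @rdname networkNodes
#' @export
nodeDegrees <- function(object)
  setNames(object@nodes$degree, object@nodes$gene)
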