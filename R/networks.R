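# Gene-act-networks from typed relation tables and per-condition
# Pearson co-expression networks, with the hub statistics the screen
# relies on: degree centrality, differential degree between case and
# control networks, and K-core decomposition.

#' Induce a gene-act-network over a gene list
#'
#' Restricts a typed relation table to the edges whose endpoints both
#' lie in `genes` (typically one contrast's DE genes), annotates nodes
#' with their DE direction, and computes degrees. Parallel relations
#' between the same pair collapse to one edge, so degree counts
#' distinct partners ("the link numbers one node has").
#'
#' @param genes character vector of genes to induce on.
#' @param deDirections optional named character vector gene ->
#'   `"up"`/`"down"`; unnamed genes get `"none"`.
#' @param relationTable a [RelationTable-class].
#' @param keepIsolated keep genes with no incident relation as
#'   degree-zero nodes? Default drops them.
#' @return A directed [GeneNetwork-class] with `type` edge attributes.
#' @export
induceGeneActNet <- function(genes, deDirections = NULL, relationTable,
                             keepIsolated = FALSE) {
  e <- relations(relationTable)
  e <- e[e$source %in% genes & e$target %in% genes, , drop = FALSE]
  nodeGenes <- if (keepIsolated) unique(genes) else
    unique(c(e$source, e$target))
  dirs <- setNames(rep("none", length(nodeGenes)), nodeGenes)
  if (!is.null(deDirections)) {
    known <- intersect(nodeGenes, names(deDirections))
    dirs[known] <- unname(deDirections[known])
  }
  nodes <- data.frame(gene = nodeGenes, de_direction = unname(dirs),
                      degree = integer(length(nodeGenes)),
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = e$source, to = e$target,
                      type = e$relation_type, stringsAsFactors = FALSE)
  newGeneNetwork(nodes, edges, directed = TRUE)
}

#' Select core genes of a network by degree centrality
#'
#' @param net a [GeneNetwork-class].
#' @param minDegree strict threshold: genes with degree > `minDegree`
#'   are cores (the baseline genotype comparison uses 5, the treatment
#'   comparisons 3).
#' @return Character vector sorted by degree descending, ties
#'   lexicographic.
#' @export
selectCoreGenes <- function(net, minDegree) {
  stopifnot(minDegree >= 0)
  n <- networkNodes(net)
  n <- n[n$degree > minDegree, , drop = FALSE]
  n <- n[order(-n$degree, n$gene), , drop = FALSE]
  n$gene
}

#' Build a Pearson co-expression network within one condition
#'
#' Computes all pairwise Pearson correlations of `genes` across
#' `samples` and keeps an undirected edge where `|r| >= rMin` and the
#' two-sided P of `t = r sqrt((m-2)/(1-r^2))` on `m - 2` df is below
#' `pMax` (`m` = number of samples). Genes with constant expression are
#' excluded with a warning (their correlation is undefined); they do
#' not appear as nodes.
#'
#' @param x numeric matrix (genes x samples) or [HscExperiment-class].
#' @param samples character vector of sample ids (>= 3).
#' @param genes genes to correlate; default all rows.
#' @param rMin absolute-correlation gate (default 0.8).
#' @param pMax significance gate on the correlation P (default 0.05).
#' @return An undirected [GeneNetwork-class] with `r` and `p` edge
#'   attributes.
#' @export
setGeneric("buildCoexpressionNet",
           function(x, samples, genes = NULL, rMin = 0.8, pMax = 0.05)
             standardGeneric("buildCoexpressionNet"))

#' @rdname buildCoexpressionNet
#' @export
setMethod("buildCoexpressionNet", "matrix",
          function(x, samples, genes = NULL, rMin = 0.8, pMax = 0.05) {
  if (length(samples) < 3L)
    stop("correlation undefined: need at least 3 samples")
  if (is.null(genes)) genes <- rownames(x)
  if (!all(genes %in% rownames(x))) stop("genes missing from the matrix")
  if (!all(samples %in% colnames(x))) stop("samples missing from the matrix")
  sub <- x[genes, samples, drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) excluded from the network")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  g <- rownames(sub)
  m <- length(samples)
  edges <- data.frame(from = character(), to = character(), r = numeric(),
                      p = numeric(), stringsAsFactors = FALSE)
  if (length(g) >= 2L) {
    cm <- cor(t(sub))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[idx]
    tstat <- r * sqrt((m - 2) / pmax(1 - r^2, 0))
    p <- 2 * pt(-abs(tstat), df = m - 2)
    p[abs(r) == 1] <- 0  # |r| = 1 gives an infinite t
    keep <- abs(r) >= rMin & p < pMax
    edges <- data.frame(from = g[idx[keep, 1]], to = g[idx[keep, 2]],
                        r = r[keep], p = p[keep], stringsAsFactors = FALSE)
  }
  nodes <- data.frame(gene = g, de_direction = "none", degree = 0L,
                      stringsAsFactors = FALSE)
  newGeneNetwork(nodes, edges, directed = FALSE)
})

#' @rdname buildCoexpressionNet
#' @export
setMethod("buildCoexpressionNet", "HscExperiment",
          function(x, samples, genes = NULL, rMin = 0.8, pMax = 0.05)
            buildCoexpressionNet(exprs(x), samples, genes, rMin, pMax))

#' Differential degree between case and control networks
#'
#' For every gene in either network, the difference of its degrees
#' (case minus control; a gene absent from a network has degree 0) —
#' the core-regulator statistic of differential co-expression analysis.
#'
#' @param netCase,netControl [GeneNetwork-class] objects.
#' @param minDif strict core threshold on the difference.
#' @param absolute select cores on `|dif_degree|` instead of the signed
#'   value (default `FALSE`).
#' @return A `data.frame` with columns `gene`, `degree_case`,
#'   `degree_control`, `dif_degree`, `is_core`, sorted by `dif_degree`
#'   descending (absolute value when `absolute = TRUE`).
#' @export
differentialDegree <- function(netCase, netControl, minDif,
                               absolute = FALSE) {
  dc <- nodeDegrees(netCase); dk <- nodeDegrees(netControl)
  genes <- union(names(dc), names(dk))
  getd <- function(d, g) ifelse(g %in% names(d), d[g], 0L)
  rep <- data.frame(gene = genes,
                    degree_case = as.integer(getd(dc, genes)),
                    degree_control = as.integer(getd(dk, genes)),
                    stringsAsFactors = FALSE, row.names = NULL)
  rep$dif_degree <- rep$degree_case - rep$degree_control
  score <- if (absolute) abs(rep$dif_degree) else rep$dif_degree
  rep$is_core <- score > minDif
  rep[order(-score, rep$gene), , drop = FALSE]
}

#' K-core of a network
#'
#' The maximal subnetwork in which every node is connected to at least
#' `k` other genes within the subnetwork, obtained by iterated removal
#' of nodes of degree < `k` until a fixpoint. May be empty; `k = 0`
#' returns the network unchanged.
#'
#' @param net a [GeneNetwork-class].
#' @param k non-negative integer.
#' @return A [GeneNetwork-class], the K-core.
#' @export
kCore <- function(net, k) {
  stopifnot(k >= 0)
  if (k == 0) return(net)
  nodes <- networkNodes(net); edges <- networkEdges(net)
  repeat {
    deg <- table(factor(c(edges$from, edges$to), levels = nodes$gene))
    drop <- nodes$gene[as.integer(deg[nodes$gene]) < k]
    if (!length(drop)) break
    nodes <- nodes[!nodes$gene %in% drop, , drop = FALSE]
    edges <- edges[!(edges$from %in% drop) & !(edges$to %in% drop), ,
                   drop = FALSE]
    if (!nrow(nodes)) break
  }
  newGeneNetwork(nodes, edges, directed = net@directed)
}
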