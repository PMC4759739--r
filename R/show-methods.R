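#' @describeIn SimulationParams-class compact display.
#' @param object a SimulationParams.
#' @export
setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", object@nGenes, "genes x",
      6L * object@replicatesPerCell, "samples (",
      object@replicatesPerCell, "replicates / design cell )\n")
  cat("  planted DE: genotype", object@nGenotypeDe,
      "| LPS-specific", object@nLpsSpecific,
      "| HMGB1-specific", object@nHmgb1Specific,
      "| shared", object@nSharedResponders,
      "| effect", object@effectSizeLog2, "log2\n")
  cat("  modules:", object@nModules, "x", object@moduleSize,
      "in", paste(object@moduleCells, collapse = ", "),
      "| gene sets:", object@nGeneSets,
      "(", object@nEnrichedSets, "enriched ) | seed", object@seed, "\n")
})

#' @describeIn GroundTruth-class compact display.
#' @param object a GroundTruth.
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:\n  contrasts:",
      paste(sprintf("%s (%d up / %d down)", names(object@deGenes),
                    vapply(object@deGenes, function(x) length(x$up), 1L),
                    vapply(object@deGenes, function(x) length(x$down), 1L)),
            collapse = ", "), "\n")
  cat("  modules:", length(object@moduleMembers),
      "| hubs:", length(unlist(object@hubGenes)),
      "| enriched sets:", length(object@enrichedSets),
      "| categorised genes:", length(object@vennCategory), "\n")
})

#' @describeIn ModerationFit-class compact display.
#' @param object a ModerationFit.
#' @export
setMethod("show", "ModerationFit", function(object) {
  cat("ModerationFit: d0 =", format(object@d0),
      ", s0^2 =", format(object@s0sq),
      ", dg =", object@dg[1], ",", length(object@s2g), "genes\n")
})

#' @describeIn GeneSetCollection-class compact display.
#' @param object a GeneSetCollection.
#' @export
setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection:", length(object@sets), "sets over",
      length(object@universe), "universe genes; set sizes",
      if (length(object@sets))
        paste0("[", min(lengths(object@sets)), ", ",
               max(lengths(object@sets)), "]") else "[]", "\n")
})

#' @describeIn RelationTable-class compact display.
#' @param object a RelationTable.
#' @export
setMethod("show", "RelationTable", function(object) {
  tab <- table(factor(object@edges$relation_type, levels = RELATION_TYPES))
  cat("RelationTable:", nrow(object@edges), "relations (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

#' @describeIn GeneNetwork-class compact display.
#' @param object a GeneNetwork.
#' @export
setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork (", if (object@directed) "directed" else "undirected",
      "):", nrow(object@nodes), "nodes,", nrow(object@edges), "edges")
  if (nrow(object@nodes))
    cat("; max degree", max(object@nodes$degree))
  cat("\n")
})
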