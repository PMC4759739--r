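# Plain-text readers and writers for every interchange format of the
# pipeline: expression TSV, design TSV, GMT gene sets, SIF-like typed
# relation tables, network edge/node tables, DE tables, and JSON for
# ground truth and summaries. All writes round-trip through the readers.

stopParse <- function(path, line, what)
  stop("parse error in ", path, if (!is.na(line)) paste0(", line ", line),
       ": ", what, call. = FALSE)

#' Read and write expression matrices
#'
#' Tab-separated, first column `gene_id`, remaining columns one per
#' sample. Values must be numeric and finite; duplicate gene ids are a
#' data error.
#'
#' @param path file path.
#' @return `readExpressionMatrix()` a numeric matrix with gene rownames
#'   and sample colnames.
#' @export
readExpressionMatrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene_id")
    stopParse(path, 1, "first column must be gene_id")
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene id in ", path, ": ",
         df$gene_id[duplicated(df$gene_id)][1])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(m), nrow = nrow(m)))) & !is.na(m), arr.ind = TRUE)
    r <- if (nrow(bad)) bad[1, 1] else 1L
    c <- if (nrow(bad)) bad[1, 2] else 1L
    stopParse(path, r + 1L, paste0("non-numeric value in row ", df$gene_id[r],
                                   ", column ", colnames(m)[c]))
  }
  rownames(m) <- df$gene_id
  m
}

#' @rdname readExpressionMatrix
#' @param x numeric matrix, gene rownames, sample colnames.
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample design tables
#'
#' Tab-separated with columns `sample_id`, `cell_line`, `treatment`,
#' `replicate`.
#'
#' @param path file path.
#' @return `readDesign()` a data.frame.
#' @export
readDesign <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "cell_line", "treatment", "replicate")
  if (!all(need %in% colnames(df)))
    stopParse(path, NA, paste0("design needs columns: ",
                               paste(need, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id in ", path)
  df
}

#' @rdname readDesign
#' @param experiment an [HscExperiment-class].
#' @export
writeDesign <- function(experiment, path) {
  cd <- SummarizedExperiment::colData(experiment)
  df <- data.frame(sample_id = rownames(cd), cell_line = cd$cell_line,
                   treatment = cd$treatment, replicate = cd$replicate,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an HscExperiment from matrix + design files
#'
#' @param matrixPath,designPath TSV paths per [readExpressionMatrix()]
#'   and [readDesign()].
#' @return An [HscExperiment-class].
#' @export
readHscExperiment <- function(matrixPath, designPath)
  HscExperiment(readExpressionMatrix(matrixPath), readDesign(designPath))

#' Read and write GMT gene-set collections
#'
#' Standard GMT: one set per line, `set_id TAB description TAB gene...`.
#' On read the universe defaults to the union of all members unless
#' given.
#'
#' @param path file path.
#' @param universe optional gene universe; defaults to the union of
#'   members.
#' @return `readGMT()` a [GeneSetCollection-class].
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopParse(path, i, "GMT line needs set_id, description, >= 1 gene")
    if (f[1] %in% names(sets))
      stopParse(path, i, paste0("duplicate set id ", f[1]))
    sets[[f[1]]] <- f[-(1:2)]
    desc[f[1]] <- f[2]
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  GeneSetCollection(sets, universe, desc)
}

#' @rdname readGMT
#' @param collection a [GeneSetCollection-class].
#' @export
writeGMT <- function(collection, path) {
  ids <- names(geneSets(collection))
  lines <- vapply(ids, function(id)
    paste(c(id, setDescriptions(collection)[[id]],
            geneSets(collection)[[id]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write SIF-like typed relation tables
#'
#' Tab-separated triples `source TAB relation_type TAB target` with
#' relation types activation, inhibition or compound. No header.
#'
#' @param path file path.
#' @return `readRelations()` a [RelationTable-class].
#' @export
readRelations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(RelationTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stopParse(path, bad[1], "relation line needs source, type, target")
  e <- data.frame(source = vapply(parts, `[`, "", 1),
                  relation_type = vapply(parts, `[`, "", 2),
                  target = vapply(parts, `[`, "", 3),
                  stringsAsFactors = FALSE)
  if (!all(e$relation_type %in% RELATION_TYPES))
    stopParse(path, which(!e$relation_type %in% RELATION_TYPES)[1],
              "unknown relation type")
  RelationTable(e)
}

#' @rdname readRelations
#' @param relationTable a [RelationTable-class].
#' @export
writeRelations <- function(relationTable, path) {
  e <- relations(relationTable)
  writeLines(paste(e$source, e$relation_type, e$target, sep = "\t"), path)
  invisible(path)
}

#' Write a network as a SIF-like edge list plus node attributes
#'
#' Produces `<path>.sif.tsv` (from, interaction, to, r, p) and
#' `<path>.nodes.tsv` (gene, de_direction, degree).
#'
#' @param net a [GeneNetwork-class].
#' @param path output prefix.
#' @return The two file paths, invisibly.
#' @export
writeNetwork <- function(net, path) {
  e <- networkEdges(net)
  ef <- data.frame(from = e$from,
                   interaction = ifelse(nzchar(e$type), e$type, "coexpression"),
                   to = e$to, r = e$r, p = e$p, stringsAsFactors = FALSE)
  sif <- paste0(path, ".sif.tsv"); nod <- paste0(path, ".nodes.tsv")
  write.table(ef, sif, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(networkNodes(net), nod, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(sif, nod))
}

#' Read and write DE tables
#'
#' The TSV twin of the [moderatedTTest()] data.frame.
#'
#' @param path file path.
#' @return `readDETable()` the DE data.frame.
#' @export
readDETable <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' @rdname readDETable
#' @param table a DE data.frame.
#' @export
writeDETable <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write ground truth as JSON
#'
#' @param path file path.
#' @return `readGroundTruth()` a [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  asChr <- function(v) if (is.null(v) || !length(v)) character() else
    as.character(v)
  new("GroundTruth",
      deGenes = lapply(x$de_genes_by_contrast, function(ct)
        list(up = asChr(ct$up), down = asChr(ct$down))),
      hubGenes = lapply(x$hub_genes, asChr),
      moduleMembers = lapply(x$module_members, asChr),
      enrichedSets = asChr(x$enriched_sets),
      vennCategory = unlist(x$venn_category_by_gene) %||%
        setNames(character(), character()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readGroundTruth
#' @param truth a [GroundTruth-class].
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(list(
    de_genes_by_contrast = truth@deGenes,
    hub_genes = truth@hubGenes,
    module_members = truth@moduleMembers,
    enriched_sets = truth@enrichedSets,
    venn_category_by_gene = as.list(truth@vennCategory)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
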