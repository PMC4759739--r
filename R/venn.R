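# Four-set Venn partitioning of the contrast DE lists and the derived
# TLR4-dependent response categories.

#' Partition labelled gene sets into Venn regions
#'
#' Assigns every gene in the union of the input sets to exactly one of
#' the `2^s - 1` non-empty membership-signature regions. Region names
#' join the labels of the sets the region belongs to with `"&"`.
#'
#' @param sets a named list of character vectors with distinct labels.
#' @return Named list of disjoint character vectors covering the union.
#' @examples
#' vennPartition(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
vennPartition <- function(sets) {
  stopifnot(is.list(sets), !is.null(names(sets)),
            !anyDuplicated(names(sets)))
  labels <- names(sets)
  allGenes <- sort(unique(unlist(sets, use.names = FALSE)))
  if (!length(allGenes)) return(setNames(list(), character()))
  member <- vapply(sets, function(s) allGenes %in% s,
                   logical(length(allGenes)))
  member <- matrix(member, nrow = length(allGenes),
                   dimnames = list(allGenes, labels))
  sig <- apply(member, 1, function(row)
    paste(labels[row], collapse = "&"))
  split(allGenes, sig)
}

#' Derive TLR4-dependent response categories from the four contrasts
#'
#' With `L = 1LvsN \ 2LvsN` (genes LPS-responsive only when TLR4 is
#' intact) and `H = 1HvsN \ 2HvsN` (likewise for HMGB1):
#' `tlr4_lps_specific = L \ 1HvsN`, `tlr4_hmgb1_specific = H \ 1LvsN`,
#' and `tlr4_common = L` intersected with `H`. Each category is split
#' into up/down by the JS1 contrast's direction call; for the common
#' category the LPS-contrast direction is used and genes whose LPS and
#' HMGB1 directions disagree are flagged with a message. Genes
#' responding in JS2 belong to no category (TLR4-independent).
#'
#' @param contrasts named list with elements `1LvsN`, `2LvsN`, `1HvsN`,
#'   `2HvsN`, each a `list(up = , down = )` of gene ids (as produced by
#'   [selectDEGenes()]).
#' @return Named list of the three categories, each `list(up, down)`.
#' @export
tlr4Categories <- function(contrasts) {
  need <- c("1LvsN", "2LvsN", "1HvsN", "2HvsN")
  if (!all(need %in% names(contrasts)))
    stop("contrasts must contain: ", paste(need, collapse = ", "))
  for (lab in need)
    if (length(intersect(contrasts[[lab]]$up, contrasts[[lab]]$down)))
      stop("up and down lists overlap in ", lab)
  whole <- lapply(contrasts, function(x) union(x$up, x$down))
  L <- setdiff(whole$`1LvsN`, whole$`2LvsN`)
  H <- setdiff(whole$`1HvsN`, whole$`2HvsN`)
  cat_lps <- setdiff(L, whole$`1HvsN`)
  cat_hmgb1 <- setdiff(H, whole$`1LvsN`)
  cat_common <- intersect(L, H)
  splitBy <- function(genes, contrast) list(
    up = sort(intersect(genes, contrast$up)),
    down = sort(intersect(genes, contrast$down)))
  common <- splitBy(cat_common, contrasts$`1LvsN`)
  discord <- c(intersect(common$up, contrasts$`1HvsN`$down),
               intersect(common$down, contrasts$`1HvsN`$up))
  if (length(discord))
    message(length(discord),
            " common gene(s) have discordant LPS/HMGB1 directions: ",
            paste(head(discord, 5), collapse = ", "))
  list(tlr4_lps_specific = splitBy(cat_lps, contrasts$`1LvsN`),
       tlr4_hmgb1_specific = splitBy(cat_hmgb1, contrasts$`1HvsN`),
       tlr4_common = common)
}

#' Enrichment tables and gene-act-nets per TLR4 response category
#'
#' For each category from [tlr4Categories()], runs signed
#' over-representation of the up and down lists against a gene-set
#' collection and induces a gene-act-network over the category's genes,
#' flagging core genes by degree centrality.
#'
#' @param categories output of [tlr4Categories()].
#' @param collection a [GeneSetCollection-class].
#' @param relationTable a [RelationTable-class].
#' @param minDegree strict core-gene degree threshold (default 5).
#' @param pMax,fdrMax significance gates for enrichment.
#' @return Named list per category:
#'   `list(enrichment = data.frame, network = GeneNetwork,
#'   core_genes = character)`.
#' @export
integrateCategories <- function(categories, collection, relationTable,
                                minDegree = 5L, pMax = 0.05,
                                fdrMax = 0.05) {
  lapply(categories, function(cat) {
    genes <- union(cat$up, cat$down)
    if (!length(genes)) {
      message("empty category: no enrichment or network computed")
      return(list(enrichment = suppressWarnings(
                    enrichGeneSets(character(0), "up", collection)),
                  network = induceGeneActNet(character(), NULL,
                                             relationTable),
                  core_genes = character()))
    }
    enr <- rbind(
      if (length(cat$up))
        suppressWarnings(enrichGeneSets(cat$up, "up", collection,
                                        pMax, fdrMax)),
      if (length(cat$down))
        suppressWarnings(enrichGeneSets(cat$down, "down", collection,
                                        pMax, fdrMax)))
    dirs <- c(setNames(rep("up", length(cat$up)), cat$up),
              setNames(rep("down", length(cat$down)), cat$down))
    net <- induceGeneActNet(genes, dirs, relationTable)
    list(enrichment = enr, network = net,
         core_genes = selectCoreGenes(net, minDegree))
  })
}
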