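#' One-sided hypergeometric over-representation P value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance that a uniformly drawn gene list of size `n` from a
#' universe of `N` genes, `K` of which belong to the set, hits the set
#' `k` or more times. Identical to the one-sided Fisher exact P for the
#' corresponding 2x2 table.
#'
#' @param k observed DE genes in the set (0 <= k <= min(K, n)).
#' @param K set size within the universe.
#' @param n DE list size.
#' @param N universe size.
#' @return The tail probability, a number in (0, 1].
#' @examples
#' hypergeometricPValue(3, 5, 10, 50)
#' @export
hypergeometricPValue <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 1 || k > min(K, n) || K > N || n > N)
    stop("require 0 <= k <= min(K, n), K <= N, n <= N")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' min(1, p_(j) * m / j)`, mapped back to the input order.
#'
#' @param p numeric vector of P values in [0, 1].
#' @return Adjusted values in [0, 1], same order as the input.
#' @export
bhAdjust <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Signed over-representation of DE gene lists in a gene-set collection
#'
#' For one direction (up or down) of a DE screen, tests every gene set
#' with at least one hit for over-representation of the DE list by the
#' hypergeometric tail, reports the signed fold enrichment
#' `+/-(k/n)/(K/N)` (positive for up lists, negative for down), adjusts
#' P values by Benjamini-Hochberg within the direction, and flags sets
#' passing both the P and FDR gates. Genes outside the collection's
#' universe are dropped from the DE list with a message; sets with no
#' hits are neither reported nor counted in the BH family.
#'
#' @param deList character vector of DE genes (one direction).
#' @param direction `"up"` or `"down"`; sets the sign of the fold.
#' @param collection a [GeneSetCollection-class].
#' @param pMax,fdrMax significance gates (defaults 0.05 and 0.05).
#' @return A `data.frame` sorted by P value with columns `set_id`,
#'   `description`, `direction`, `k`, `K`, `n`, `N`, `fold_enrichment`,
#'   `p_value`, `q_value`, `significant`, `dif_genes` (comma-joined).
#' @export
enrichGeneSets <- function(deList, direction = c("up", "down"), collection,
                           pMax = 0.05, fdrMax = 0.05) {
  direction <- match.arg(direction)
  univ <- universe(collection)
  dropped <- setdiff(deList, univ)
  if (length(dropped))
    message(length(dropped), " DE gene(s) outside the universe dropped")
  deList <- unique(intersect(deList, univ))
  empty <- data.frame(set_id = character(), description = character(),
                      direction = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), significant = logical(),
                      dif_genes = character(), stringsAsFactors = FALSE)
  if (!length(deList)) {
    warning("empty DE list: no enrichment computed")
    return(empty)
  }
  N <- length(univ); n <- length(deList)
  sets <- geneSets(collection)
  hits <- lapply(sets, intersect, x = deList)
  keep <- lengths(hits) >= 1L
  if (!any(keep)) return(empty)
  sets <- sets[keep]; hits <- hits[keep]
  k <- lengths(hits); K <- lengths(sets)
  p <- mapply(hypergeometricPValue, k, K, MoreArgs = list(n = n, N = N))
  sign <- if (direction == "up") 1 else -1
  res <- data.frame(
    set_id = names(sets),
    description = unname(setDescriptions(collection)[names(sets)]),
    direction = direction, k = as.integer(k), K = as.integer(K),
    n = n, N = N,
    fold_enrichment = sign * (k / n) / (K / N),
    p_value = p, q_value = bhAdjust(p),
    stringsAsFactors = FALSE, row.names = NULL)
  res$significant <- res$p_value < pMax & res$q_value < fdrMax
  res$dif_genes <- vapply(hits, function(g) paste(sort(g), collapse = ","), "")
  res[order(res$p_value, res$set_id), , drop = FALSE]
}
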