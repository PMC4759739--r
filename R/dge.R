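# Two-group empirical-Bayes moderated t screen.
#
# Gene-wise pooled residual variances s2_g with d_g = nA + nB - 2 df are
# shrunk towards a prior (d0, s0^2) estimated by the method of moments
# on e_g = log s2_g - digamma(d_g/2) + log(d_g/2), whose mean and excess
# variance over trigamma(d_g/2) identify the scaled-inverse-chi-square
# prior. The moderated statistic uses the posterior variance
# (d0 s0^2 + d_g s2_g) / (d0 + d_g) and a Student-t reference with
# d0 + d_g degrees of freedom.

# Newton inversion of the trigamma function on (0, Inf)
trigammaInverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

groupIndices <- function(x, groupA, groupB) {
  a <- match(groupA, colnames(x)); b <- match(groupB, colnames(x))
  if (anyNA(a) || anyNA(b)) stop("group samples not found in the matrix")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 samples")
  list(a = a, b = b)
}

pooledVariances <- function(x, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ssA <- rowSums((x[, ia, drop = FALSE] - rowMeans(x[, ia, drop = FALSE]))^2)
  ssB <- rowSums((x[, ib, drop = FALSE] - rowMeans(x[, ib, drop = FALSE]))^2)
  (ssA + ssB) / (na + nb - 2L)
}

#' Fit the variance-moderation prior for a two-group comparison
#'
#' Estimates the scaled-inverse-chi-square prior `(d0, s0^2)` on
#' gene-wise residual variances by the method of moments on log
#' variances. If the observed spread of log variances does not exceed
#' what sampling alone explains (`var(e) <= trigamma(d_g/2)`), the
#' complete-pooling fit `d0 = Inf` is returned and every gene shares the
#' prior variance. Genes with zero residual variance are retained for
#' moderation but excluded from the moment equations.
#'
#' @param x numeric log2 intensity matrix (genes x samples) or an
#'   [HscExperiment-class].
#' @param groupA,groupB disjoint character vectors of sample ids, each
#'   of size >= 2.
#' @return A [ModerationFit-class].
#' @export
setGeneric("fitModeration", function(x, groupA, groupB)
  standardGeneric("fitModeration"))

#' @rdname fitModeration
#' @export
setMethod("fitModeration", "matrix", function(x, groupA, groupB) {
  idx <- groupIndices(x, groupA, groupB)
  dg <- length(idx$a) + length(idx$b) - 2L
  s2 <- pooledVariances(x, idx$a, idx$b)
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  ok <- is.finite(e)
  if (!any(ok))
    stop("no gene has positive residual variance; nothing to moderate")
  me <- mean(e[ok])
  # a single informative gene cannot identify d0: pool completely
  ve <- if (sum(ok) >= 2L) var(e[ok]) else 0
  target <- ve - trigamma(dg / 2)
  if (target <= 0) {
    d0 <- Inf
    s0sq <- exp(me)
  } else {
    d0 <- 2 * trigammaInverse(target)
    s0sq <- exp(me + digamma(d0 / 2) - log(d0 / 2))
  }
  new("ModerationFit", d0 = d0, s0sq = s0sq, dg = as.numeric(dg), s2g = s2)
})

#' @rdname fitModeration
#' @export
setMethod("fitModeration", "HscExperiment", function(x, groupA, groupB)
  fitModeration(exprs(x), groupA, groupB))

#' Moderated t-test for one two-group contrast
#'
#' Computes, per gene, the log2 fold change `mean(groupA) -
#' mean(groupB)`, the ordinary pooled-variance t, the moderated t based
#' on the posterior variance `(d0 s0^2 + d_g s2_g) / (d0 + d_g)`, the
#' two-sided P value from a Student-t reference with `d0 + d_g` degrees
#' of freedom (normal reference under complete pooling, `d0 = Inf`; at
#' `d0 = 0` the moderated t reduces to the ordinary t), and the
#' Benjamini-Hochberg q value across all genes. The direction call
#' applies the default screen (P < `pMax`, fold change > `minFold`).
#'
#' @inheritParams fitModeration
#' @param fit a [ModerationFit-class]; when `NULL` it is fitted from the
#'   data. Passing `d0 = 0` (no shrinkage) or other fixed priors is
#'   allowed.
#' @param pMax,minFold thresholds forwarded to [selectDEGenes()] for the
#'   `call` column.
#' @return A `data.frame` (one row per gene) with columns `gene_id`,
#'   `log2_fc`, `t_ordinary`, `t_moderated`, `df_total`, `p_value`,
#'   `q_value`, `call`.
#' @export
setGeneric("moderatedTTest", function(x, groupA, groupB, fit = NULL,
                                      pMax = 0.05, minFold = 1.5)
  standardGeneric("moderatedTTest"))

#' @rdname moderatedTTest
#' @export
setMethod("moderatedTTest", "matrix", function(x, groupA, groupB, fit = NULL,
                                               pMax = 0.05, minFold = 1.5) {
  idx <- groupIndices(x, groupA, groupB)
  if (is.null(fit)) fit <- fitModeration(x, groupA, groupB)
  na <- length(idx$a); nb <- length(idx$b)
  dg <- na + nb - 2L
  s2 <- pooledVariances(x, idx$a, idx$b)
  lfc <- rowMeans(x[, idx$a, drop = FALSE]) - rowMeans(x[, idx$b, drop = FALSE])
  seFac <- sqrt(1 / na + 1 / nb)
  tOrd <- lfc / (sqrt(s2) * seFac)
  tOrd[lfc == 0 & s2 == 0] <- 0
  if (is.infinite(fit@d0)) {
    s2post <- rep(fit@s0sq, length(s2))
    dfTotal <- Inf
  } else if (fit@d0 == 0) {
    s2post <- s2
    dfTotal <- dg
  } else {
    s2post <- (fit@d0 * fit@s0sq + dg * s2) / (fit@d0 + dg)
    dfTotal <- fit@d0 + dg
  }
  tMod <- lfc / (sqrt(s2post) * seFac)
  tMod[lfc == 0] <- 0  # 0/0 when both the effect and variance vanish
  p <- 2 * pt(-abs(tMod), df = dfTotal)
  tab <- data.frame(gene_id = rownames(x), log2_fc = lfc,
                    t_ordinary = tOrd, t_moderated = tMod,
                    df_total = dfTotal, p_value = p,
                    q_value = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  sel <- selectDEGenes(tab, pMax = pMax, minFold = minFold)
  tab$call <- ifelse(tab$gene_id %in% sel$up, "up",
                     ifelse(tab$gene_id %in% sel$down, "down", "not_de"))
  tab
})

#' @rdname moderatedTTest
#' @export
setMethod("moderatedTTest", "HscExperiment",
          function(x, groupA, groupB, fit = NULL, pMax = 0.05, minFold = 1.5)
            moderatedTTest(exprs(x), groupA, groupB, fit, pMax, minFold))

#' Screen differentially expressed genes from a contrast table
#'
#' Applies the two-stage screen: unadjusted P below `pMax`, then a fold
#' change larger than `minFold`. On the default log scale the fold gate
#' is `|log2 fold change| > log2(minFold)`; `foldScale = "linear"`
#' instead requires `|log2_fc| > minFold` (i.e. the threshold read as a
#' log2 difference).
#'
#' @param table a DE table from [moderatedTTest()] (needs `gene_id`,
#'   `log2_fc`, `p_value`).
#' @param pMax unadjusted P-value threshold (default 0.05).
#' @param minFold fold-change threshold (> 1 on the default scale).
#' @param foldScale `"log"` (default) or `"linear"`.
#' @return `list(up = character(), down = character())`, disjoint.
#' @export
selectDEGenes <- function(table, pMax = 0.05, minFold = 1.5,
                          foldScale = c("log", "linear")) {
  foldScale <- match.arg(foldScale)
  if (foldScale == "log" && minFold <= 1) stop("minFold must be > 1")
  thr <- if (foldScale == "log") log2(minFold) else minFold
  sig <- table$p_value < pMax
  list(up = table$gene_id[sig & table$log2_fc > thr],
       down = table$gene_id[sig & table$log2_fc < -thr])
}

CONTRAST_CELLS <- list(
  `1LvsN` = c("JS1.LPS", "JS1.PBS"),
  `2LvsN` = c("JS2.LPS", "JS2.PBS"),
  `1HvsN` = c("JS1.HMGB1", "JS1.PBS"),
  `2HvsN` = c("JS2.HMGB1", "JS2.PBS"),
  `1Nvs2N` = c("JS1.PBS", "JS2.PBS"))

#' Run one named contrast of the study design
#'
#' Convenience wrapper mapping the Venn contrast labels (`1LvsN`,
#' `2LvsN`, `1HvsN`, `2HvsN`, and the baseline `1Nvs2N`) onto
#' [moderatedTTest()] with the orientation case minus control
#' (treated minus untreated; JS1 minus JS2). Arbitrary contrasts can be
#' given as `"JS1.LPS-vs-JS2.LPS"`.
#'
#' @param experiment an [HscExperiment-class].
#' @param contrast a label from the design (`"1LvsN"`, ...) or a string
#'   `"<cell>-vs-<cell>"` over design cells.
#' @inheritParams moderatedTTest
#' @return The DE `data.frame` of [moderatedTTest()].
#' @export
runContrast <- function(experiment, contrast, fit = NULL,
                        pMax = 0.05, minFold = 1.5) {
  cells <- if (contrast %in% names(CONTRAST_CELLS)) CONTRAST_CELLS[[contrast]]
  else strsplit(contrast, "-vs-", fixed = TRUE)[[1]]
  if (length(cells) != 2L) stop("cannot parse contrast: ", contrast)
  moderatedTTest(experiment, cellSamples(experiment, cells[1]),
                 cellSamples(experiment, cells[2]), fit = fit,
                 pMax = pMax, minFold = minFold)
}
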