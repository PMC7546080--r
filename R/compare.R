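## Baseline comparisons: equal-weight test, over-representation, and
## leave-one-out gene influence.

#' Unweighted (equal-weight) gene-set test
#'
#' The weighted test with \eqn{w_i = 1/m}; the statistic is then the mean
#' rank of the set genes. Identical in every respect (including the
#' Monte Carlo sample path under a given seed) to running
#' [geneSetTest()] with uniform weights.
#'
#' @param genes character vector of set gene identifiers.
#' @param ranked a [RankedGeneList-class].
#' @param ... passed to [geneSetTest()] (`method`, `sided`, `K`, `seed`,
#'   `corr`, ...).
#' @return A [NullEstimate-class].
#' @export
equalWeightTest <- function(genes, ranked, ...) {
  geneSetTest(equalWeightSet(genes), ranked, ...)
}

#' One-sided Fisher exact over-representation test
#'
#' Labels genes significant when their gene-level p-value is at or below
#' (or strictly below, with `strict = TRUE`) `cutoff`, forms the 2x2
#' table of set membership by significance over the background, and
#' returns the hypergeometric upper-tail probability
#' \eqn{P(X \ge x)} of observing at least the attained number of
#' significant genes inside the set.
#'
#' @param pValues named numeric vector of gene-level p-values over the
#'   whole background (names are gene identifiers).
#' @param setGenes character vector of set members (must be a subset of
#'   the background, and a proper subset: the complement may not be
#'   empty).
#' @param cutoff significance cutoff in (0, 1); typically derived from a
#'   false-discovery-rate criterion, see [bhThreshold()].
#' @param strict logical; significance requires `p < cutoff` instead of
#'   `p <= cutoff`.
#' @return One-sided p-value (numeric scalar) with attributes `table`
#'   (the 2x2 table) and `cutoff`.
#' @examples
#' p <- setNames(seq(0.001, 1, length.out = 100), sprintf("g%03d", 1:100))
#' fisherOverrep(p, sprintf("g%03d", 1:10), cutoff = 0.05)
#' @export
fisherOverrep <- function(pValues, setGenes, cutoff, strict = FALSE) {
  if (cutoff <= 0 || cutoff >= 1) stop("'cutoff' must lie in (0, 1)")
  if (is.null(names(pValues))) stop("'pValues' must be named by gene")
  bad <- setdiff(setGenes, names(pValues))
  if (length(bad))
    stop("set genes absent from background: ",
         paste(bad, collapse = ", "))
  n <- length(pValues)
  m <- length(setGenes)
  if (m < 1) stop("empty gene set")
  if (m >= n) stop("the background complement of the set is empty")
  sig <- if (strict) pValues < cutoff else pValues <= cutoff
  x <- sum(sig[setGenes])
  K <- sum(sig)
  # P(X >= x) for X ~ Hypergeom(white = K significant, black = n - K,
  # drawn = m in-set)
  p <- phyper(x - 1, K, n - K, m, lower.tail = FALSE)
  structure(p, table = matrix(c(x, K - x, m - x, (n - K) - (m - x)), 2, 2,
                              dimnames = list(c("inSet", "outSet"),
                                              c("significant", "not"))),
            cutoff = cutoff)
}

#' Benjamini-Hochberg significance cutoff
#'
#' Derives the data-dependent p-value cutoff implied by controlling the
#' false discovery rate at `level`: the largest p-value among the
#' BH-rejected hypotheses (0 if none are rejected). Useful for feeding
#' [fisherOverrep()] with an FDR-derived significance threshold.
#'
#' @param pValues numeric vector of p-values.
#' @param level FDR level (e.g. 0.1).
#' @return The cutoff (numeric scalar).
#' @export
bhThreshold <- function(pValues, level = 0.1) {
  adj <- p.adjust(pValues, method = "BH")
  if (!any(adj <= level)) return(0)
  max(pValues[adj <= level])
}

#' Leave-one-out gene influence
#'
#' Re-runs the gene-set test with each gene removed in turn (remaining
#' weights renormalized) and reports the resulting p-values. Genes whose
#' removal most increases the p-value contribute the most evidence to the
#' set's association; the result is sorted by decreasing p-value.
#'
#' @param set a [WeightedGeneSet-class] with at least two genes.
#' @param ranked a [RankedGeneList-class].
#' @param ... passed to [geneSetTest()] (`method`, `K`, `seed`, ...).
#' @return A data.frame with columns `gene`, `p` (p-value with the gene
#'   removed), ordered by decreasing `p`.
#' @export
leaveOneOut <- function(set, ranked, ...) {
  stopifnot(is(set, "WeightedGeneSet"))
  m <- setSize(set)
  if (m < 2) stop("leave-one-out needs at least 2 genes in the set")
  ids <- geneIds(set)
  w <- geneWeights(set)
  p <- vapply(seq_len(m), function(i) {
    wi <- w[-i]
    if (sum(wi) <= 0)
      stop("removing gene ", ids[i], " leaves no positive weight")
    pValue(geneSetTest(WeightedGeneSet(ids[-i], wi), ranked, ...))
  }, numeric(1))
  out <- data.frame(gene = ids, p = p)
  out[order(-out$p), , drop = FALSE]
}
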