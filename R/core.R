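## Core domain constructors and the weighted rank statistic.

#' Construct a ranked background gene list
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param ranks integer vector assigning each gene a rank in `1:n`;
#'   must be a permutation (rank 1 = strongest association).
#' @return A [RankedGeneList-class] object.
#' @examples
#' RankedGeneList(c("A", "B", "C"), c(2L, 1L, 3L))
#' @export
RankedGeneList <- function(geneIds, ranks) {
  new("RankedGeneList", geneIds = as.character(geneIds),
      ranks = as.integer(ranks))
}

#' Rank genes by gene-level association p-value
#'
#' Genes with the smallest p-values receive the ranks closest to 1. Ties
#' are broken by a declared policy: `"stable"` keeps input order (the
#' default, so results are deterministic), `"random"` permutes tied genes
#' under `seed`.
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param pValues numeric vector of p-values in `[0, 1]`, one per gene.
#' @param ties `"stable"` or `"random"`.
#' @param seed RNG seed, used only by the random tie policy.
#' @return A [RankedGeneList-class].
#' @examples
#' rgl <- rankGenes(c("g1", "g2", "g3"), c(0.01, 0.5, 0.2))
#' geneRanks(rgl)  # 1 3 2
#' @export
rankGenes <- function(geneIds, pValues, ties = c("stable", "random"),
                      seed = 1L) {
  ties <- match.arg(ties)
  geneIds <- as.character(geneIds)
  if (anyDuplicated(geneIds))
    stop("duplicate gene identifiers: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))
  if (length(pValues) != length(geneIds))
    stop("'geneIds' and 'pValues' must have the same length")
  if (anyNA(pValues) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  n <- length(pValues)
  ord <- if (ties == "stable") {
    order(pValues)                      # stable for ties: input order
  } else {
    withSeed(seed, order(pValues, runif(n)))
  }
  ranks <- integer(n)
  ranks[ord] <- seq_len(n)
  RankedGeneList(geneIds, ranks)
}

#' Normalize non-negative weights to sum to 1
#'
#' Weights can always be rescaled to sum to 1 without changing the test,
#' so they are stored normalized.
#'
#' @param w numeric vector of non-negative weights, at least one positive.
#' @return `w / sum(w)`.
#' @examples
#' normalizeWeights(c(2, 2))        # 0.5 0.5
#' @export
normalizeWeights <- function(w) {
  if (anyNA(w) || any(w < 0))
    stop("weights must be non-negative and non-missing")
  s <- sum(w)
  if (s <= 0) stop("at least one weight must be positive (sum w > 0)")
  w / s
}

#' Construct a weighted gene set
#'
#' @param geneIds character vector of unique gene identifiers.
#' @param weights non-negative weights, normalized internally to sum to 1
#'   (set `normalize = FALSE` to require already-normalized input).
#' @param normalize logical; rescale weights to sum to 1.
#' @return A [WeightedGeneSet-class].
#' @examples
#' WeightedGeneSet(c("A", "B"), c(3, 1))
#' @export
WeightedGeneSet <- function(geneIds, weights, normalize = TRUE) {
  if (normalize) weights <- normalizeWeights(weights)
  new("WeightedGeneSet", geneIds = as.character(geneIds),
      weights = as.numeric(weights))
}

#' Equal-weight gene set
#'
#' Convenience constructor for the unweighted special case
#' \eqn{w_i = 1/m}, under which the statistic is the mean rank of the set.
#'
#' @param geneIds character vector of gene identifiers.
#' @return A [WeightedGeneSet-class] with uniform weights.
#' @export
equalWeightSet <- function(geneIds) {
  m <- length(geneIds)
  WeightedGeneSet(geneIds, rep(1 / m, m), normalize = FALSE)
}

#' Compute the weighted rank statistic
#'
#' Evaluates \eqn{v = \sum_{i \in S} w_i r_i} for a weighted gene set
#' against a ranked background, and caches the null moments
#' \eqn{\mu = (n+1)/2} and
#' \eqn{\sigma_w^2 = [(n^2 - 1)/12] \sum_{i \in S} w_i^2} used by the
#' normal approximation. With equal weights \eqn{v} is the mean rank of
#' the set genes; with a single unit weight it is that gene's rank.
#'
#' @param set a [WeightedGeneSet-class].
#' @param ranked a [RankedGeneList-class] containing every set gene.
#' @param matchCase logical; if `FALSE`, gene identifiers are uppercased on
#'   both sides before matching. Matching is exact and case-sensitive by
#'   default so that data errors are not silently hidden.
#' @return A [SetRankStatistic-class].
#' @examples
#' rgl <- RankedGeneList(c("A", "B", "C", "D"), 1:4)
#' statValue(setStatistic(equalWeightSet(c("A", "B")), rgl))  # 1.5
#' @export
setStatistic <- function(set, ranked, matchCase = TRUE) {
  stopifnot(is(set, "WeightedGeneSet"), is(ranked, "RankedGeneList"))
  sid <- geneIds(set); bid <- geneIds(ranked)
  if (!matchCase) { sid <- toupper(sid); bid <- toupper(bid) }
  idx <- match(sid, bid)
  if (anyNA(idx))
    stop("set genes absent from the ranked background: ",
         paste(geneIds(set)[is.na(idx)], collapse = ", "))
  w <- geneWeights(set)
  r <- geneRanks(ranked)[idx]
  n <- nGenes(ranked)
  new("SetRankStatistic",
      v = sum(w * r), n = n, m = setSize(set),
      mu = (n + 1) / 2,
      sigmaW = sqrt((n^2 - 1) / 12 * sum(w^2)))
}

## -- accessors ---------------------------------------------------------

#' @rdname mbgsa-accessors
#' @export
setMethod("geneIds", "RankedGeneList", function(object) object@geneIds)

#' @rdname mbgsa-accessors
#' @export
setMethod("geneIds", "WeightedGeneSet", function(object) object@geneIds)

#' @rdname mbgsa-accessors
#' @export
setMethod("geneRanks", "RankedGeneList", function(object)
  setNames(object@ranks, object@geneIds))

#' @rdname mbgsa-accessors
#' @export
setMethod("geneWeights", "WeightedGeneSet", function(object)
  setNames(object@weights, object@geneIds))

#' @rdname mbgsa-accessors
#' @export
setMethod("nGenes", "RankedGeneList", function(object)
  length(object@geneIds))

#' @rdname mbgsa-accessors
#' @export
setMethod("setSize", "WeightedGeneSet", function(object)
  length(object@geneIds))

#' @rdname mbgsa-accessors
#' @export
setMethod("statValue", "SetRankStatistic", function(object) object@v)

#' @rdname mbgsa-accessors
#' @export
setMethod("nullMean", "SetRankStatistic", function(object) object@mu)

#' @rdname mbgsa-accessors
#' @export
setMethod("nullSd", "SetRankStatistic", function(object) object@sigmaW)

#' @rdname mbgsa-accessors
#' @export
setMethod("pValue", "NullEstimate", function(object) object@p)

#' @rdname mbgsa-accessors
#' @export
setMethod("stdError", "NullEstimate", function(object) object@stdError)

## -- show methods ------------------------------------------------------

setMethod("show", "RankedGeneList", function(object) {
  cat("RankedGeneList with", length(object@geneIds), "genes\n")
  k <- min(4L, length(object@geneIds))
  top <- object@geneIds[order(object@ranks)][seq_len(k)]
  cat("  top-ranked:", paste(top, collapse = ", "),
      if (length(object@geneIds) > k) "..." else "", "\n")
})

setMethod("show", "WeightedGeneSet", function(object) {
  cat("WeightedGeneSet with", length(object@geneIds), "genes",
      sprintf("(%d with positive weight)\n", sum(object@weights > 0)))
})

setMethod("show", "SetRankStatistic", function(object) {
  cat(sprintf(
    "SetRankStatistic: v = %.4g (m = %d of n = %d; mu = %.1f, sigma_w = %.4g)\n",
    object@v, object@m, object@n, object@mu, object@sigmaW))
})

setMethod("show", "NullEstimate", function(object) {
  cat(sprintf("NullEstimate: p = %.4g (%s, %s-sided)\n",
              object@p, object@method, object@sided))
  if (is.finite(object@nSamples))
    cat(sprintf("  K = %g samples, SE = %.3g, seed = %g\n",
                object@nSamples, object@stdError, object@seed))
  if (length(object@note) && nzchar(object@note))
    cat(" ", object@note, "\n")
})
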