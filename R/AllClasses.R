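#' Ranked background gene list
#'
#' Holds the full background of \eqn{n} genes together with a rank for each,
#' where rank 1 marks the gene most strongly associated with the phenotype
#' and rank \eqn{n} the least. Ranks must form a permutation of
#' \eqn{\{1, \dots, n\}}.
#'
#' @slot geneIds character vector of unique gene identifiers.
#' @slot ranks integer vector, same length, a permutation of `1:n`.
#'
#' @seealso [rankGenes()] to construct one from gene-level p-values.
#' @examples
#' rgl <- RankedGeneList(c("A", "B", "C"), c(2L, 1L, 3L))
#' geneRanks(rgl)
#' @name RankedGeneList-class
#' @aliases RankedGeneList-class
#' @exportClass RankedGeneList
setClass("RankedGeneList",
  slots = c(geneIds = "character", ranks = "integer"))

setValidity("RankedGeneList", function(object) {
  n <- length(object@geneIds)
  if (n < 1L) return("at least one gene is required")
  if (length(object@ranks) != n)
    return("'geneIds' and 'ranks' must have the same length")
  if (anyDuplicated(object@geneIds))
    return("gene identifiers must be unique")
  if (anyNA(object@ranks) || !identical(sort(object@ranks), seq_len(n)))
    return("'ranks' must be a permutation of 1..n (no gaps, no duplicates)")
  TRUE
})

#' Weighted gene set
#'
#' A set of \eqn{m} genes with non-negative weights stored normalized to sum
#' to 1. Weights encode the a priori, model-predicted relative contribution
#' of each gene to the biological function under test; a weight of zero
#' states that the gene is believed not to contribute.
#'
#' @slot geneIds character vector of unique identifiers (the set S).
#' @slot weights numeric vector of non-negative weights summing to 1.
#'
#' @seealso [geneWeightsFromPrcc()] for model-derived weights,
#'   [geneSetTest()] to test a set against a [RankedGeneList-class].
#' @name WeightedGeneSet-class
#' @aliases WeightedGeneSet-class
#' @exportClass WeightedGeneSet
setClass("WeightedGeneSet",
  slots = c(geneIds = "character", weights = "numeric"))

setValidity("WeightedGeneSet", function(object) {
  m <- length(object@geneIds)
  if (m < 1L) return("at least one gene is required")
  if (length(object@weights) != m)
    return("'geneIds' and 'weights' must have the same length")
  if (anyDuplicated(object@geneIds))
    return("gene identifiers must be unique")
  if (anyNA(object@weights) || any(object@weights < 0))
    return("weights must be non-negative and non-missing")
  if (abs(sum(object@weights) - 1) > 1e-12)
    return("weights must sum to 1 (use WeightedGeneSet() to normalize)")
  TRUE
})

#' Weighted rank statistic with its null moments
#'
#' The observed statistic \eqn{v = \sum_{i \in S} w_i r_i} together with the
#' background size, the set size, the null mean \eqn{\mu = (n+1)/2}, and the
#' with-replacement null standard deviation
#' \eqn{\sigma_w = \sqrt{[(n^2-1)/12] \sum_i w_i^2}} used by the normal
#' approximation. Caching \eqn{\mu} and \eqn{\sigma_w} here gives all
#' downstream p-value code a single definition of the approximation moments.
#'
#' @slot v numeric statistic value, in \eqn{[1, n]}.
#' @slot n integer background size.
#' @slot m integer set size.
#' @slot mu numeric, \eqn{(n+1)/2}.
#' @slot sigmaW numeric, the approximation null standard deviation.
#' @name SetRankStatistic-class
#' @aliases SetRankStatistic-class
#' @exportClass SetRankStatistic
setClass("SetRankStatistic",
  slots = c(v = "numeric", n = "integer", m = "integer",
            mu = "numeric", sigmaW = "numeric"))

setValidity("SetRankStatistic", function(object) {
  if (length(object@v) != 1L || !is.finite(object@v))
    return("'v' must be a single finite number")
  if (object@v < 1 - 1e-9 || object@v > object@n + 1e-9)
    return("'v' must lie in [1, n]")
  if (abs(object@mu - (object@n + 1) / 2) > 1e-9)
    return("'mu' must equal (n + 1)/2")
  TRUE
})

#' Null-distribution tail probability with estimator metadata
#'
#' A p-value for the weighted rank statistic, tagged with the method that
#' produced it, sidedness, and (for Monte Carlo methods) the sample count,
#' binomial standard error and RNG seed.
#'
#' @slot p numeric probability in \eqn{[0, 1]}.
#' @slot method one of `"monte_carlo"`, `"normal"`, `"exact"`,
#'   `"correlated_mc"`.
#' @slot sided `"one"` or `"two"`.
#' @slot v the observed statistic the tail was evaluated at.
#' @slot nSamples Monte Carlo sample count K (`NA` for normal/exact).
#' @slot stdError estimated standard error of `p`
#'   (\eqn{\sqrt{\hat p(1-\hat p)/K}}; `NA` for normal/exact).
#' @slot seed RNG seed used (`NA` for normal/exact).
#' @slot note character; e.g. flags a zero MC estimate with its 1/K
#'   resolution.
#' @name NullEstimate-class
#' @aliases NullEstimate-class
#' @exportClass NullEstimate
setClass("NullEstimate",
  slots = c(p = "numeric", method = "character", sided = "character",
            v = "numeric", nSamples = "numeric", stdError = "numeric",
            seed = "numeric", note = "character"))

setValidity("NullEstimate", function(object) {
  if (object@p < 0 || object@p > 1) return("'p' must lie in [0, 1]")
  if (!object@method %in% c("monte_carlo", "normal", "exact",
                            "correlated_mc"))
    return("unknown method")
  if (!object@sided %in% c("one", "two")) return("'sided' must be one|two")
  TRUE
})

#' Gene-gene correlation structure for the correlated null
#'
#' A symmetric correlation matrix over the background genes, adjusted so
#' that all eigenvalues are at least `eigenFloor` (eigenvectors untouched),
#' making it usable as the covariance of the latent multivariate normal
#' that generates correlated ranks.
#'
#' @slot matrix symmetric numeric matrix (after eigenvalue adjustment).
#' @slot eigenFloor minimum eigenvalue enforced by [adjustCorrelation()].
#' @name CorrelationModel-class
#' @aliases CorrelationModel-class
#' @exportClass CorrelationModel
setClass("CorrelationModel",
  slots = c(matrix = "matrix", eigenFloor = "numeric"))

setValidity("CorrelationModel", function(object) {
  M <- object@matrix
  if (nrow(M) != ncol(M)) return("matrix must be square")
  if (max(abs(M - t(M))) > 1e-8) return("matrix must be symmetric")
  TRUE
})

#' Model parameters and their mapped genes
#'
#' The parameter side of the weight-derivation pipeline: each parameter has
#' a name, a baseline value with units, and the list of genes mapped to it
#' (whose length is \eqn{N_k}). Genes known to the mapping but excluded from
#' analysis (e.g. because no rank is available for them) are carried
#' separately.
#'
#' @slot name character parameter names.
#' @slot baseline numeric baseline values.
#' @slot units character unit strings.
#' @slot genes list of character vectors, analyzed genes per parameter.
#' @slot excluded list of character vectors, excluded genes per parameter.
#' @seealso [calciumParameters()] for the bundled calcium-handling mapping.
#' @name ParameterSet-class
#' @aliases ParameterSet-class
#' @exportClass ParameterSet
setClass("ParameterSet",
  slots = c(name = "character", baseline = "numeric", units = "character",
            genes = "list", excluded = "list"))

setValidity("ParameterSet", function(object) {
  p <- length(object@name)
  if (length(object@baseline) != p || length(object@units) != p ||
      length(object@genes) != p || length(object@excluded) != p)
    return("all slots must have one entry per parameter")
  if (anyDuplicated(object@name)) return("parameter names must be unique")
  if (anyNA(object@baseline) || any(!is.finite(object@baseline)))
    return("baselines must be finite")
  TRUE
})

#' Global sensitivity analysis result
#'
#' Partial rank correlation coefficients, one per model parameter, from
#' [prcc()].
#'
#' @slot parameter character parameter names.
#' @slot rho numeric PRCC values in \eqn{[-1, 1]}.
#' @slot n integer sample count used for estimation.
#' @slot output name of the measured model output.
#' @name SensitivityResult-class
#' @aliases SensitivityResult-class
#' @exportClass SensitivityResult
setClass("SensitivityResult",
  slots = c(parameter = "character", rho = "numeric", n = "integer",
            output = "character"))

setValidity("SensitivityResult", function(object) {
  if (length(object@rho) != length(object@parameter))
    return("one PRCC per parameter required")
  if (any(abs(object@rho) > 1 + 1e-8)) return("|rho| must be <= 1")
  TRUE
})

#' Power simulation scenario
#'
#' Configuration for the rejection-region power study: gene-level test
#' statistics follow a (non)central F with \eqn{\nu - 1} and \eqn{k - \nu}
#' degrees of freedom, with non-centrality \eqn{k d_g} for gene \eqn{g};
#' p-values are identified with normalized gene ranks.
#'
#' @slot nu number of gene-level principal components \eqn{\nu}.
#' @slot sampleSize number of subjects \eqn{k}.
#' @slot effects per-gene effect sizes \eqn{d_g \ge 0}.
#' @slot alpha target type-I level.
#' @slot weights per-gene test weights (normalized).
#' @slot replicates simulation replicate count.
#' @slot seed RNG seed.
#' @seealso [powerScenario()], [estimatePower()].
#' @name PowerScenario-class
#' @aliases PowerScenario-class
#' @exportClass PowerScenario
setClass("PowerScenario",
  slots = c(nu = "integer", sampleSize = "integer", effects = "numeric",
            alpha = "numeric", weights = "numeric", replicates = "integer",
            seed = "numeric"))

setValidity("PowerScenario", function(object) {
  if (object@nu < 2L) return("'nu' must be >= 2")
  if (object@sampleSize <= object@nu)
    return("'sampleSize' must exceed 'nu'")
  if (any(object@effects < 0)) return("effects must be >= 0")
  if (object@alpha <= 0 || object@alpha >= 1)
    return("'alpha' must lie in (0, 1)")
  if (length(object@weights) != length(object@effects))
    return("one weight per gene required")
  TRUE
})
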