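## Model-based gene weight derivation: Latin hypercube sampling, a
## pluggable model interface, PRCC estimation, and the |rho_k|/N_k rule.

#' Construct a parameter set
#'
#' @param name character parameter names (unique).
#' @param baseline numeric baseline values.
#' @param units character unit strings.
#' @param genes list of character vectors: genes mapped to each parameter
#'   (the length of each is \eqn{N_k}).
#' @param excluded optional list of character vectors: genes known for the
#'   mapping but excluded from analysis.
#' @return A [ParameterSet-class].
#' @examples
#' ps <- ParameterSet("gX", 1.5, "mS cm-2", list(c("G1", "G2")))
#' parameterNames(ps)
#' @export
ParameterSet <- function(name, baseline, units = rep("", length(name)),
                         genes, excluded = NULL) {
  if (is.null(excluded))
    excluded <- rep(list(character(0)), length(name))
  new("ParameterSet", name = as.character(name),
      baseline = as.numeric(baseline), units = as.character(units),
      genes = lapply(genes, as.character),
      excluded = lapply(excluded, as.character))
}

#' @rdname ParameterSet
#' @param object a [ParameterSet-class].
#' @export
parameterNames <- function(object) object@name

#' @rdname ParameterSet
#' @export
baselines <- function(object) setNames(object@baseline, object@name)

#' @rdname ParameterSet
#' @param includeExcluded logical; append the excluded genes too.
#' @export
mappedGenes <- function(object, includeExcluded = FALSE) {
  g <- object@genes
  if (includeExcluded)
    g <- mapply(c, g, object@excluded, SIMPLIFY = FALSE)
  setNames(g, object@name)
}

setMethod("show", "ParameterSet", function(object) {
  cat(sprintf("ParameterSet: %d parameters, %d mapped genes (+%d excluded)\n",
              length(object@name), sum(lengths(object@genes)),
              sum(lengths(object@excluded))))
})

setMethod("length", "ParameterSet", function(x) length(x@name))

#' Latin hypercube sample of model parameters
#'
#' Draws `N` parameter vectors by Latin hypercube sampling from
#' independent normal marginals centered at each parameter's baseline with
#' standard deviation `sdFrac` times the absolute baseline (5% by
#' default). Per parameter, the `N` normal CDF values occupy each of the
#' `N` equal-probability strata exactly once, with uniform placement
#' within the stratum and independently permuted strata across parameters.
#'
#' @param params a [ParameterSet-class] (or anything with
#'   [baselines()]-style named numeric baselines).
#' @param N number of samples.
#' @param sdFrac marginal standard deviation as a fraction of the
#'   absolute baseline.
#' @param sd optional named numeric vector of absolute standard
#'   deviations, overriding `sdFrac` (required for zero baselines).
#' @param seed RNG seed.
#' @return An `N x P` numeric matrix, columns named by parameter.
#' @examples
#' ps <- ParameterSet(c("a", "b"), c(1, 10), genes = list("G1", "G2"))
#' colMeans(latinHypercubeNormal(ps, N = 64))
#' @export
latinHypercubeNormal <- function(params, N = 320, sdFrac = 0.05,
                                 sd = NULL, seed = 1L) {
  b <- if (is(params, "ParameterSet")) baselines(params) else
    setNames(as.numeric(params), names(params))
  P <- length(b)
  if (N < 2) stop("'N' must be at least 2")
  if (is.null(sd)) {
    if (any(b == 0))
      stop("zero baseline for parameter(s) ",
           paste(names(b)[b == 0], collapse = ", "),
           "; supply absolute standard deviations via 'sd'")
    sd <- sdFrac * abs(b)
  } else {
    sd <- sd[names(b)]
    if (anyNA(sd)) stop("'sd' must name every parameter")
  }
  u <- withSeed(seed, lhs::randomLHS(N, P))
  x <- qnorm(u)
  x <- sweep(sweep(x, 2, sd, "*"), 2, b, "+")
  colnames(x) <- names(b)
  x
}

#' Evaluate a model over sampled parameter sets
#'
#' Applies a scalar-valued model function to each row of a sampled
#' parameter matrix. The model plug-in contract: a callable taking a named
#' numeric vector (parameter name to value) and returning one finite
#' scalar. Non-finite outputs are collected and surfaced as an error
#' naming the offending rows, never silently dropped.
#'
#' @param modelFn the model function.
#' @param x `N x P` parameter matrix with column names.
#' @return Numeric vector of `N` model outputs.
#' @export
evaluateModel <- function(modelFn, x) {
  stopifnot(is.function(modelFn), is.matrix(x), !is.null(colnames(x)))
  y <- vapply(seq_len(nrow(x)),
              function(i) as.numeric(modelFn(setNames(x[i, ],
                                                      colnames(x)))),
              numeric(1))
  bad <- which(!is.finite(y))
  if (length(bad))
    stop("model returned non-finite output at row(s): ",
         paste(head(bad, 20), collapse = ", "),
         if (length(bad) > 20) " ..." else "")
  y
}

#' Partial rank correlation coefficients
#'
#' Global sensitivity measure: for each parameter k, all columns of `x`
#' and the output `y` are rank-transformed (average ranks for ties);
#' rank(x_k) and rank(y) are each regressed by ordinary least squares
#' (with intercept) on the ranks of the other P-1 parameters; the PRCC
#' \eqn{\rho_k} is the Pearson correlation of the two residual vectors.
#' It measures the monotone influence of parameter k on the output while
#' controlling for the contribution of the other parameters.
#'
#' @param x `N x P` sampled parameter matrix with column names.
#' @param y numeric vector of `N` model outputs.
#' @param output name recorded for the measured output.
#' @return A [SensitivityResult-class].
#' @examples
#' x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
#' prccValues(prcc(x, 2 * x[, 1] - x[, 2] + rnorm(100, sd = 0.1)))
#' @export
prcc <- function(x, y, output = "y") {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  N <- nrow(x); P <- ncol(x)
  if (length(y) != N) stop("'y' must have one value per sample")
  if (N <= P + 2)
    stop("need N > P + 2 samples (N = ", N, ", P = ", P,
         "): residual degrees of freedom exhausted")
  const <- apply(x, 2, function(col) diff(range(col)) == 0)
  if (any(const))
    stop("constant parameter column(s): ",
         paste(colnames(x)[const], collapse = ", "))
  rx <- apply(x, 2, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  rho <- vapply(seq_len(P), function(k) {
    z <- cbind(1, rx[, -k, drop = FALSE])
    resK <- lm.fit(z, rx[, k])$residuals
    resY <- lm.fit(z, ry)$residuals
    cor(resK, resY)
  }, numeric(1))
  new("SensitivityResult", parameter = colnames(x), rho = rho,
      n = as.integer(N), output = output)
}

#' @rdname prcc
#' @param object a [SensitivityResult-class].
#' @export
prccValues <- function(object) setNames(object@rho, object@parameter)

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult (%s, N = %d):\n", object@output,
              object@n))
  print(round(setNames(object@rho, object@parameter), 3))
})

#' Permutation significance of PRCC values
#'
#' Optional significance assessment (off the main path; no p-values are
#' attached to weights): permutes the model output and recomputes PRCCs to
#' build a per-parameter permutation null for \eqn{|\rho_k|}.
#'
#' @inheritParams prcc
#' @param nPerm number of permutations.
#' @param seed RNG seed.
#' @return A data.frame with the observed PRCC and a permutation p-value
#'   per parameter.
#' @export
prccPermutationTest <- function(x, y, nPerm = 199, seed = 1L) {
  obs <- prccValues(prcc(x, y))
  perm <- withSeed(seed, {
    vapply(seq_len(nPerm),
           function(i) abs(prccValues(prcc(x, sample(y)))),
           numeric(length(obs)))
  })
  perm <- matrix(perm, nrow = length(obs))
  pval <- (rowSums(perm >= abs(obs)) + 1) / (nPerm + 1)
  data.frame(parameter = names(obs), rho = as.numeric(obs), p = pval,
             row.names = NULL)
}

#' Gene weights from PRCC sensitivities
#'
#' The model-to-genes weight rule: each of the \eqn{N_k} genes assigned to
#' parameter k with PRCC \eqn{\rho_k} receives raw weight
#' \eqn{|\rho_k|/N_k}; weights are then renormalized to sum to 1 over all
#' genes. Only the magnitude of the PRCC is used (gene-phenotype
#' association measures are not specific enough to carry direction), and
#' dividing by \eqn{N_k} keeps a model component from being weighted
#' heavily simply because many genes map to it. Genes of a zero-PRCC
#' parameter get weight 0.
#'
#' @param sens a [SensitivityResult-class] covering every parameter.
#' @param params a [ParameterSet-class] with non-empty gene lists.
#' @param multiMap logical; a gene mapped to several parameters is an
#'   error unless `multiMap = TRUE`, in which case its \eqn{|\rho_k|/N_k}
#'   contributions are summed (an implementation choice; the underlying
#'   method does not define this case).
#' @return A [WeightedGeneSet-class] over all mapped genes.
#' @examples
#' ps <- ParameterSet(c("a", "b"), c(1, 2),
#'                    genes = list(c("G1", "G2"), "G3"))
#' sr <- new("SensitivityResult", parameter = c("a", "b"),
#'           rho = c(0.5, -0.5), n = 100L, output = "y")
#' geneWeights(geneWeightsFromPrcc(sr, ps))  # 0.25 0.25 0.50
#' @export
geneWeightsFromPrcc <- function(sens, params, multiMap = FALSE) {
  stopifnot(is(sens, "SensitivityResult"), is(params, "ParameterSet"))
  rho <- prccValues(sens)
  miss <- setdiff(parameterNames(params), names(rho))
  if (length(miss))
    stop("no PRCC for parameter(s): ", paste(miss, collapse = ", "))
  genes <- mappedGenes(params)
  if (any(lengths(genes) == 0))
    stop("empty gene list for parameter(s): ",
         paste(names(genes)[lengths(genes) == 0], collapse = ", "))
  gene <- unlist(genes, use.names = FALSE)
  raw <- unlist(mapply(function(p, g)
    rep(abs(rho[[p]]) / length(g), length(g)),
    names(genes), genes, SIMPLIFY = FALSE), use.names = FALSE)
  if (anyDuplicated(gene)) {
    if (!multiMap)
      stop("gene(s) mapped to multiple parameters: ",
           paste(unique(gene[duplicated(gene)]), collapse = ", "),
           "; set multiMap = TRUE to sum contributions")
    raw <- tapply(raw, factor(gene, levels = unique(gene)), sum)
    gene <- unique(gene)
    raw <- as.numeric(raw)
  }
  WeightedGeneSet(gene, raw)
}
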