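## Null distributions and p-values for the weighted rank statistic.

# Positive-weight reduction: ranks of zero-weight genes never enter V, and
# the remaining genes' ranks are still a uniform injection into {1..n}, so
# sampling/enumeration can be restricted to genes with w > 0. This also
# makes removal of a zero-weight gene a bit-identical no-op for MC methods.
positiveWeights <- function(set) {
  w <- geneWeights(set)
  w[w > 0]
}

#' Sample the Monte Carlo null of the weighted rank statistic
#'
#' Draws `K` samples of \eqn{V = \sum_{i \in S} w_i R_i} where the ranks
#' \eqn{R_i} of the set genes are drawn uniformly at random from
#' \eqn{\{1, \dots, n\}} without replacement — the null in which the set's
#' genes were chosen uniformly at random from the background.
#'
#' @param set a [WeightedGeneSet-class].
#' @param n background gene count; must be at least the number of
#'   positive-weight genes in the set.
#' @param K number of Monte Carlo samples.
#' @param seed RNG seed (results are reproducible given the seed).
#' @return Numeric vector of `K` null samples of \eqn{V}.
#' @examples
#' s <- equalWeightSet(c("A", "B"))
#' mean(sampleNull(s, n = 1000, K = 1e4) <= 100)
#' @export
sampleNull <- function(set, n, K = 1e5, seed = 1L) {
  stopifnot(is(set, "WeightedGeneSet"))
  w <- positiveWeights(set)
  if (length(w) > n)
    stop("set has more positive-weight genes (", length(w),
         ") than the background size n = ", n)
  if (K < 1) stop("'K' must be at least 1")
  withSeed(seed, cpp_sample_null(as.numeric(w), as.integer(n), K))
}

#' Monte Carlo p-value from null samples
#'
#' One-sided: the proportion of samples with \eqn{V \le v} (non-strict).
#' Two-sided: the proportion with
#' \eqn{|V - (n+1)/2| \ge |v - (n+1)/2|}. The plain proportion is the
#' unbiased estimator with variance \eqn{P(V \le v)/K} for small p; the
#' conservative \eqn{(r+1)/(K+1)} variant is available for inference use.
#'
#' @param v observed statistic.
#' @param samples numeric vector of null samples (from [sampleNull()] or
#'   [sampleNullCorrelated()]).
#' @param n background size (needed for the two-sided center
#'   \eqn{\mu=(n+1)/2}).
#' @param sided `"one"` or `"two"`.
#' @param conservative logical; use \eqn{(r+1)/(K+1)} instead of \eqn{r/K}.
#' @param method method label recorded in the result.
#' @param seed seed recorded in the result.
#' @return A [NullEstimate-class].
#' @export
mcPvalue <- function(v, samples, n, sided = c("one", "two"),
                     conservative = FALSE, method = "monte_carlo",
                     seed = NA_real_) {
  sided <- match.arg(sided)
  K <- length(samples)
  if (K < 1) stop("'samples' must be nonempty")
  r <- if (sided == "one") {
    sum(samples <= v)
  } else {
    mu <- (n + 1) / 2
    sum(abs(samples - mu) >= abs(v - mu))
  }
  p <- if (conservative) (r + 1) / (K + 1) else r / K
  note <- if (r == 0L && !conservative)
    sprintf("no null sample at or beyond v; resolution 1/K = %.3g", 1 / K)
  else ""
  new("NullEstimate", p = p, method = method, sided = sided, v = v,
      nSamples = as.numeric(K), stdError = sqrt(p * (1 - p) / K),
      seed = as.numeric(seed), note = note)
}

#' Normal-approximation p-value
#'
#' Approximates \eqn{P(V \le v)} by \eqn{\Phi((v - \mu)/\sigma_w)} with
#' \eqn{\mu = (n+1)/2} and
#' \eqn{\sigma_w^2 = [(n^2-1)/12]\sum_{i \in S} w_i^2}, the moments
#' obtained when ranks are drawn with replacement. Two-sided:
#' \eqn{2\Phi(-|v - \mu|/\sigma_w)}.
#'
#' The degenerate case of an equal-weight set covering the whole background
#' (`m == n`) errors: there \eqn{V} is constant so the with-replacement
#' variance formula is not the truth; use the exact or MC method.
#'
#' @param stat a [SetRankStatistic-class] from [setStatistic()], or a plain
#'   list with elements `v`, `n`, `mu`, `sigmaW`.
#' @param sided `"one"` or `"two"`.
#' @return A [NullEstimate-class].
#' @examples
#' rgl <- RankedGeneList(letters[1:4], 1:4)
#' st <- setStatistic(equalWeightSet(c("a", "b")), rgl)
#' pValue(normalPvalue(st))
#' @export
normalPvalue <- function(stat, sided = c("one", "two")) {
  sided <- match.arg(sided)
  if (is(stat, "SetRankStatistic")) {
    # sum w_i^2 >= 1/m with equality iff equal weights; m = n + equal
    # weights makes V constant so the approximation variance is not the
    # truth there.
    sumw2 <- stat@sigmaW^2 * 12 / (stat@n^2 - 1)
    if (stat@m == stat@n && stat@m > 1L && sumw2 * stat@m <= 1 + 1e-9)
      stop("degenerate null: equal weights with m = n make V constant; ",
           "use the exact or Monte Carlo method")
    v <- stat@v; mu <- stat@mu; sw <- stat@sigmaW
  } else {
    v <- stat$v; mu <- stat$mu; sw <- stat$sigmaW
  }
  if (!is.finite(sw) || sw <= 0)
    stop("sigma_w must be positive; use the exact or Monte Carlo method")
  p <- if (sided == "one") pnorm((v - mu) / sw) else
    2 * pnorm(-abs(v - mu) / sw)
  new("NullEstimate", p = min(p, 1), method = "normal", sided = sided,
      v = v, nSamples = NA_real_, stdError = NA_real_, seed = NA_real_,
      note = "")
}

# All values of V under the permutation null, by exhaustive enumeration.
# When the positive weights are all equal the statistic is symmetric in the
# assigned ranks, so unordered combinations suffice; otherwise all
# injections (ordered arrangements) are enumerated. Returns equally likely
# values.
exactNullValues <- function(set, n, cap = 1e7) {
  w <- positiveWeights(set)
  m <- length(w)
  if (m > n) stop("set size exceeds background size")
  equal <- diff(range(w)) < 1e-12
  if (equal) {
    count <- choose(n, m)
    if (count > cap)
      stop("enumeration would need ", format(count), " combinations ",
           "(cap ", format(cap), "); use the Monte Carlo method")
    cmb <- combn(n, m)
    as.vector(w[1L] * colSums(cmb))
  } else {
    count <- prod(seq.int(n, by = -1, length.out = m))
    if (count > cap)
      stop("enumeration would need ", format(count), " injections ",
           "(cap ", format(cap), "); use the Monte Carlo method")
    cmb <- combn(n, m)
    perms <- permutationsOf(m)
    out <- numeric(0)
    for (j in seq_len(ncol(cmb)))
      out <- c(out, colSums(w * matrix(cmb[perms, j], nrow = m)))
    out
  }
}

# All permutations of 1..m as an m x m! index matrix (m is small).
permutationsOf <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- permutationsOf(m - 1L)
  out <- NULL
  for (i in seq_len(m)) {
    rest <- seq_len(m)[-i]
    out <- cbind(out, rbind(i, matrix(rest[sub], nrow = m - 1L)))
  }
  unname(out)
}

#' Exact p-value by exhaustive enumeration
#'
#' Brute-force oracle for the permutation null: enumerates every equally
#' likely assignment of distinct ranks to the set's positive-weight genes
#' and computes the exact tail probability. Feasible only for small
#' problems; the `cap` guards against blow-up.
#'
#' @param set a [WeightedGeneSet-class].
#' @param n background gene count.
#' @param v observed statistic.
#' @param sided `"one"` or `"two"`.
#' @param cap maximum number of arrangements to enumerate.
#' @return A [NullEstimate-class] with `method = "exact"`.
#' @examples
#' pValue(exactPvalue(WeightedGeneSet("g", 1), n = 3, v = 1))  # 1/3
#' @export
exactPvalue <- function(set, n, v, sided = c("one", "two"), cap = 1e7) {
  sided <- match.arg(sided)
  vals <- exactNullValues(set, n, cap)
  eps <- 1e-9 * max(1, abs(v))
  p <- if (sided == "one") {
    mean(vals <= v + eps)
  } else {
    mu <- (n + 1) / 2
    mean(abs(vals - mu) >= abs(v - mu) - eps)
  }
  new("NullEstimate", p = p, method = "exact", sided = sided, v = v,
      nSamples = NA_real_, stdError = NA_real_, seed = NA_real_, note = "")
}

#' Compare Monte Carlo and normal-approximation tail estimates
#'
#' Builds weights \eqn{w_i \propto i^l} for \eqn{i = 1, \dots, m}
#' (normalized), takes the set to occupy those weights over a background of
#' `n` genes, and evaluates the one-sided tail probability
#' \eqn{P(V \le v)} at \eqn{v = \mu - j\sigma_w} for
#' \eqn{j = 4, 3, 2, 1}, by Monte Carlo (`K` samples, without replacement)
#' and by the normal approximation \eqn{\Phi(-j)}. Both estimates and
#' their difference (Monte Carlo minus normal) are returned so either sign
#' convention is visible.
#'
#' @param l weight exponent.
#' @param m set size.
#' @param n background size.
#' @param K Monte Carlo sample count.
#' @param seed RNG seed.
#' @return A data.frame with columns `sigmaMultiple`, `v`, `mc`, `normal`,
#'   `diff` (= `mc - normal`) and `se` (binomial SE of the MC estimate).
#' @examples
#' mcNormalComparison(l = 0.5, m = 10, n = 1000, K = 1e5)
#' @export
mcNormalComparison <- function(l, m, n, K = 1e7, seed = 1L) {
  w <- normalizeWeights(seq_len(m)^l)
  set <- WeightedGeneSet(sprintf("g%03d", seq_len(m)), w,
                         normalize = FALSE)
  mu <- (n + 1) / 2
  sw <- sqrt((n^2 - 1) / 12 * sum(w^2))
  j <- 4:1
  v <- mu - j * sw
  samples <- sampleNull(set, n, K, seed)
  mc <- vapply(v, function(x) mean(samples <= x), 0.0)
  norm <- pnorm(-j)
  data.frame(sigmaMultiple = j, v = v, mc = mc, normal = norm,
             diff = mc - norm, se = sqrt(mc * (1 - mc) / K))
}

#' Weighted gene-set test
#'
#' High-level interface: computes the weighted rank statistic for `set`
#' against `ranked` and evaluates its p-value under the chosen null method.
#'
#' @param set a [WeightedGeneSet-class].
#' @param ranked a [RankedGeneList-class].
#' @param method `"mc"` (Monte Carlo without replacement), `"normal"`
#'   (asymptotic approximation), `"exact"` (enumeration; small problems
#'   only) or `"correlated"` (latent multivariate-normal ranks; requires
#'   `corr`).
#' @param sided `"one"` or `"two"`.
#' @param K Monte Carlo sample count (MC methods).
#' @param seed RNG seed (MC methods).
#' @param corr a [CorrelationModel-class] or symmetric matrix over the
#'   background genes, for `method = "correlated"`.
#' @param conservative logical; use the \eqn{(r+1)/(K+1)} MC estimator.
#' @inheritParams setStatistic
#' @return A [NullEstimate-class].
#' @examples
#' rgl <- rankGenes(sprintf("g%02d", 1:50), seq(0.01, 0.99, length = 50))
#' geneSetTest(equalWeightSet(c("g01", "g03", "g05")), rgl, method = "exact")
#' @export
geneSetTest <- function(set, ranked, method = c("mc", "normal", "exact",
                                                "correlated"),
                        sided = c("one", "two"), K = 1e5, seed = 1L,
                        corr = NULL, conservative = FALSE,
                        matchCase = TRUE) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  stat <- setStatistic(set, ranked, matchCase = matchCase)
  n <- stat@n
  switch(method,
    normal = normalPvalue(stat, sided),
    exact = exactPvalue(set, n, stat@v, sided),
    mc = mcPvalue(stat@v, sampleNull(set, n, K, seed), n, sided,
                  conservative, seed = seed),
    correlated = {
      if (is.null(corr))
        stop("method = 'correlated' requires a correlation model")
      samples <- sampleNullCorrelated(set, corr, K, seed,
                                      geneOrder = geneIds(ranked))
      mcPvalue(stat@v, samples, n, sided, conservative,
               method = "correlated_mc", seed = seed)
    })
}
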