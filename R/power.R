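## Rejection-region type-I error and power simulation on normalized ranks.

#' Construct a power simulation scenario
#'
#' @param nu number of gene-level principal components in the F test.
#' @param sampleSize number of subjects k; non-centrality for gene g is
#'   `sampleSize * effects[g]`.
#' @param effects per-gene effect sizes d (0 = null gene).
#' @param alpha target type-I level.
#' @param weights per-gene weights for the weighted-set region
#'   (normalized; default equal).
#' @param replicates number of simulation replicates.
#' @param seed RNG seed.
#' @return A [PowerScenario-class].
#' @examples
#' powerScenario(sampleSize = 1000, effects = c(0.01, 0.002))
#' @export
powerScenario <- function(nu = 10, sampleSize, effects, alpha = 0.05,
                          weights = NULL, replicates = 1e4, seed = 1L) {
  if (is.null(weights)) weights <- rep(1, length(effects))
  new("PowerScenario", nu = as.integer(nu),
      sampleSize = as.integer(sampleSize), effects = as.numeric(effects),
      alpha = as.numeric(alpha), weights = normalizeWeights(weights),
      replicates = as.integer(replicates), seed = as.numeric(seed))
}

setMethod("show", "PowerScenario", function(object) {
  cat(sprintf(
    "PowerScenario: nu = %d, k = %d, %d genes, alpha = %g, %d replicates\n",
    object@nu, object@sampleSize, length(object@effects), object@alpha,
    object@replicates))
})

#' Read a power scenario from a YAML config
#'
#' Expected keys: `nu`, `sample_size` (or `sampleSize`), `effects`,
#' `alpha`, `weights`, `replicates`, `seed`; missing keys take the
#' [powerScenario()] defaults.
#'
#' @param file path to a YAML file.
#' @return A [PowerScenario-class].
#' @export
readPowerScenario <- function(file) {
  cfg <- yaml::read_yaml(file)
  k <- cfg$sample_size
  if (is.null(k)) k <- cfg$sampleSize
  args <- list(sampleSize = k, effects = unlist(cfg$effects))
  for (f in c("nu", "alpha", "replicates", "seed"))
    if (!is.null(cfg[[f]])) args[[f]] <- cfg[[f]]
  if (!is.null(cfg$weights)) args$weights <- unlist(cfg$weights)
  do.call(powerScenario, args)
}

#' Threshold of the weighted-sum rejection region
#'
#' Finds `t` such that the region
#' \eqn{\{u \in [0,1]^m : \sum_i w_i u_i \le t\}} has volume exactly
#' `alpha`, so the set test controls type-I error at `alpha` when
#' normalized ranks are uniform. Closed form (simplex geometry) for
#' \eqn{m \le 2}; for larger m, `t` is the empirical `alpha`-quantile of
#' `K` Monte Carlo draws of \eqn{\sum_i w_i U_i} under a fixed seed.
#'
#' @param weights m normalized weights.
#' @param alpha target region volume in (0, 1).
#' @param K Monte Carlo draws for the m > 2 case.
#' @param seed RNG seed for the m > 2 case.
#' @return The threshold t.
#' @examples
#' sumRegionThreshold(c(0.5, 0.5), 0.05)   # sqrt(0.1)/2
#' @export
sumRegionThreshold <- function(weights, alpha, K = 1e7, seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  w <- normalizeWeights(weights)
  m <- length(w)
  if (m == 1L) return(alpha)
  if (m == 2L) {
    w1 <- max(w); w2 <- min(w)
    # area(t): triangle t^2/(2 w1 w2) while t <= w2; then a trapezoid
    # (2t - w2) / (2 w1) up to t <= w1; then 1 minus the opposite corner.
    aLow <- w2 / (2 * w1)                 # area at t = w2
    aHigh <- 1 - w2 / (2 * w1)            # area at t = w1
    if (alpha <= aLow) return(sqrt(2 * alpha * w1 * w2))
    if (alpha <= aHigh) return(w1 * alpha + w2 / 2)
    return(1 - sqrt(2 * (1 - alpha) * w1 * w2))
  }
  withSeed(seed, {
    chunk <- 2e6
    done <- 0
    # draw in chunks, keep all K weighted sums for the quantile
    out <- numeric(K)
    while (done < K) {
      kc <- min(chunk, K - done)
      u <- matrix(runif(kc * m), m, kc)
      out[done + seq_len(kc)] <- as.vector(w %*% u)
      done <- done + kc
    }
    unname(quantile(out, alpha, type = 7))
  })
}

#' Per-gene cutoff of the multiple-testing-corrected single-gene region
#'
#' Exact-area form: the per-gene cutoff c solves
#' \eqn{1 - (1 - c)^m = \alpha} (Sidak form), so the L-shaped region
#' "any gene's normalized rank below c" has volume exactly `alpha`,
#' making the single-gene baseline directly comparable to the set
#' regions. Bonferroni (`alpha/m`, slightly conservative) is available
#' behind the `method` flag.
#'
#' @param m number of genes tested.
#' @param alpha target region volume.
#' @param method `"sidak"` (exact area) or `"bonferroni"`.
#' @return The per-gene cutoff c.
#' @examples
#' singleGeneThreshold(2, 0.05)   # 1 - sqrt(0.95)
#' @export
singleGeneThreshold <- function(m, alpha,
                                method = c("sidak", "bonferroni")) {
  method <- match.arg(method)
  if (m < 1) stop("'m' must be at least 1")
  if (method == "sidak") 1 - (1 - alpha)^(1 / m) else alpha / m
}

#' Simulate gene-level p-values under the (non)central F model
#'
#' For each replicate and gene, draws the gene's test statistic from a
#' noncentral F with \eqn{\nu - 1} and \eqn{k - \nu} degrees of freedom
#' and non-centrality \eqn{k d_g} (central when \eqn{d_g = 0}), and
#' converts it to a p-value with the central F survival function. Under
#' the null the p-values are exactly uniform.
#'
#' @param scenario a [PowerScenario-class].
#' @return A `replicates x genes` matrix of p-values.
#' @export
simulateGenePvalues <- function(scenario) {
  stopifnot(is(scenario, "PowerScenario"))
  nu <- scenario@nu; k <- scenario@sampleSize
  df1 <- nu - 1; df2 <- k - nu
  R <- scenario@replicates
  withSeed(scenario@seed, {
    vapply(scenario@effects, function(d) {
      f <- if (d == 0) rf(R, df1, df2) else rf(R, df1, df2, ncp = k * d)
      pf(f, df1, df2, lower.tail = FALSE)
    }, numeric(R))
  })
}

#' Estimate power of the single-gene, set, and weighted-set tests
#'
#' Simulated gene p-values are identified with normalized gene ranks (the
#' large-n simplification under which ranks divided by n are uniform),
#' and each method rejects when they fall in its rejection region, all
#' regions having volume `alpha`:
#' single-gene — any p-value below the Sidak-form cutoff; set — the
#' equal-weight mean below its [sumRegionThreshold()]; weighted set — the
#' scenario-weighted sum below its threshold. All methods are evaluated
#' on the same simulated replicates, so comparisons are paired.
#'
#' @param scenario a [PowerScenario-class].
#' @param methods subset of `c("single", "set", "weighted")`.
#' @param singleMethod correction form for the single-gene cutoff, see
#'   [singleGeneThreshold()].
#' @return A data.frame with columns `method`, `power`, `se` (binomial
#'   standard error over replicates).
#' @examples
#' sc <- powerScenario(sampleSize = 1000, effects = c(0.005, 0.005),
#'                     replicates = 2000)
#' estimatePower(sc)
#' @export
estimatePower <- function(scenario,
                          methods = c("single", "set", "weighted"),
                          singleMethod = "sidak") {
  methods <- match.arg(methods, several.ok = TRUE)
  p <- simulateGenePvalues(scenario)
  m <- ncol(p)
  R <- nrow(p)
  alpha <- scenario@alpha
  rej <- lapply(methods, function(meth) {
    switch(meth,
      single = {
        cc <- singleGeneThreshold(m, alpha, singleMethod)
        rowSums(p <= cc) > 0
      },
      set = {
        t0 <- sumRegionThreshold(rep(1 / m, m), alpha)
        as.vector(p %*% rep(1 / m, m)) <= t0
      },
      weighted = {
        tw <- sumRegionThreshold(scenario@weights, alpha)
        as.vector(p %*% scenario@weights) <= tw
      })
  })
  pow <- vapply(rej, mean, 0.0)
  data.frame(method = methods, power = pow,
             se = sqrt(pow * (1 - pow) / R))
}
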