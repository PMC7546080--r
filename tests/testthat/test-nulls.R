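test_that("Monte Carlo null sampling has the permutation-null law", {
  # n = m = 2 with equal weights: the statistic is constant at 1.5
  s2 <- equalWeightSet(c("a", "b"))
  expect_true(all(sampleNull(s2, n = 2, K = 500, seed = 1) == 1.5))
  # null mean is (n+1)/2 whatever the weights
  set.seed(3)
  w <- runif(10)
  s10 <- WeightedGeneSet(sprintf("g%02d", 1:10), w)
  x <- sampleNull(s10, n = 1000, K = 2e5, seed = 4)
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 500.5), 4 * se)
  # small-case tail matches the enumeration oracle
  x4 <- sampleNull(s2, n = 4, K = 2e5, seed = 5)
  pHat <- mean(x4 <= 1.5)
  expect_lt(abs(pHat - 1 / 6), 3 * sqrt(1 / 6 * 5 / 6 / 2e5))
  # reproducible given the seed
  expect_identical(sampleNull(s10, 100, 1000, seed = 9),
                   sampleNull(s10, 100, 1000, seed = 9))
  expect_error(sampleNull(s10, n = 5, K = 10), "background size")
})

test_that("Monte Carlo p-values count tail samples with binomial SE", {
  samp <- c(1.5, 2, 2.5, 3, 3.5)
  est <- mcPvalue(10, samp, n = 10)
  expect_equal(pValue(est), 1)          # v >= max possible V
  est0 <- mcPvalue(0.5, samp, n = 10)
  expect_equal(pValue(est0), 0)
  expect_match(est0@note, "resolution")
  estc <- mcPvalue(0.5, samp, n = 10, conservative = TRUE)
  expect_equal(pValue(estc), 1 / 6)     # (0 + 1)/(5 + 1)
  est2 <- mcPvalue(2, samp, n = 10)
  expect_equal(pValue(est2), 2 / 5)
  expect_equal(stdError(est2), sqrt(0.4 * 0.6 / 5))
})

test_that("two-sided p is at least one-sided p below the null mean", {
  s <- equalWeightSet(letters[1:3])
  x <- sampleNull(s, 20, 5e3, seed = 2)
  for (v in c(2, 4, 7, 10.5)) {
    p1 <- pValue(mcPvalue(v, x, n = 20, sided = "one"))
    p2 <- pValue(mcPvalue(v, x, n = 20, sided = "two"))
    expect_gte(p2, p1)
  }
})

test_that("normal approximation evaluates Phi((v - mu)/sigma_w)", {
  rgl <- makeRanked(1000)
  ids <- geneIds(rgl)[order(geneRanks(rgl))]
  set <- equalWeightSet(ids[c(55, 201, 388, 402, 511, 600, 648, 777, 910,
                              998)])
  st <- setStatistic(set, rgl)
  expect_equal(pValue(normalPvalue(list(v = st@mu, n = 1000, mu = st@mu,
                                        sigmaW = st@sigmaW))), 0.5)
  # v = mu - sigma_w gives Phi(-1)
  expect_equal(
    pValue(normalPvalue(list(v = st@mu - st@sigmaW, mu = st@mu,
                             sigmaW = st@sigmaW))),
    pnorm(-1))
  # printed-formula case: equal weights, m = 10, n = 1000, v = 400
  sw <- sqrt((1e6 - 1) / 12 * 0.1)
  pRef <- pnorm((400 - 500.5) / sw)
  expect_equal(pRef, pnorm(-1.1010), tolerance = 1e-3)
  expect_equal(pValue(normalPvalue(list(v = 400, mu = 500.5, sigmaW = sw))),
               pRef)
  # and the approximation is close to the true MC tail there (allowing
  # for the approximation bias itself, a few 1e-3 at this m and tail)
  x <- sampleNull(set, 1000, 2e5, seed = 8)
  pMc <- mean(x <= 400)
  expect_lt(abs(pMc - pRef), 3 * sqrt(pRef * (1 - pRef) / 2e5) + 6e-3)
  # two-sided symmetry
  p2 <- pValue(normalPvalue(list(v = 400, mu = 500.5, sigmaW = sw),
                            sided = "two"))
  expect_equal(p2, 2 * pRef)
})

test_that("degenerate nulls are refused by the normal approximation", {
  rgl <- makeRanked(4)
  st <- setStatistic(equalWeightSet(geneIds(rgl)), rgl)  # m = n
  expect_error(normalPvalue(st), "degenerate|constant")
  expect_error(normalPvalue(list(v = 1, mu = 1, sigmaW = 0)), "sigma_w")
  # exact method handles it: constant V = mu has p = 1
  expect_equal(pValue(exactPvalue(equalWeightSet(c("a", "b")), 2, 1.5)), 1)
})

test_that("exact enumeration reproduces closed-form small cases", {
  expect_equal(pValue(exactPvalue(WeightedGeneSet("g", 1), 3, 1)), 1 / 3)
  expect_equal(pValue(exactPvalue(equalWeightSet(c("a", "b")), 4, 1.5)),
               1 / 6)
  expect_error(exactPvalue(equalWeightSet(letters[1:3]), 500, 10),
               "cap|Monte Carlo")
})

test_that("exact enumeration agrees with the independent injection oracle", {
  for (seed in 1:10) {
    set.seed(100 + seed)
    n <- sample(3:8, 1)
    m <- sample(1:min(3, n - 1), 1)
    w <- normalizeWeights(runif(m) + 0.05)
    set <- WeightedGeneSet(letters[1:m], w, normalize = FALSE)
    vals <- oracleNullValues(w, n)
    for (v in sample(unique(vals), min(5, length(unique(vals))))) {
      expect_equal(pValue(exactPvalue(set, n, v)),
                   oracleTailProb(w, n, v))
    }
    # null symmetry about mu: P(V <= mu - x) = P(V >= mu + x)
    mu <- (n + 1) / 2
    for (x in c(0.3, 0.9, 1.7)) {
      expect_equal(mean(vals <= mu - x + 1e-9),
                   mean(vals >= mu + x - 1e-9))
      expect_equal(pValue(exactPvalue(set, n, mu - x)),
                   mean(vals <= mu - x + 1e-9))
    }
  }
})

test_that("equal-weight enumeration shortcut matches the injection oracle", {
  w <- rep(0.25, 4)
  set <- equalWeightSet(letters[1:4])
  vals <- oracleNullValues(w, 7)
  for (v in c(1.9, 2.5, 3.25, 4))
    expect_equal(pValue(exactPvalue(set, 7, v)), oracleTailProb(w, 7, v))
})

test_that("normal approximation error at mu - sigma shrinks as the set grows", {
  # needs m/n small throughout: the with-replacement variance overshoots
  # by the finite-population factor (n-m)/(n-1), so the approximation
  # converges in m only away from m ~ n. Reference tail by MC (validated
  # against the enumeration oracle elsewhere); K large enough that the
  # error differences (~1e-2 .. 3e-3) dwarf the MC noise (~2e-4).
  n <- 1000
  err <- vapply(c(2, 5, 8), function(m) {
    set <- equalWeightSet(letters[1:m])
    sw <- sqrt((n^2 - 1) / 12 / m)
    v <- (n + 1) / 2 - sw
    pMc <- mean(sampleNull(set, n, K = 4e6, seed = 50 + m) <= v)
    abs(pnorm(-1) - pMc)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("MC estimator is unbiased against the enumeration value", {
  set <- WeightedGeneSet(c("a", "b"), c(0.7, 0.3), normalize = FALSE)
  n <- 6; v <- 2.1
  pExact <- oracleTailProb(c(0.7, 0.3), n, v)
  K <- 2000; R <- 60
  pHat <- vapply(seq_len(R), function(r)
    mean(sampleNull(set, n, K, seed = 1000 + r) <= v), numeric(1))
  se <- sqrt(pExact * (1 - pExact) / K)
  expect_lt(abs(mean(pHat) - pExact), 3 * se / sqrt(R))
})

test_that("MC/normal comparison grid reports both estimates and their difference", {
  cmp <- mcNormalComparison(l = 0, m = 10, n = 1000, K = 5e4, seed = 2)
  expect_equal(cmp$sigmaMultiple, 4:1)
  expect_equal(cmp$normal, pnorm(-(4:1)))
  expect_equal(cmp$diff, cmp$mc - cmp$normal)
  # l = 0 means equal weights: sigma_w^2 = (n^2-1)/(12 m)
  sw <- sqrt((1000^2 - 1) / 12 / 10)
  expect_equal(cmp$v, 500.5 - (4:1) * sw)
  # at mu - sigma the MC tail is near Phi(-1)
  expect_lt(abs(cmp$mc[4] - pnorm(-1)), 0.02)
})

test_that("the high-level test wrapper ties the pieces together", {
  rgl <- makeRanked(50)
  topSet <- equalWeightSet(geneIds(rgl)[order(geneRanks(rgl))][1:3])
  pEx <- pValue(geneSetTest(topSet, rgl, method = "exact"))
  expect_equal(pEx, oracleTailProb(rep(1 / 3, 3), 50, 2))
  pMc <- pValue(geneSetTest(topSet, rgl, method = "mc", K = 5e4,
                            seed = 3))
  expect_lt(abs(pMc - pEx), 3 * sqrt(pEx * (1 - pEx) / 5e4))
  est <- geneSetTest(topSet, rgl, method = "mc", K = 100, seed = 17)
  expect_equal(est@seed, 17)
  expect_equal(est@nSamples, 100)
})
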