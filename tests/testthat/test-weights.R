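test_that("Latin hypercube sample stratifies each marginal exactly", {
  ps <- ParameterSet(c("a", "b", "c"), c(1, -4, 0.316),
                     genes = list("G1", "G2", "G3"))
  N <- 64
  X <- latinHypercubeNormal(ps, N = N, sdFrac = 0.05, seed = 7)
  expect_equal(dim(X), c(N, 3))
  expect_equal(colnames(X), c("a", "b", "c"))
  b <- baselines(ps)
  for (j in 1:3) {
    u <- pnorm(X[, j], mean = b[j], sd = 0.05 * abs(b[j]))
    # exactly one draw per equal-probability stratum
    expect_equal(sort(floor(u * N)), 0:(N - 1))
  }
  # reproducibility
  expect_identical(X, latinHypercubeNormal(ps, N = N, seed = 7))
  expect_false(identical(X, latinHypercubeNormal(ps, N = N, seed = 8)))
})

test_that("LHS marginals track baseline and 5% standard deviation", {
  ps <- ParameterSet("gCaL", 0.316, "mS cm-1", genes = list("CACNA1C"))
  X <- latinHypercubeNormal(ps, N = 320, sdFrac = 0.05, seed = 11)
  expect_lt(abs(mean(X[, 1]) - 0.316), 0.002)
  expect_lt(abs(sd(X[, 1]) - 0.0158) / 0.0158, 0.1)
})

test_that("zero baselines need an absolute-sd override", {
  ps0 <- ParameterSet(c("a", "b"), c(0, 2), genes = list("G1", "G2"))
  expect_error(latinHypercubeNormal(ps0, N = 16), "zero baseline")
  X <- latinHypercubeNormal(ps0, N = 64, sd = c(a = 0.5, b = 0.1),
                            seed = 3)
  expect_lt(abs(sd(X[, "a"]) - 0.5) / 0.5, 0.2)
})

test_that("model evaluation applies row-wise and surfaces bad outputs", {
  X <- matrix(1:6, 3, 2, dimnames = list(NULL, c("p1", "p2")))
  expect_equal(evaluateModel(function(p) 2, X), rep(2, 3))
  expect_equal(evaluateModel(function(p) p[["p1"]], X), c(1, 2, 3))
  expect_error(evaluateModel(function(p) if (p[["p1"]] == 2) NaN else 1, X),
               "non-finite.*2")
})

test_that("the calcium surrogate is monotone in the documented directions", {
  b <- baselines(calciumParameters())
  base <- calciumSurrogate(b)
  expect_equal(base, 0.75 / 2.05)
  # strictly increasing in NMDA permeability
  up <- vapply(seq(0.9, 1.1, length.out = 7), function(f) {
    p <- b; p["PNMDA"] <- p["PNMDA"] * f; calciumSurrogate(p)
  }, numeric(1))
  expect_true(all(diff(up) > 0))
  # strictly decreasing in SERCA uptake amplitude
  dn <- vapply(seq(0.9, 1.1, length.out = 7), function(f) {
    p <- b; p["Vmax"] <- p["Vmax"] * f; calciumSurrogate(p)
  }, numeric(1))
  expect_true(all(diff(dn) < 0))
  expect_error(calciumSurrogate(b[-1]), "gamma0")
})

test_that("PRCC recovers perfect monotone dependence with its sign", {
  set.seed(5)
  X <- matrix(rnorm(300), 100, 3,
              dimnames = list(NULL, c("x1", "x2", "x3")))
  s1 <- prcc(X, exp(X[, 1]))            # monotone in x1 only
  r1 <- prccValues(s1)
  expect_gt(r1["x1"], 0.99)
  expect_lt(max(abs(r1[c("x2", "x3")])), 0.3)
  r2 <- prccValues(prcc(X, -X[, 2]))
  expect_lt(r2["x2"], -0.99)
  expect_error(prcc(X[1:4, ], rnorm(4)), "degrees of freedom")
  Xc <- X; Xc[, 2] <- 1
  expect_error(prcc(Xc, X[, 1]), "constant")
})

test_that("PRCC separates signal from noise in a known generative model", {
  hits <- vapply(1:60, function(r) {
    set.seed(4000 + r)
    X <- matrix(rnorm(960), 320, 3,
                dimnames = list(NULL, c("x1", "x2", "x3")))
    y <- 2 * X[, 1] - X[, 2] + rnorm(320, sd = 0.5)
    rho <- prccValues(prcc(X, y))
    rho["x1"] > 0 && rho["x2"] < 0 && abs(rho["x3"]) < 0.15
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("PRCC permutation null is calibrated at the 5% level", {
  nRep <- 400
  exceed <- vapply(seq_len(nRep), function(r) {
    set.seed(7000 + r)
    X <- matrix(rnorm(50 * 3), 50, 3,
                dimnames = list(NULL, c("a", "b", "c")))
    y <- rnorm(50)                      # independent of every column
    obs <- abs(prccValues(prcc(X, y))[["a"]])
    perm <- vapply(1:60, function(i)
      abs(prccValues(prcc(X, sample(y)))[["a"]]), numeric(1))
    obs > quantile(perm, 0.95, type = 1)
  }, logical(1))
  rate <- mean(exceed)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / nRep) + 0.02)
})

test_that("permutation significance helper flags only influential parameters", {
  set.seed(9)
  X <- matrix(rnorm(600), 200, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(200, sd = 0.2)
  out <- prccPermutationTest(X, y, nPerm = 99, seed = 2)
  expect_equal(out$parameter, c("a", "b", "c"))
  expect_lt(out$p[1], 0.05)
  expect_gt(min(out$p[2:3]), 0.05)
})

test_that("LHS reduces the variance of a monotone mean estimator", {
  ps <- ParameterSet(c("a", "b"), c(1, 2), genes = list("G1", "G2"))
  f <- function(x) x[, 1] + x[, 2]      # monotone in both
  estL <- estS <- numeric(200)
  for (r in 1:200) {
    X <- latinHypercubeNormal(ps, N = 16, seed = 5000 + r)
    estL[r] <- mean(f(X))
    set.seed(5000 + r)
    S <- cbind(rnorm(16, 1, 0.05), rnorm(16, 2, 0.1))
    estS[r] <- mean(f(S))
  }
  expect_lt(var(estL), var(estS))
})

test_that("gene weights follow the |rho|/N rule with global renormalization", {
  ps <- ParameterSet(c("A", "B"), c(1, 2),
                     genes = list(c("G1", "G2"), "G3"))
  mkSens <- function(rho) new("SensitivityResult",
                              parameter = c("A", "B"), rho = rho,
                              n = 100L, output = "y")
  w <- geneWeights(geneWeightsFromPrcc(mkSens(c(0.5, -0.5)), ps))
  expect_equal(unname(w), c(0.25, 0.25, 0.5))
  # single parameter, any nonzero rho: equal split
  ps1 <- ParameterSet("A", 1, genes = list(sprintf("G%d", 1:4)))
  s1 <- new("SensitivityResult", parameter = "A", rho = -0.3, n = 50L,
            output = "y")
  expect_equal(unname(geneWeights(geneWeightsFromPrcc(s1, ps1))),
               rep(0.25, 4))
  # zero-PRCC parameter: its genes get weight 0, others renormalize
  w0 <- geneWeights(geneWeightsFromPrcc(mkSens(c(0, 0.4)), ps))
  expect_equal(unname(w0), c(0, 0, 1))
  # magnitude-only and scale invariance
  wFlip <- geneWeights(geneWeightsFromPrcc(mkSens(c(-0.5, 0.5)), ps))
  expect_equal(wFlip, w)
  wScaled <- geneWeights(geneWeightsFromPrcc(mkSens(c(0.1, -0.1)), ps))
  expect_equal(wScaled, w)
})

test_that("per-parameter total weight is proportional to |rho|, not gene count", {
  ps <- ParameterSet(c("A", "B"), c(1, 1),
                     genes = list(sprintf("a%d", 1:8), "b1"))
  sens <- new("SensitivityResult", parameter = c("A", "B"),
              rho = c(0.6, 0.3), n = 100L, output = "y")
  w <- geneWeights(geneWeightsFromPrcc(sens, ps))
  totalA <- sum(w[sprintf("a%d", 1:8)])
  expect_equal(totalA / w[["b1"]], 0.6 / 0.3)
})

test_that("genes mapped to several parameters need the multi-map flag", {
  ps <- ParameterSet(c("A", "B"), c(1, 1),
                     genes = list(c("G1", "G2"), c("G2", "G3")))
  sens <- new("SensitivityResult", parameter = c("A", "B"),
              rho = c(0.4, 0.2), n = 100L, output = "y")
  expect_error(geneWeightsFromPrcc(sens, ps), "G2.*multiMap")
  w <- geneWeights(geneWeightsFromPrcc(sens, ps, multiMap = TRUE))
  raw <- c(G1 = 0.2, G2 = 0.2 + 0.1, G3 = 0.1)
  expect_equal(w, raw / sum(raw))
})

test_that("the packaged calcium mapping has the published structure", {
  ps <- calciumParameters()
  expect_equal(length(ps), 13L)
  expect_equal(sum(lengths(mappedGenes(ps))), 65L)
  expect_setequal(unlist(ps@excluded),
                  c("ATP2B3", "CACNA1F", "GRIA3", "KCND1"))
  expect_equal(sum(lengths(mappedGenes(ps, includeExcluded = TRUE))), 69L)
  b <- baselines(ps)
  expect_equal(unname(b["gCaL"]), 0.316)
  expect_equal(unname(b["gNa"]), 90)
  expect_equal(unname(b["PNMDA"]), 1.938107025)
  # no gene appears under two parameters
  expect_equal(anyDuplicated(unlist(mappedGenes(ps))), 0L)
})

test_that("the surrogate-to-weights pipeline produces a valid 65-gene set", {
  ps <- calciumParameters()
  X <- latinHypercubeNormal(ps, N = 320, sdFrac = 0.05, seed = 13)
  y <- evaluateModel(calciumSurrogate, X)
  expect_true(all(is.finite(y)))
  sens <- prcc(X, y)
  rho <- prccValues(sens)
  expect_gt(rho[["PNMDA"]], 0)
  expect_lt(rho[["Vmax"]], 0)
  w <- geneWeightsFromPrcc(sens, ps)
  expect_s4_class(w, "WeightedGeneSet")
  expect_equal(setSize(w), 65L)
  expect_equal(sum(geneWeights(w)), 1)
})
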