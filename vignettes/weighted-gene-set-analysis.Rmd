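---
title: "Model-weighted gene-set analysis: methods and design"
author: "mbgsa package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-weighted gene-set analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbgsa)
```

# The statistic and its interpretation

A competitive gene-set test asks whether a phenotype is more strongly
associated with the genes in a set than with genes outside it. `mbgsa`
implements a weighted rank-sum form of this question. The inputs are

* a background of $n$ genes, each with a rank $r_i \in \{1,\dots,n\}$
  from any gene-level association analysis (rank 1 = smallest p-value,
  i.e. strongest association), and
* a set $S$ of $m$ genes with non-negative weights $w_i$, stored
  normalized so $\sum_{i \in S} w_i = 1$.

The test statistic is the weighted sum of the set genes' ranks,

$$v = \sum_{i \in S} w_i\, r_i .$$

Small $v$ means the set's genes sit disproportionately near the top of
the ranking, weighted by their hypothesized contribution. Equal weights
$w_i = 1/m$ recover an unweighted test ($v$ is the set's mean rank); a
single unit weight recovers a single-gene test ($v$ is that gene's
rank); a zero weight removes a gene from the statistic entirely. The
centered statistic $v - (n+1)/2$ changes sign when the ranking is
reversed.

Weights encode an a priori hypothesis about relative contribution to a
biological function. They can come from anywhere (networks, experiments,
literature), but the pipeline in this package derives them from a
mathematical model of the biological function of interest, via global
sensitivity analysis (below).

# Null distributions

Under the null hypothesis that the set's genes were chosen uniformly at
random from the background, the set genes' ranks $R_i$ are a uniformly
random draw without replacement from $\{1,\dots,n\}$ and
$V = \sum_{i \in S} w_i R_i$ is the null statistic. The one-sided
p-value is $P(V \le v)$; the two-sided version uses
$P(|V - \tfrac{n+1}{2}| \ge |v - \tfrac{n+1}{2}|)$. Four estimators are
provided:

* **Monte Carlo** (`sampleNull()` + `mcPvalue()`, or
  `geneSetTest(method = "mc")`): draws $K$ samples of $V$ and counts the
  proportion at or below $v$. The plain proportion is used because it is
  unbiased with variance $P(V \le v)/K$ in the small-$p$ regime; the
  conservative $(r+1)/(K+1)$ estimator is available behind
  `conservative = TRUE` for inference when $\hat p$ can be 0. A zero
  estimate is flagged with its $1/K$ resolution rather than silently
  reported. Sampling is implemented as a partial Fisher–Yates shuffle
  with an $O(m)$ undo step per draw (compiled code, R's RNG), so
  $K = 10^7$ is a matter of seconds.
* **Normal approximation** (`normalPvalue()`):
  $\Phi\!\big((v-\mu)/\sigma_w\big)$ with $\mu = (n+1)/2$ and
  $\sigma_w^2 = [(n^2-1)/12]\sum_{i\in S} w_i^2$, the moments of the
  with-replacement relaxation of the null. `mcNormalComparison()`
  quantifies its accuracy on a grid $v = \mu - j\sigma_w$,
  $j = 4,\dots,1$, returning both estimates and their difference
  (Monte Carlo minus normal — both columns are printed so either sign
  convention is checkable).
* **Exact enumeration** (`exactPvalue()`): enumerates every equally
  likely assignment of distinct ranks to the positive-weight genes.
  When the positive weights are all equal the statistic is symmetric in
  the ranks, so unordered combinations suffice and much larger sets
  become enumerable; otherwise all ordered arrangements are generated.
  A cap (default $10^7$ arrangements) guards against blow-up. This is
  the oracle the test suite validates the other estimators against.
* **Correlated ranks** (`sampleNullCorrelated()`,
  `geneSetTest(method = "correlated")`): draws a latent vector from
  $N(0, \Sigma)$ over all $n$ genes, ranks it, and forms $V$ from the
  set genes' ranks. $\Sigma = I$ reduces exactly to the permutation
  null; correlation among set genes inflates the spread of $V$.
  `adjustCorrelation()` prepares an estimated $\Sigma$ that is not
  positive definite by clipping its eigenvalues from below at a floor
  (default $10^{-6}$) while leaving the eigenvectors — and hence the
  correlation structure's principal directions — untouched. The
  diagonal is not re-standardized after clipping, matching the
  eigenvalue-only repair.

## Numerical choices and degenerate inputs

* $P(V \le v)$ uses non-strict $\le$; enumeration comparisons use a
  $10^{-9}$ relative tolerance so that floating-point representations of
  attainable values of the discrete statistic count as ties.
* Ranks tied on identical p-values are broken by input order by default
  (deterministic), or by a seeded random shuffle (`ties = "random"`).
  The choice can move borderline genes by a few ranks; it is a declared
  policy, not a claim about any upstream ranking tool.
* Zero-weight genes are dropped before sampling or enumeration: their
  ranks never enter $V$, and the remaining genes' ranks keep the same
  marginal law. Removing a zero-weight gene therefore reproduces the
  identical Monte Carlo sample path under the same seed.
* An equal-weight set covering the whole background makes $V$ constant;
  `normalPvalue()` refuses this case (the with-replacement variance is
  not the truth there) and directs to the exact or MC method.
* Every stochastic routine takes a `seed` argument (default 1) and
  records it in its result; the caller's RNG state is restored.
* Gene identifiers match exactly and case-sensitively by default, with
  an opt-in `matchCase = FALSE` uppercasing; silent case-folding can
  hide upstream data errors.

## Accuracy of the normal approximation

The with-replacement variance $\sigma_w^2$ overshoots the true null
variance by the finite-population factor $(n-m)/(n-1)$. The
approximation error at a fixed standardized tail point therefore behaves
like $c_1\, m/n + c_2/m$: it shrinks as the set grows *only while
$m/n$ stays small*, and grows again when the set is an appreciable
fraction of the background (at $n = 12$, $m = 8$ the one-sided error at
$\mu - \sigma_w$ is about 0.10). This is why the package's accuracy
tests hold $m/n$ small when demonstrating convergence, and why the MC
method is the default.

# Model-derived gene weights

The weight pipeline turns a model of a biological function into gene
weights in four steps:

1. **Parameter mapping** (`ParameterSet`, `calciumParameters()`): each
   model parameter $k$ has a baseline value, units, and the list of
   $N_k$ genes mapped to it. The packaged example maps 13 parameters of
   a CA1 pyramidal-cell calcium-handling model (channel and pump
   conductances/rates, receptor densities/permeabilities) to 65
   analyzed genes, with four further genes carried as excluded because
   no gene rank was available for them.
2. **Latin hypercube sampling** (`latinHypercubeNormal()`): $N$
   parameter vectors (default 320) with independent normal marginals
   centered at the baselines, standard deviation 5% of each baseline
   (`sdFrac = 0.05`; absolute overrides available for zero baselines).
   Placement within each equal-probability stratum is uniform random,
   not midpoint, so distributional tests remain meaningful.
3. **PRCC** (`prcc()`): for each parameter, all columns and the model
   output are rank-transformed (average ranks on ties); the parameter's
   and output's ranks are each regressed (OLS with intercept) on the
   other parameters' ranks, and the PRCC $\rho_k$ is the correlation of
   the residuals — a monotone-influence measure controlling for the
   other parameters. Estimation requires $N > P + 2$ and no constant
   column. No p-values are attached by default; a permutation option
   (`prccPermutationTest()`) exists off the main path.
4. **Weight rule** (`geneWeightsFromPrcc()`): every gene of parameter
   $k$ gets raw weight $|\rho_k|/N_k$, then weights are renormalized to
   sum to 1. Only the magnitude is used (association measures carry no
   direction specific enough to exploit), and the $N_k$ division keeps
   a model component from dominating merely because many genes map to
   it. A gene mapped to several parameters is an error unless
   `multiMap = TRUE`, which sums its $|\rho_k|/N_k$ contributions — an
   implementation choice for a case the method itself leaves open.

## The bundled surrogate

A full biophysical simulation is outside this package's scope.
`calciumSurrogate()` is a smooth rational surrogate of mean
intracellular Ca$^{2+}$ during an induced transient:
$0.75\,\frac{\sum_i a_i\,p_i/b_i}{1 + \sum_j c_j\,p_j/b_j}$ over
baseline-scaled parameters, strictly increasing in every influx/release
parameter and strictly decreasing in every efflux/repolarization
parameter, with NMDA-receptor permeability the strongest positive and
SERCA uptake the strongest negative influence — the qualitative
sensitivity structure reported for the full model. Its coefficients are
fixed package constants; the baseline output is exactly $0.75/2.05$.
It exists so the LHS → PRCC → weights pipeline is fully testable; PRCC
magnitudes derived from it are surrogate properties, not predictions of
the real model.

```{r weights-pipeline}
ps <- calciumParameters()
X <- latinHypercubeNormal(ps, N = 320, sdFrac = 0.05, seed = 1)
y <- evaluateModel(calciumSurrogate, X)
sens <- prcc(X, y, output = "mean Ca proxy")
round(prccValues(sens), 2)
w <- geneWeightsFromPrcc(sens, ps)
head(sort(geneWeights(w), decreasing = TRUE))
```

# Type-I error and power framework

For power analysis the package adopts the simplification that a gene's
normalized rank $r_i/n$ behaves as its p-value (exact as
$n \to \infty$; finite-$n$ rank discreteness is deliberately ignored).
Gene-level statistics follow a noncentral $F(\nu - 1,\, k - \nu)$ with
noncentrality $k d_g$ for sample size $k$ and effect $d_g$
(`simulateGenePvalues()`; $\nu$ defaults to 10 principal components).
Three rejection regions on $[0,1]^m$, all of volume exactly $\alpha$:

* **single-gene**: any $u_i \le c$ with $1-(1-c)^m = \alpha$ (the
  exact-area Šidák form, so the comparison with the set tests is fair;
  Bonferroni $\alpha/m$ — area $0.049375$ at $m=2,\ \alpha=0.05$ — is
  available behind a flag);
* **set**: $\frac{1}{m}\sum u_i \le t$;
* **weighted set**: $\sum w_i u_i \le t_w$.

`sumRegionThreshold()` solves for $t$ in closed form for $m \le 2$
(simplex geometry: the $\alpha=0.05$ equal-weight threshold is
$\sqrt{0.1}/2 \approx 0.158$) and by the empirical $\alpha$-quantile of
$10^7$ seeded Monte Carlo draws of $\sum w_i U_i$ otherwise.
`estimatePower()` evaluates all requested methods on the *same*
simulated replicates, so method comparisons are paired.

# Synthetic data

`generateGeneResults()` emulates gene-level association output: every
gene gets a latent $z \sim N(0,1)$, signal genes a shift $\delta_i$,
and the reported p-value is $2\Phi(-|z|)$. Null p-values are exactly
uniform, so the permutation null of the downstream test is valid under
no signal, while $\delta$ controls rank enrichment under signal —
injecting signal on the latent scale rather than on ranks keeps those
two regimes cleanly separated. `generateBlockCorrelation()` builds
positive semidefinite block correlation structures for the correlated
null. `goldenExample()` bundles a deterministic worked example: the
13-parameter/65-gene calcium mapping, surrogate-derived weights, a
2,000-gene synthetic ranked background with signal planted on the
mapped genes, and a 182-member pathway-style comparison set in which
identifiers beyond the mapped family members are synthetic
(`SYNCA...`).

What the generators do **not** emulate: linkage disequilibrium and
SNP-level structure, the dependence of gene-level p-values on gene
length or SNP count, inter-gene correlation in the *observed* ranks
(only the latent correlated null models that), and real pathway
membership. Passing tests therefore demonstrate the statistical
machinery — calibration, power ordering, estimator agreement — not
properties of any real GWAS dataset.

# Validation problem sizes

The test suite validates estimators against exhaustive enumeration on
all backgrounds $n \le 8$ with sets $m \le 3$ (every attainable value
of the statistic), reproduces the published MC-vs-normal tail
comparison at $K = 10^7$ samples for the $m = 10$ rows and $K = 4\times
10^6$ for the $m = 100$ rows, calibrates the full synthetic pipeline
over 2,000 null replicates ($n = 500$ genes, $m = 10$, $K = 10^4$ MC
samples per test), checks all three rejection-region areas at
$K = 10^7$, and verifies PRCC sign recovery over 500 replicates of a
known generative model ($y = 2x_1 - x_2 + \varepsilon$,
$\mathrm{sd}(\varepsilon) = 0.5$, $N = 320$ samples). Monte Carlo
assertions use binomial standard-error bounds; where hundreds of cells
are checked at a $3\sigma$ level the suite asserts the equivalent
aggregate statement (nominal $3\sigma$ exceedance rate, nothing beyond
$5\sigma$) rather than pretending independent certainty per cell.

# Known limitations

* The null models random set membership; it does not model correlation
  between observed gene ranks beyond the latent-normal device, nor
  does it estimate $\Sigma$ from data (an external estimate is taken
  as given).
* Weights are only as good as the model and the gene-to-parameter map;
  a gene's weight is a model prediction, not a measurement.
* The power framework treats genes as independent and identifies
  normalized ranks with p-values; both idealizations are inherited
  design choices, kept so the rejection-region geometry stays exact.
* PRCC measures monotone influence only; strongly non-monotone
  parameter effects need a variance-decomposition method instead and
  are out of scope.
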