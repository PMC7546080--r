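## Gene-gene correlation: eigenvalue adjustment and the correlated null.

#' Adjust a correlation matrix to be positive definite
#'
#' Eigendecomposes a symmetric matrix, clips eigenvalues from below at
#' `eigenFloor`, and reassembles with the original eigenvectors. An
#' already positive definite matrix (all eigenvalues at or above the
#' floor) is returned unchanged up to numerical tolerance.
#'
#' @param x symmetric numeric matrix (unit diagonal expected for a
#'   correlation matrix; the diagonal may deviate slightly after
#'   adjustment, which is left alone just as the eigenvectors are).
#' @param eigenFloor minimum eigenvalue of the result.
#' @return A [CorrelationModel-class].
#' @examples
#' m <- matrix(c(1, 1, 1, 1), 2, 2)  # rank deficient
#' eigen(correlationMatrix(adjustCorrelation(m)))$values
#' @export
adjustCorrelation <- function(x, eigenFloor = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) stop("correlation matrix must be square")
  if (max(abs(x - t(x))) > 1e-8)
    stop("correlation matrix must be symmetric")
  e <- eigen((x + t(x)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, eigenFloor)
  adj <- e$vectors %*% (vals * t(e$vectors))
  dimnames(adj) <- dimnames(x)
  new("CorrelationModel", matrix = (adj + t(adj)) / 2,
      eigenFloor = eigenFloor)
}

#' @rdname adjustCorrelation
#' @param object a [CorrelationModel-class].
#' @export
correlationMatrix <- function(object) {
  stopifnot(is(object, "CorrelationModel"))
  object@matrix
}

setMethod("show", "CorrelationModel", function(object) {
  cat(sprintf("CorrelationModel: %d x %d, eigen floor %g\n",
              nrow(object@matrix), ncol(object@matrix),
              object@eigenFloor))
})

#' Sample the correlated null of the weighted rank statistic
#'
#' Accounts for gene-gene correlation by drawing a latent vector
#' \eqn{(\epsilon_1, \dots, \epsilon_n)} from a zero-mean multivariate
#' normal with covariance \eqn{\Sigma} (the adjusted correlation matrix),
#' letting \eqn{R_i} be the rank of \eqn{\epsilon_i} among all \eqn{n}
#' entries, and forming \eqn{V = \sum_{i \in S} w_i R_i}. With
#' \eqn{\Sigma = I} this reduces to the uniform-permutation null.
#'
#' @param set a [WeightedGeneSet-class].
#' @param corr a [CorrelationModel-class], or a symmetric matrix which is
#'   passed through [adjustCorrelation()] first. Its dimension is the
#'   background size `n`. Set genes are located by the matrix dimnames,
#'   or by `geneOrder`.
#' @param K number of samples.
#' @param seed RNG seed.
#' @param geneOrder optional character vector giving the background gene
#'   order corresponding to the matrix rows, used when the matrix carries
#'   no dimnames.
#' @param chunkSize draws are generated in chunks of this many samples to
#'   bound memory.
#' @return Numeric vector of `K` null samples of \eqn{V}.
#' @export
sampleNullCorrelated <- function(set, corr, K = 1e5, seed = 1L,
                                 geneOrder = NULL, chunkSize = NULL) {
  stopifnot(is(set, "WeightedGeneSet"))
  if (!is(corr, "CorrelationModel")) corr <- adjustCorrelation(corr)
  M <- corr@matrix
  n <- nrow(M)
  ids <- rownames(M)
  if (is.null(ids) && !is.null(geneOrder)) {
    if (length(geneOrder) != n)
      stop("'geneOrder' length must match the correlation dimension")
    ids <- geneOrder
  }
  w <- positiveWeights(set)
  if (is.null(ids)) {
    if (setSize(set) > n) stop("dimension mismatch: set larger than Sigma")
    stop("correlation matrix has no dimnames; supply 'geneOrder' to ",
         "locate the set genes")
  }
  idx <- match(names(w), ids)
  if (anyNA(idx))
    stop("set genes absent from the correlation matrix: ",
         paste(names(w)[is.na(idx)], collapse = ", "))
  L <- t(chol(M))
  if (is.null(chunkSize)) chunkSize <- max(1L, floor(4e6 / n))
  withSeed(seed, {
    out <- numeric(K)
    done <- 0L
    while (done < K) {
      kc <- min(chunkSize, K - done)
      eps <- L %*% matrix(rnorm(n * kc), n, kc)
      rk <- cpp_col_ranks(eps)
      out[done + seq_len(kc)] <- as.vector(w %*% rk[idx, , drop = FALSE])
      done <- done + kc
    }
    out
  })
}
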