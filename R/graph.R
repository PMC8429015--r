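#' Build a kNN heat-kernel affinity graph
#'
#' Computes \eqn{w_{ij} = \exp(-\|x_i - x_j\|_2^2 / (2\sigma^2))} whenever
#' subject i is among the k nearest neighbours of subject j (i != j), zero
#' otherwise, and then symmetrizes by the elementwise maximum (union-kNN),
#' so the graph is undirected as the regularizer requires. Nearest-neighbour
#' ties are broken by lowest subject index.
#'
#' When `sigma` is `NULL` the bandwidth is set by the median heuristic: the
#' median Euclidean distance over the retained kNN pairs. A degenerate
#' all-coincident neighbourhood (median distance 0) falls back to
#' `sigma = 1`, which still yields the correct unit weights.
#'
#' @param X d x n feature matrix (features in rows, subjects in columns).
#' @param k neighbour count, `1 <= k <= n - 1`.
#' @param sigma fixed heat-kernel bandwidth (> 0), or `NULL` for the median
#'   heuristic.
#' @param viewTag label recording the originating view.
#' @return an [AffinityGraph-class].
#' @examples
#' X <- rbind(c(0, 1, 10))           # three 1-D subjects
#' g <- buildAffinity(X, k = 1, sigma = sqrt(0.5))
#' g@W[1, 2]                          # exp(-1)
#' @export
buildAffinity <- function(X, k, sigma = NULL, viewTag = "CT") {
  X <- as.matrix(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least 2 subjects to build a graph", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L || k >= n)
    stop("k must satisfy 1 <= k <= n - 1 (got k = ", k, ", n = ", n, ")",
         call. = FALSE)
  if (!is.null(sigma) && !(sigma > 0))
    stop("fixed sigma must be > 0", call. = FALSE)
  stopIfNotFinite(X, "X")

  D2 <- as.matrix(dist(t(X)))^2
  # directed membership: mask[i, j] = TRUE iff x_i in N_k(x_j)
  mask <- matrix(FALSE, n, n)
  for (j in seq_len(n)) {
    ord <- order(D2[, j])            # stable: ties broken by lowest index
    ord <- ord[ord != j]
    mask[ord[seq_len(k)], j] <- TRUE
  }
  if (is.null(sigma)) {
    sigma <- median(sqrt(D2[mask]))
    if (!(sigma > 0)) sigma <- 1
  }
  W <- exp(-D2 / (2 * sigma^2))
  W[!mask] <- 0
  W <- pmax(W, t(W))                 # undirected: union of neighbourhoods
  diag(W) <- 0
  new("AffinityGraph", W = W, k = k, sigma = as.numeric(sigma),
      viewTag = as.character(viewTag))
}

#' Build the graph Laplacian L = D - W
#'
#' @param graph an [AffinityGraph-class], or a symmetric nonnegative weight
#'   matrix.
#' @return a [GraphLaplacian-class] with `L = D - W`, `D_ii = sum_j w_ij`.
#' @export
buildLaplacian <- function(graph) {
  W <- if (is(graph, "AffinityGraph")) graph@W else as.matrix(graph)
  checkSymmetric(W)
  deg <- rowSums(W)
  L <- -W
  diag(L) <- deg - diag(W)
  new("GraphLaplacian", L = L, degree = deg)
}

#' Graph-smoothness penalty of a projection
#'
#' Evaluates \eqn{\mathrm{tr}(P^T X L X^T P)}, the Laplacian quadratic form
#' of the projected data: it equals
#' \eqn{\frac{1}{2}\sum_{ij} w_{ij}\|a_i - a_j\|^2} where \eqn{a_i} is the
#' i-th column of \eqn{P^T X}, so it is small when graph-neighbouring
#' subjects stay close after projection.
#'
#' @param P d x c projection matrix.
#' @param X d x n feature matrix.
#' @param L a [GraphLaplacian-class] or an n x n Laplacian matrix.
#' @return nonnegative scalar.
#' @export
smoothness <- function(P, X, L) {
  Lm <- if (is(L, "GraphLaplacian")) L@L else as.matrix(L)
  P <- as.matrix(P); X <- as.matrix(X)
  if (nrow(P) != nrow(X))
    stop("P and X must agree on the feature dimension d", call. = FALSE)
  if (nrow(Lm) != ncol(X))
    stop("L must be n x n with n = ncol(X)", call. = FALSE)
  A <- crossprod(X, P)               # n x c projected samples
  sum(A * (Lm %*% A))
}
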