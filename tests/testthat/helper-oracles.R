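# Independent scalar-loop oracles and random-instance builders used across
# the suite. Every oracle is written as plain double loops / textbook
# formulas so it shares no code path with the package implementation.

# scalar evaluation of all four objective terms, elementwise loops only
oracleObjective <- function(U, V, Xct, Xcv, Y, Lct, Lcv, hp) {
  n <- ncol(Xct); cc <- ncol(Y)
  Act <- t(Xct) %*% U
  Acv <- t(Xcv) %*% V
  label <- 0; cross <- 0
  for (i in seq_len(n)) for (j in seq_len(cc)) {
    label <- label + (Y[i, j] - Act[i, j])^2 + (Y[i, j] - Acv[i, j])^2
    cross <- cross + (Act[i, j] - Acv[i, j])^2
  }
  Lct <- if (is(Lct, "GraphLaplacian")) Lct@L else Lct
  Lcv <- if (is(Lcv, "GraphLaplacian")) Lcv@L else Lcv
  Wct <- -Lct; diag(Wct) <- 0
  Wcv <- -Lcv; diag(Wcv) <- 0
  graph <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    graph <- graph + 0.5 * Wct[i, j] * sum((Act[i, ] - Act[j, ])^2) +
      0.5 * Wcv[i, j] * sum((Acv[i, ] - Acv[j, ])^2)
  }
  ridge <- sum(U * U) + sum(V * V)
  as.numeric(hp$lambda * label + (1 - hp$lambda) * cross +
               hp$alpha * graph + hp$beta * ridge)
}

# Laplacian quadratic form as the pairwise double sum (1/2) sum w_ij ||a_i - a_j||^2
oracleQuadForm <- function(P, X, W) {
  A <- t(X) %*% P
  n <- nrow(A)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + 0.5 * W[i, j] * sum((A[i, ] - A[j, ])^2)
  s
}

# ridge solution of min ||Y - X^T U||^2 + beta ||U||^2 via QR on the
# augmented least-squares system (independent of the package's Cholesky)
oracleRidge <- function(X, Y, beta) {
  d <- nrow(X)
  A <- rbind(t(X), sqrt(beta) * diag(d))
  B <- rbind(Y, matrix(0, d, ncol(Y)))
  qr.solve(A, B)
}

# central-difference gradient of the objective with respect to one block
numGradient <- function(f, M, step = 1e-6) {
  G <- M
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    Mp <- M; Mp[i, j] <- M[i, j] + step
    Mm <- M; Mm[i, j] <- M[i, j] - step
    G[i, j] <- (f(Mp) - f(Mm)) / (2 * step)
  }
  G
}

# exhaustive pairwise AUC: wins + half-ties over all positive-negative pairs
oracleAUC <- function(yTrue, scores, positive) {
  pos <- which(yTrue == positive)
  neg <- which(yTrue != positive)
  s <- 0
  for (i in pos) for (j in neg)
    s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  s / (length(pos) * length(neg))
}

# a random small problem instance: two views, one-hot labels, two Laplacians
randomInstance <- function(d = 6, n = 10, cc = 2, seed = 1) {
  set.seed(seed)
  Xct <- matrix(rnorm(d * n), d, n)
  Xcv <- matrix(rnorm(d * n), d, n)
  cls <- sample(letters[seq_len(cc)], n, replace = TRUE)
  cls[seq_len(cc)] <- letters[seq_len(cc)]      # every class represented
  Y <- encodeLabels(cls, letters[seq_len(cc)])
  k <- max(1L, min(3L, n - 1L))
  Lct <- buildLaplacian(buildAffinity(Xct, k))
  Lcv <- buildLaplacian(buildAffinity(Xcv, k))
  hp <- hyperParams(lambda = runif(1, 0.1, 0.9), alpha = 10^runif(1, -2, 0),
                    beta = 10^runif(1, -1, 1), kCT = k, kCV = k,
                    eta = runif(1))
  list(Xct = Xct, Xcv = Xcv, Y = Y, Lct = Lct, Lcv = Lcv, hp = hp,
       d = d, n = n, cc = cc)
}

# symmetric random affinity matrix (not necessarily kNN-structured)
randomW <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# split a four-group cohort into its auxiliary (AD/NC) and target
# (pMCI/sMCI) halves
splitCohort <- function(cohort) {
  g <- groupLabels(cohort)
  list(aux = cohort[, g %in% c("AD", "NC")],
       target = cohort[, g %in% c("pMCI", "sMCI")])
}
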