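#' Hyperparameters of the joint projection objective
#'
#' The objective balances four terms: label regression (weight `lambda`),
#' cross-view consistency (weight `1 - lambda`), graph smoothness per view
#' (weight `alpha`) and a ridge penalty on the projections (weight `beta`).
#' `kCT`/`kCV` are the kNN graph neighbour counts per view, `eta` the fusion
#' weight of the thickness view in the final biomarker, and
#' `sigmaCT`/`sigmaCV` optional fixed heat-kernel bandwidths (`NULL` =
#' median heuristic). Defaults are the selected operating point of the
#' method: `lambda = 0.1`, `alpha = 0.1`, `beta = 10`, `kCT = 11`,
#' `kCV = 3`, `eta = 0.03`.
#'
#' @param lambda label-regression weight in `(0, 1]`; `1` switches the
#'   cross-view term off.
#' @param alpha graph-regularization weight, `>= 0`.
#' @param beta ridge weight, `> 0` (guarantees the update systems are
#'   positive definite).
#' @param kCT,kCV neighbour counts for the thickness/volume graphs.
#' @param eta fusion weight in `[0, 1]`.
#' @param sigmaCT,sigmaCV fixed bandwidths or `NULL`.
#' @param standardize how to rescale features with training-set statistics
#'   before fitting: `"scale"` (default) divides each feature by its
#'   training sd — thickness is in mm and volume in mm^3, so the raw scales
#'   differ by orders of magnitude — while keeping the positive means the
#'   no-intercept label regression needs; `"zscore"` additionally centers
#'   (note: centering makes the two label-subspace axes exact negatives of
#'   each other for binary one-hot labels, which collapses the squared
#'   fusion — use for diagnostics only); `"none"` fits raw features.
#'   `TRUE`/`FALSE` are accepted as `"scale"`/`"none"`.
#' @return a validated named list.
#' @export
hyperParams <- function(lambda = 0.1, alpha = 0.1, beta = 10,
                        kCT = 11L, kCV = 3L, eta = 0.03,
                        sigmaCT = NULL, sigmaCV = NULL,
                        standardize = "scale") {
  if (is.logical(standardize))
    standardize <- if (isTRUE(standardize)) "scale" else "none"
  standardize <- match.arg(standardize, c("scale", "zscore", "none"))
  if (!(lambda > 0 && lambda <= 1))
    stop("lambda must be in (0, 1]", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (!(beta > 0)) stop("beta must be > 0", call. = FALSE)
  if (kCT < 1L || kCV < 1L) stop("neighbour counts must be >= 1", call. = FALSE)
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]", call. = FALSE)
  for (s in list(sigmaCT, sigmaCV))
    if (!is.null(s) && !(s > 0)) stop("fixed sigma must be > 0", call. = FALSE)
  list(lambda = lambda, alpha = alpha, beta = beta,
       kCT = as.integer(kCT), kCV = as.integer(kCV), eta = eta,
       sigmaCT = sigmaCT, sigmaCV = sigmaCV,
       standardize = standardize)
}

#' One-hot encode class labels
#'
#' @param classes length-n vector of class codes.
#' @param classOrder ordered class labels defining the columns of Y.
#' @return n x c 0/1 indicator matrix with one 1 per row, columns named by
#'   `classOrder`. A class with zero members is accepted with a warning
#'   (the optimization stays well-posed), an unknown code is an error.
#' @export
encodeLabels <- function(classes, classOrder) {
  if (length(classes) < 1L) stop("no class codes supplied", call. = FALSE)
  classes <- as.character(classes)
  classOrder <- as.character(classOrder)
  bad <- setdiff(unique(classes), classOrder)
  if (length(bad))
    stop("unknown class code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  missing <- setdiff(classOrder, unique(classes))
  if (length(missing))
    warning("class(es) with zero members: ", paste(missing, collapse = ", "))
  Y <- matrix(0, length(classes), length(classOrder),
              dimnames = list(NULL, classOrder))
  Y[cbind(seq_along(classes), match(classes, classOrder))] <- 1
  Y
}

.lap <- function(L) if (is(L, "GraphLaplacian")) L@L else as.matrix(L)

#' Joint projection objective
#'
#' Evaluates
#' \deqn{Q = \lambda(\|Y - X_{CT}^T U\|_F^2 + \|Y - X_{CV}^T V\|_F^2)
#'   + (1-\lambda)\|X_{CT}^T U - X_{CV}^T V\|_F^2
#'   + \alpha(\mathrm{tr}(U^T X_{CT} L_{CT} X_{CT}^T U)
#'          + \mathrm{tr}(V^T X_{CV} L_{CV} X_{CV}^T V))
#'   + \beta(\|U\|_F^2 + \|V\|_F^2).}
#'
#' @param U,V d x c projection matrices.
#' @param Xct,Xcv d x n view matrices (subject columns aligned).
#' @param Y n x c one-hot label matrix.
#' @param Lct,Lcv per-view [GraphLaplacian-class] objects (or matrices).
#' @param hp hyperparameter list from [hyperParams()].
#' @return the scalar objective value (nonnegative).
#' @export
objectiveQ <- function(U, V, Xct, Xcv, Y, Lct, Lcv, hp) {
  U <- as.matrix(U); V <- as.matrix(V)
  Xct <- as.matrix(Xct); Xcv <- as.matrix(Xcv); Y <- as.matrix(Y)
  n <- ncol(Xct); d <- nrow(Xct)
  if (ncol(Xcv) != n || nrow(Xcv) != d)
    stop("view matrices must share dimensions d x n", call. = FALSE)
  if (nrow(Y) != n) stop("Y must have n rows", call. = FALSE)
  if (nrow(U) != d || nrow(V) != d || ncol(U) != ncol(Y) || ncol(V) != ncol(Y))
    stop("projections must be d x c", call. = FALSE)
  Act <- crossprod(Xct, U)           # n x c
  Acv <- crossprod(Xcv, V)
  hp$lambda * (sum((Y - Act)^2) + sum((Y - Acv)^2)) +
    (1 - hp$lambda) * sum((Act - Acv)^2) +
    hp$alpha * (smoothness(U, Xct, Lct) + smoothness(V, Xcv, Lcv)) +
    hp$beta * (sum(U^2) + sum(V^2))
}

# solve the SPD system G Z = B via Cholesky (no explicit inversion)
.spdSolve <- function(G, B) {
  G <- (G + t(G)) / 2
  R <- chol(G)
  backsolve(R, backsolve(R, B, transpose = TRUE))
}

#' Closed-form block updates of the projections
#'
#' `updateU` minimizes the joint objective over U with V fixed:
#' \deqn{U = (X_{CT} X_{CT}^T + \alpha X_{CT} L_{CT} X_{CT}^T + \beta I)^{-1}
#'   (\lambda X_{CT} Y + (1-\lambda) X_{CT} X_{CV}^T V),}
#' solved as a symmetric positive-definite linear system; the block gradient
#' of Q vanishes at the result. `updateV` is the mirror update with the
#' views and Laplacians swapped.
#'
#' @inheritParams objectiveQ
#' @param L the Laplacian of the view being updated.
#' @return the d x c minimizing projection block.
#' @export
updateU <- function(V, Xct, Xcv, Y, L, hp) {
  Xct <- as.matrix(Xct); Xcv <- as.matrix(Xcv)
  V <- as.matrix(V); Y <- as.matrix(Y)
  stopIfNotFinite(Xct, "Xct"); stopIfNotFinite(Xcv, "Xcv")
  stopIfNotFinite(V, "V"); stopIfNotFinite(Y, "Y")
  Lm <- .lap(L)
  d <- nrow(Xct)
  G <- tcrossprod(Xct) + hp$alpha * (Xct %*% Lm %*% t(Xct)) +
    hp$beta * diag(d)
  B <- hp$lambda * (Xct %*% Y) +
    (1 - hp$lambda) * (Xct %*% crossprod(Xcv, V))
  .spdSolve(G, B)
}

#' @rdname updateU
#' @param U the fixed thickness-view projection when updating V.
#' @export
updateV <- function(U, Xct, Xcv, Y, L, hp) {
  updateU(U, Xcv, Xct, Y, L, hp)
}

#' Alternating minimization of the joint objective
#'
#' Starts from `U = V = 0` and alternates the exact block updates
#' ([updateU()] then [updateV()]) until the relative change of the objective
#' falls below `tol` or `maxIter` is reached. Each update is an exact block
#' minimizer, so the recorded objective trace is nonincreasing; an increase
#' beyond numerical tolerance raises an error.
#'
#' @inheritParams objectiveQ
#' @param tol relative-change stopping tolerance
#'   (`|Q_t - Q_{t-1}| / max(1, Q_{t-1}) < tol`).
#' @param maxIter maximum number of alternating iterations.
#' @return list with elements `U`, `V`, `trace` (objective after each
#'   iteration), `nIter`, `converged`.
#' @export
fitProjections <- function(Xct, Xcv, Y, Lct, Lcv, hp,
                           tol = 1e-8, maxIter = 200L) {
  if (!(tol > 0)) stop("tol must be > 0", call. = FALSE)
  maxIter <- as.integer(maxIter)
  if (maxIter < 1L) stop("maxIter must be >= 1", call. = FALSE)
  Xct <- as.matrix(Xct); Xcv <- as.matrix(Xcv); Y <- as.matrix(Y)
  d <- nrow(Xct); cc <- ncol(Y)
  U <- matrix(0, d, cc)
  V <- matrix(0, d, cc)
  qPrev <- objectiveQ(U, V, Xct, Xcv, Y, Lct, Lcv, hp)
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    U <- updateU(V, Xct, Xcv, Y, Lct, hp)
    V <- updateV(U, Xct, Xcv, Y, Lcv, hp)
    q <- objectiveQ(U, V, Xct, Xcv, Y, Lct, Lcv, hp)
    if (q > qPrev + 1e-9 * max(1, qPrev))
      stop("objective increased during alternating minimization; ",
           "solver contract violated", call. = FALSE)
    trace <- c(trace, q)
    if (abs(q - qPrev) / max(1, qPrev) < tol) {
      converged <- TRUE
      qPrev <- q
      break
    }
    qPrev <- q
  }
  list(U = U, V = V, trace = trace, nIter = it, converged = converged)
}

.standardizeStats <- function(X, mode) {
  ctr <- if (mode == "zscore") rowMeans(X) else rep(0, nrow(X))
  scl <- if (mode == "none") rep(1, nrow(X)) else apply(X, 1, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

.applyStandardize <- function(X, ctr, scl) (X - ctr) / scl

#' Learn the two-view projection model from labeled auxiliary data
#'
#' End-to-end fit on a labeled cohort (typically AD/NC auxiliary subjects):
#' optional per-feature z-scoring, per-view kNN heat-kernel graph and
#' Laplacian construction, and alternating closed-form minimization of the
#' joint objective. The returned [ProjectionModel-class] carries everything
#' needed to map new subjects into the label subspace with the training
#' transform.
#'
#' @param x a [MultiViewCohort-class] with group labels.
#' @param hp hyperparameters from [hyperParams()].
#' @param classOrder class labels defining the label-subspace axes;
#'   defaults to the sorted distinct labels of `x`.
#' @param tol,maxIter stopping rule of the alternating solver.
#' @param ... unused.
#' @return a [ProjectionModel-class].
#' @examples
#' aux <- generateCohort(cohortSpec(
#'   nPerGroup = c(AD = 40, NC = 40, pMCI = 0, sMCI = 0),
#'   d = 12, delta = 2, seed = 3))
#' model <- learnProjections(aux, hyperParams(kCT = 5, kCV = 5))
#' model
#' @rdname learnProjections
#' @export
setMethod("learnProjections", "MultiViewCohort",
  function(x, hp = hyperParams(), classOrder = NULL,
           tol = 1e-8, maxIter = 200L, ...) {
    labels <- groupLabels(x)
    if (length(labels) < 2L)
      stop("need at least 2 subjects to learn projections", call. = FALSE)
    classOrder <- classOrder %||% sort(unique(labels))
    Xct <- thicknessView(x)
    Xcv <- volumeView(x)
    sct <- .standardizeStats(Xct, hp$standardize)
    scv <- .standardizeStats(Xcv, hp$standardize)
    Xct <- .applyStandardize(Xct, sct$center, sct$scale)
    Xcv <- .applyStandardize(Xcv, scv$center, scv$scale)
    Y <- encodeLabels(labels, classOrder)
    gct <- buildAffinity(Xct, hp$kCT, hp$sigmaCT, viewTag = "CT")
    gcv <- buildAffinity(Xcv, hp$kCV, hp$sigmaCV, viewTag = "CV")
    fit <- fitProjections(Xct, Xcv, Y, buildLaplacian(gct),
                          buildLaplacian(gcv), hp,
                          tol = tol, maxIter = maxIter)
    new("ProjectionModel",
        U = fit$U, V = fit$V, classOrder = classOrder, hp = hp,
        centerCT = unname(sct$center), scaleCT = unname(sct$scale),
        centerCV = unname(scv$center), scaleCV = unname(scv$scale),
        sigmaCT = gct@sigma, sigmaCV = gcv@sigma,
        trace = fit$trace, nIter = fit$nIter, converged = fit$converged,
        standardize = hp$standardize)
  })

#' Accessors for ProjectionModel
#'
#' @param x a [ProjectionModel-class].
#' @name ProjectionModel-accessors
NULL

#' @rdname ProjectionModel-accessors
setMethod("projectionU", "ProjectionModel", function(x) x@U)

#' @rdname ProjectionModel-accessors
setMethod("projectionV", "ProjectionModel", function(x) x@V)

#' @rdname ProjectionModel-accessors
setMethod("fitTrace", "ProjectionModel", function(x) x@trace)

#' @rdname ProjectionModel-accessors
setMethod("classOrder", "ProjectionModel", function(x) x@classOrder)

#' Serialize / restore a projection model as JSON
#'
#' Matrices are stored as nested row-major lists; the document carries the
#' projections, class order, standardization statistics, bandwidths and
#' hyperparameters, so a restored model reproduces [extractBiomarkers()]
#' output exactly.
#'
#' @param model a [ProjectionModel-class].
#' @param path file path of the JSON document.
#' @return `writeProjectionModel` returns `path` invisibly;
#'   `readProjectionModel` returns the restored [ProjectionModel-class].
#' @export
writeProjectionModel <- function(model, path) {
  stopifnot(is(model, "ProjectionModel"))
  hp <- model@hp
  hp$sigmaCT <- hp$sigmaCT %||% NA
  hp$sigmaCV <- hp$sigmaCV %||% NA
  doc <- list(
    U = model@U, V = model@V,
    classOrder = model@classOrder,
    hp = hp,
    centerCT = model@centerCT, scaleCT = model@scaleCT,
    centerCV = model@centerCV, scaleCV = model@scaleCV,
    sigmaCT = model@sigmaCT, sigmaCV = model@sigmaCV,
    trace = model@trace, nIter = model@nIter,
    converged = model@converged, standardize = model@standardize)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeProjectionModel
#' @export
readProjectionModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  hp <- doc$hp
  hp$kCT <- as.integer(hp$kCT); hp$kCV <- as.integer(hp$kCV)
  if (is.na(hp$sigmaCT %||% NA)) hp$sigmaCT <- NULL
  if (is.na(hp$sigmaCV %||% NA)) hp$sigmaCV <- NULL
  hp$standardize <- as.character(hp$standardize)
  new("ProjectionModel",
      U = as.matrix(doc$U), V = as.matrix(doc$V),
      classOrder = as.character(doc$classOrder), hp = hp,
      centerCT = as.numeric(doc$centerCT), scaleCT = as.numeric(doc$scaleCT),
      centerCV = as.numeric(doc$centerCV), scaleCV = as.numeric(doc$scaleCV),
      sigmaCT = as.numeric(doc$sigmaCT), sigmaCV = as.numeric(doc$sigmaCV),
      trace = as.numeric(doc$trace), nIter = as.integer(doc$nIter),
      converged = isTRUE(doc$converged),
      standardize = as.character(doc$standardize))
}
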