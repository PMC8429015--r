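#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats dist median rnorm sd t.test predict
#' @importFrom utils read.csv write.csv
NULL

GROUPS <- c("AD", "NC", "pMCI", "sMCI")

#' Specification of a synthetic two-view cohort
#'
#' Describes the statistical structure of a simulated four-group
#' (AD / NC / pMCI / sMCI) cohort observed through two correlated
#' morphological views (thickness-like and volume-like). See
#' [cohortSpec()] for the constructor and the meaning of each slot.
#'
#' @slot nPerGroup named integer vector of group sizes (AD, NC, pMCI, sMCI).
#' @slot d number of region features per view.
#' @slot delta between-class mean separation, in units of within-class sd.
#' @slot rho fraction of a subject's latent signal variance shared between
#'   the two views, in `[0, 1]`.
#' @slot noiseSd standard deviation of per-feature measurement noise (> 0).
#' @slot nInformative number of leading features carrying class signal.
#' @slot mix how far the pMCI mean sits from the AD mean toward NC (and
#'   sMCI from NC toward AD), in `[0, 0.5]`.
#' @slot seed integer RNG seed; generation is deterministic given the spec.
#' @export
setClass("CohortSpec",
  representation(
    nPerGroup = "integer",
    d = "integer",
    delta = "numeric",
    rho = "numeric",
    noiseSd = "numeric",
    nInformative = "integer",
    mix = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!identical(names(object@nPerGroup), GROUPS))
    msg <- c(msg, "nPerGroup must be named AD, NC, pMCI, sMCI (in order)")
  if (any(object@nPerGroup < 0L)) msg <- c(msg, "nPerGroup: counts must be >= 0")
  if (object@d < 1L) msg <- c(msg, "d: must be >= 1")
  if (!(object@noiseSd > 0)) msg <- c(msg, "noiseSd: must be > 0")
  if (object@rho < 0 || object@rho > 1) msg <- c(msg, "rho: must be in [0, 1]")
  if (object@mix < 0 || object@mix > 0.5) msg <- c(msg, "mix: must be in [0, 0.5]")
  if (object@delta < 0) msg <- c(msg, "delta: must be >= 0")
  if (object@nInformative < 1L || object@nInformative > object@d)
    msg <- c(msg, "nInformative: must satisfy 1 <= nInformative <= d")
  if (length(msg)) msg else TRUE
})

#' Two-view cohort container
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the two aligned
#' feature views as assays `"thickness"` and `"volume"` (features in rows,
#' subjects in columns) and a `group` column in `colData`. Synthetic cohorts
#' additionally carry their generating [CohortSpec-class] in `metadata`.
#'
#' @seealso [generateCohort()], [alignViews()], [thicknessView()],
#'   [volumeView()], [groupLabels()]
#' @export
setClass("MultiViewCohort", contains = "SummarizedExperiment")

setValidity("MultiViewCohort", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("thickness", "volume") %in% an))
    msg <- c(msg, "assays must include 'thickness' and 'volume'")
  if (!("group" %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain a 'group' column")
  else if (anyNA(SummarizedExperiment::colData(object)$group))
    msg <- c(msg, "group labels must not be missing")
  if (length(msg)) msg else TRUE
})

#' kNN heat-kernel affinity graph over subjects
#'
#' Symmetric nonnegative affinity matrix built by [buildAffinity()]:
#' \eqn{w_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2))} when one of the two
#' subjects is among the other's k nearest neighbours, 0 otherwise.
#'
#' @slot W symmetric n x n weight matrix with zero diagonal, entries in [0,1].
#' @slot k neighbour count used.
#' @slot sigma heat-kernel bandwidth actually used (> 0).
#' @slot viewTag label recording which view the graph was built from.
#' @export
setClass("AffinityGraph",
  representation(W = "matrix", k = "integer", sigma = "numeric",
                 viewTag = "character")
)

setValidity("AffinityGraph", function(object) {
  W <- object@W
  msg <- character()
  if (nrow(W) != ncol(W)) msg <- c(msg, "W must be square")
  else {
    if (max(abs(W - t(W))) > 1e-10) msg <- c(msg, "W must be symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "W must have zero diagonal")
    if (any(W < 0) || any(W > 1)) msg <- c(msg, "weights must lie in [0, 1]")
  }
  if (!(object@sigma > 0)) msg <- c(msg, "sigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Graph Laplacian L = D - W
#'
#' @slot L the n x n Laplacian matrix.
#' @slot degree diagonal of the degree matrix, `degree[i] = sum_j w_ij`.
#' @seealso [buildLaplacian()], [smoothness()]
#' @export
setClass("GraphLaplacian",
  representation(L = "matrix", degree = "numeric")
)

setValidity("GraphLaplacian", function(object) {
  L <- object@L
  msg <- character()
  if (nrow(L) != ncol(L)) msg <- c(msg, "L must be square")
  else {
    if (max(abs(L - t(L))) > 1e-8) msg <- c(msg, "L must be symmetric")
    if (max(abs(rowSums(L))) > 1e-8 * max(1, max(abs(L))))
      msg <- c(msg, "rows of L must sum to 0")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted two-view projection model
#'
#' Result of [learnProjections()]: the projections U (thickness view) and V
#' (volume view) mapping d standardized region features into the
#' c-dimensional class-label subspace, together with the standardization
#' statistics, graph bandwidths, hyperparameters and the optimization trace.
#'
#' @slot U,V d x c projection matrices.
#' @slot classOrder class labels defining the label-subspace axes.
#' @slot hp hyperparameter list as produced by [hyperParams()].
#' @slot centerCT,scaleCT,centerCV,scaleCV per-feature standardization
#'   statistics of the training (auxiliary) set.
#' @slot sigmaCT,sigmaCV heat-kernel bandwidths actually used per view.
#' @slot trace objective value after each alternating iteration
#'   (nonincreasing).
#' @slot nIter number of iterations run.
#' @slot converged whether the relative-change stopping rule fired.
#' @slot standardize feature rescaling mode used (`"scale"`, `"zscore"` or
#'   `"none"`).
#' @export
setClass("ProjectionModel",
  representation(
    U = "matrix", V = "matrix",
    classOrder = "character",
    hp = "list",
    centerCT = "numeric", scaleCT = "numeric",
    centerCV = "numeric", scaleCV = "numeric",
    sigmaCT = "numeric", sigmaCV = "numeric",
    trace = "numeric", nIter = "integer", converged = "logical",
    standardize = "character"
  )
)

#' Result of a repeated cross-validation protocol run
#'
#' @slot perRepeat data.frame with one row per repeat: acc, sen, spe, auc.
#' @slot means named numeric vector of metric means over repeats.
#' @slot protocol `"auxiliary"` or `"self"`.
#' @slot positiveClass label treated as positive (sensitivity numerator).
#' @slot config the cross-validation configuration used (list).
#' @slot foldRecords data.frame of pooled out-of-fold predictions:
#'   repeat index, fold, subject id, true label, predicted label, score.
#' @seealso [runProtocol()]
#' @export
setClass("ProtocolResult",
  representation(
    perRepeat = "data.frame",
    means = "numeric",
    protocol = "character",
    positiveClass = "character",
    config = "list",
    foldRecords = "data.frame"
  )
)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", sum(object@nPerGroup), "subjects (",
      paste(sprintf("%s=%d", names(object@nPerGroup), object@nPerGroup),
            collapse = ", "),
      ")\n  d =", object@d,
      " delta =", object@delta,
      " rho =", object@rho,
      " noiseSd =", object@noiseSd,
      "\n  nInformative =", object@nInformative,
      " mix =", object@mix,
      " seed =", object@seed, "\n")
})

setMethod("show", "AffinityGraph", function(object) {
  n <- nrow(object@W)
  nz <- sum(object@W > 0)
  cat(sprintf("AffinityGraph (%s view): %d subjects, k = %d, sigma = %.4g, %d nonzero edges\n",
              object@viewTag, n, object@k, object@sigma, nz / 2))
})

setMethod("show", "ProjectionModel", function(object) {
  cat(sprintf("ProjectionModel: d = %d features -> c = %d label dimensions (%s)\n",
              nrow(object@U), ncol(object@U),
              paste(object@classOrder, collapse = " vs ")))
  cat(sprintf("  %d iterations, converged: %s, final objective %.6g\n",
              object@nIter, object@converged,
              object@trace[length(object@trace)]))
  cat(sprintf("  lambda = %g, alpha = %g, beta = %g, k = (%d, %d), eta = %g\n",
              object@hp$lambda, object@hp$alpha, object@hp$beta,
              object@hp$kCT, object@hp$kCV, object@hp$eta))
})

setMethod("show", "ProtocolResult", function(object) {
  cat(sprintf("ProtocolResult (protocol = %s, positive class = %s)\n",
              object@protocol, object@positiveClass))
  cat(sprintf("  %d repeats of %d-fold CV, classifier = %s\n",
              nrow(object@perRepeat), object@config$nFolds,
              object@config$classifier))
  m <- object@means
  cat(sprintf("  mean ACC = %.4f  SEN = %.4f  SPE = %.4f  AUC = %.4f\n",
              m["acc"], m["sen"], m["spe"], m["auc"]))
})
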