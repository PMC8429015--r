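#' Define a synthetic two-view cohort
#'
#' Constructs a [CohortSpec-class] describing a simulated cohort of the four
#' diagnostic groups (AD, NC, pMCI, sMCI) observed through two correlated
#' morphological views. The defaults mirror the study conditions of a
#' typical structural-MRI conversion cohort: the four group sizes of the
#' reference ADNI sample (142 AD, 165 NC, 126 pMCI, 95 sMCI) and 78 cortical
#' regions per view.
#'
#' Each subject draws a latent signal vector with class-dependent mean; the
#' two views observe `sqrt(rho)` of a shared latent draw plus
#' `sqrt(1 - rho)` of a view-private draw (so within-class variance is 1
#' before noise and `rho` is the fraction of signal variance shared between
#' views), plus independent Gaussian noise. Only the first `nInformative`
#' coordinates carry class-mean differences: AD at `+delta/2`, NC at
#' `-delta/2`, and the MCI groups interpolated, pMCI at
#' `(1 - mix) * AD + mix * NC` and sMCI symmetrically — encoding that
#' progressive MCI resembles AD and stable MCI resembles NC. Every feature
#' additionally carries a fixed positive per-region baseline
#' ([viewBaselines()]) giving the two views the positive means and
#' differing scales of real thickness/volume measurements; baselines are
#' identical across classes, so class-mean differences live only on the
#' informative coordinates.
#'
#' @param nPerGroup named integer vector of group sizes; names must be
#'   AD, NC, pMCI, sMCI.
#' @param d number of region features per view.
#' @param delta between-class mean separation (within-class sd units).
#' @param rho shared-variance fraction between views, in `[0, 1]`.
#' @param noiseSd per-feature noise standard deviation (> 0).
#' @param nInformative number of leading features carrying class signal;
#'   default `NULL` means `ceiling(d / 4)` (20 regions at the default
#'   d = 78, reflecting that atrophy concentrates in a subset of regions).
#' @param mix pMCI/sMCI interpolation toward the opposite pole, in
#'   `[0, 0.5]`.
#' @param seed integer RNG seed.
#' @return a validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(nPerGroup = c(AD = 30, NC = 30, pMCI = 20, sMCI = 20),
#'                    d = 10, delta = 2, seed = 7)
#' cohort <- generateCohort(spec)
#' table(groupLabels(cohort))
#' @export
cohortSpec <- function(nPerGroup = c(AD = 142L, NC = 165L, pMCI = 126L, sMCI = 95L),
                       d = 78L, delta = 1, rho = 0.5, noiseSd = 1,
                       nInformative = NULL, mix = 0.25, seed = 1L) {
  if (is.null(names(nPerGroup)))
    stop("nPerGroup: must be a named vector (AD, NC, pMCI, sMCI)", call. = FALSE)
  if (!setequal(names(nPerGroup), GROUPS))
    stop("nPerGroup: names must be exactly ", paste(GROUPS, collapse = ", "),
         call. = FALSE)
  counts <- as.integer(nPerGroup[GROUPS])
  names(counts) <- GROUPS
  nInformative <- nInformative %||% ceiling(as.integer(d) / 4)
  spec <- new("CohortSpec",
    nPerGroup = counts,
    d = as.integer(d), delta = as.numeric(delta), rho = as.numeric(rho),
    noiseSd = as.numeric(noiseSd),
    nInformative = as.integer(nInformative),
    mix = as.numeric(mix), seed = as.integer(seed))
  validObject(spec)
  spec
}

#' Per-region view baselines of the synthetic generator
#'
#' Fixed positive baselines added to every class mean, emulating the
#' magnitudes of real morphological views: thickness-like values around
#' 2-3.5 (mm scale) and volume-like values around 8-20 (a rescaled volume
#' axis, roughly 5x the thickness scale). Class-mean *differences* are
#' unaffected; the baselines give the views the positive, affine structure
#' that raw cortical measurements have.
#'
#' @param spec a [CohortSpec-class].
#' @return list with numeric vectors `ct` and `cv` of length `d`.
#' @export
viewBaselines <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  list(ct = seq(2, 3.5, length.out = spec@d),
       cv = seq(8, 20, length.out = spec@d))
}

#' Group mean deviations implied by a cohort spec
#'
#' Class-mean offsets relative to the per-region baselines of
#' [viewBaselines()]; only the first `nInformative` coordinates are
#' nonzero. The expected value of view feature j in class g is
#' `baseline[j] + groupMeans(spec)[j, g]`.
#'
#' @param spec a [CohortSpec-class].
#' @return d x 4 matrix of class mean deviations (columns AD, NC, pMCI,
#'   sMCI).
#' @export
groupMeans <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  mu <- matrix(0, spec@d, 4L, dimnames = list(NULL, GROUPS))
  inf <- seq_len(spec@nInformative)
  mu[inf, "AD"] <- +spec@delta / 2
  mu[inf, "NC"] <- -spec@delta / 2
  mu[, "pMCI"] <- (1 - spec@mix) * mu[, "AD"] + spec@mix * mu[, "NC"]
  mu[, "sMCI"] <- (1 - spec@mix) * mu[, "NC"] + spec@mix * mu[, "AD"]
  mu
}

#' Generate a synthetic two-view cohort
#'
#' Draws a [MultiViewCohort-class] from the model described in
#' [cohortSpec()]. Generation is deterministic given the spec (including
#' its seed) and never touches the caller's RNG state.
#'
#' @param spec a valid [CohortSpec-class].
#' @return a [MultiViewCohort-class] with assays `thickness` and `volume`
#'   (regions x subjects), `group` labels in `colData`, and the generating
#'   spec in `metadata(x)$spec`.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  n <- spec@nPerGroup
  N <- sum(n)
  d <- spec@d
  labels <- rep(GROUPS, times = n)
  mu <- groupMeans(spec)
  M <- mu[, labels, drop = FALSE]

  draws <- withSeed(spec@seed, {
    list(shared = matrix(rnorm(d * N), d, N),
         privCT = matrix(rnorm(d * N), d, N),
         privCV = matrix(rnorm(d * N), d, N),
         noiseCT = matrix(rnorm(d * N, sd = spec@noiseSd), d, N),
         noiseCV = matrix(rnorm(d * N, sd = spec@noiseSd), d, N))
  })
  a <- sqrt(spec@rho)
  b <- sqrt(1 - spec@rho)
  bl <- viewBaselines(spec)
  xct <- bl$ct + M + a * draws$shared + b * draws$privCT + draws$noiseCT
  xcv <- bl$cv + M + a * draws$shared + b * draws$privCV + draws$noiseCV

  ids <- if (N > 0) {
    unlist(lapply(GROUPS, function(g) {
      if (n[g] == 0L) character(0)
      else sprintf("%s_%03d", g, seq_len(n[g]))
    }), use.names = FALSE)
  } else character(0)
  regions <- sprintf("region_%03d", seq_len(d))
  dimnames(xct) <- dimnames(xcv) <- list(regions, ids)

  MultiViewCohort(xct, xcv, labels, spec = spec, subjectIds = ids)
}

#' Assemble a two-view cohort from matrices
#'
#' @param thickness,volume aligned d x n feature matrices (regions x
#'   subjects), identical dimensions and subject order.
#' @param group length-n vector of class labels.
#' @param spec optional generating [CohortSpec-class], stored in metadata.
#' @param subjectIds optional subject identifiers (defaults to existing
#'   column names, or S1..Sn).
#' @return a [MultiViewCohort-class].
#' @export
MultiViewCohort <- function(thickness, volume, group, spec = NULL,
                            subjectIds = NULL) {
  thickness <- as.matrix(thickness)
  volume <- as.matrix(volume)
  if (!identical(dim(thickness), dim(volume)))
    stop("views must have identical dimensions", call. = FALSE)
  n <- ncol(thickness)
  if (length(group) != n)
    stop("group labels must match the number of subjects", call. = FALSE)
  ids <- subjectIds %||% colnames(thickness) %||%
    (if (n > 0) sprintf("S%03d", seq_len(n)) else character(0))
  colnames(thickness) <- colnames(volume) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(thickness = thickness, volume = volume),
    colData = S4Vectors::DataFrame(group = as.character(group), row.names = ids))
  if (!is.null(spec)) S4Vectors::metadata(se)$spec <- spec
  obj <- new("MultiViewCohort", se)
  validObject(obj)
  obj
}

#' Accessors for MultiViewCohort
#'
#' `thicknessView`/`volumeView` return the d x n assay matrices,
#' `groupLabels` the per-subject class labels, and `generatingSpec` the
#' [CohortSpec-class] (or `NULL`) a synthetic cohort was drawn from.
#'
#' @param x a [MultiViewCohort-class].
#' @name thicknessView
#' @aliases volumeView groupLabels generatingSpec
NULL

#' @rdname thicknessView
setMethod("thicknessView", "MultiViewCohort", function(x)
  SummarizedExperiment::assay(x, "thickness"))

#' @rdname thicknessView
setMethod("volumeView", "MultiViewCohort", function(x)
  SummarizedExperiment::assay(x, "volume"))

#' @rdname thicknessView
setMethod("groupLabels", "MultiViewCohort", function(x)
  as.character(SummarizedExperiment::colData(x)$group))

#' @rdname thicknessView
setMethod("generatingSpec", "MultiViewCohort", function(x)
  S4Vectors::metadata(x)$spec)
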