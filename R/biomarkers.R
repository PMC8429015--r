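#' Project target subjects into the label subspace
#'
#' Maps a d x m block of target-subject features through a learned d x c
#' projection: returns \eqn{Z^T P}, one row of subspace coordinates per
#' subject. Standardization, when enabled, is the caller's responsibility
#' (see [extractBiomarkers()], which applies the training transform).
#'
#' @param Z d x m target feature block.
#' @param P d x c projection matrix.
#' @return m x c matrix of subspace features.
#' @export
projectView <- function(Z, P) {
  Z <- as.matrix(Z); P <- as.matrix(P)
  if (nrow(Z) != nrow(P))
    stop("Z and P must agree on the feature dimension d", call. = FALSE)
  crossprod(Z, P)
}

#' Self-weighted fusion of two projected views
#'
#' Fuses the two views' subspace features into the final biomarker:
#' \deqn{Fea = \eta\,|Fea_{CT}|\odot|Fea_{CT}|
#'   + (1-\eta)\,|Fea_{CV}|\odot|Fea_{CV}|,}
#' i.e. a convex combination of the elementwise squares. The self-weighting
#' (each feature multiplied by its own magnitude) amplifies large subspace
#' coordinates; the result is nonnegative everywhere and invariant to sign
#' flips of either view.
#'
#' @param featCT,featCV m x c projected features of the two views.
#' @param eta fusion weight of the thickness view, in `[0, 1]`.
#' @return m x c nonnegative biomarker matrix.
#' @export
fuseBiomarkers <- function(featCT, featCV, eta) {
  featCT <- as.matrix(featCT); featCV <- as.matrix(featCV)
  if (!identical(dim(featCT), dim(featCV)))
    stop("the two subspace feature blocks must have identical shape",
         call. = FALSE)
  if (length(eta) != 1L || !is.finite(eta) || eta < 0 || eta > 1)
    stop("eta must be a single value in [0, 1]", call. = FALSE)
  eta * featCT^2 + (1 - eta) * featCV^2
}

#' Extract fused subspace biomarkers for target subjects
#'
#' Applies the model's training standardization to the target views,
#' projects each view with its learned matrix ([projectView()]) and fuses
#' them ([fuseBiomarkers()]). Subjects never seen during projection
#' learning (e.g. MCI subjects under the auxiliary protocol) are mapped
#' with the auxiliary-set transform, exactly as the method prescribes.
#'
#' @param model a [ProjectionModel-class] from [learnProjections()].
#' @param x a [MultiViewCohort-class] of target subjects.
#' @param eta fusion weight; defaults to the model's `eta`.
#' @param ... unused.
#' @return m x c nonnegative biomarker matrix, rows named by subject id and
#'   columns by the model's class order.
#' @rdname extractBiomarkers
#' @export
setMethod("extractBiomarkers", signature("ProjectionModel", "MultiViewCohort"),
  function(model, x, eta = NULL, ...) {
    eta <- eta %||% model@hp$eta
    Zct <- .applyStandardize(thicknessView(x), model@centerCT, model@scaleCT)
    Zcv <- .applyStandardize(volumeView(x), model@centerCV, model@scaleCV)
    fea <- fuseBiomarkers(projectView(Zct, model@U),
                          projectView(Zcv, model@V), eta)
    dimnames(fea) <- list(colnames(x), model@classOrder)
    fea
  })

#' Write biomarkers to CSV
#'
#' One row per subject: subject id followed by the c biomarker columns.
#'
#' @param fea biomarker matrix from [extractBiomarkers()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeBiomarkers <- function(fea, path) {
  df <- data.frame(subject_id = rownames(fea) %||% seq_len(nrow(fea)),
                   as.data.frame(fea), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
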