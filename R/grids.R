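#' Default hyperparameter search grids
#'
#' The grids the method was tuned over: `lambda` in 0.1..0.9 (step 0.1),
#' `alpha` in 10^-3..10^1, `beta` in 10^-1..10^1 (log scale), neighbour
#' counts 3, 5, ..., 15 per view, and `eta` in q*10^-2 and q*10^-1 for
#' q = 1..9. Their Cartesian product has 119070 combinations.
#'
#' @return named list of numeric grids (`lambda`, `alpha`, `beta`, `kCT`,
#'   `kCV`, `eta`).
#' @export
defaultGrids <- function() {
  list(lambda = seq(0.1, 0.9, by = 0.1),
       alpha = 10^(-3:1),
       beta = 10^(-1:1),
       kCT = c(3L, 5L, 7L, 9L, 11L, 13L, 15L),
       kCV = c(3L, 5L, 7L, 9L, 11L, 13L, 15L),
       eta = c(outer(1:9, c(1e-2, 1e-1))))
}

#' Enumerate a hyperparameter grid
#'
#' @param grids named list of grids as in [defaultGrids()]; every name must
#'   be one of lambda, alpha, beta, kCT, kCV, eta, and every grid nonempty.
#' @return data.frame with one row per hyperparameter combination.
#' @export
gridCombinations <- function(grids = defaultGrids()) {
  needed <- c("lambda", "alpha", "beta", "kCT", "kCV", "eta")
  if (!all(needed %in% names(grids)))
    stop("grids must name: ", paste(needed, collapse = ", "), call. = FALSE)
  if (any(lengths(grids[needed]) == 0L))
    stop("empty grid", call. = FALSE)
  expand.grid(grids[needed], KEEP.OUT.ATTRS = FALSE)
}

#' Exhaustive hyperparameter grid search
#'
#' Runs [runProtocol()] for every combination in `grids` and returns the
#' full ranked table, sorted by mean accuracy (ties broken by mean AUC,
#' then lexicographically by the parameters). Because the top row is
#' selected on test performance, it is an optimistic selection-on-test
#' quantity; the full table is returned so that can be judged.
#'
#' A screening mode (`screeningRepeats`, default 5) evaluates each
#' combination with a reduced repeat count to keep large grids tractable;
#' rerun the best rows at the full `cfg$nRepeats` for reporting.
#'
#' @inheritParams runProtocol
#' @param grids named list of grids (see [defaultGrids()]).
#' @param screeningRepeats repeats used per combination (`NULL` = use
#'   `cfg$nRepeats`).
#' @return data.frame: one row per combination with mean acc/sen/spe/auc,
#'   sorted best-first.
#' @export
gridSearch <- function(aux, target, grids = defaultGrids(),
                       cfg = cvConfig(), protocol = "auxiliary",
                       screeningRepeats = 5L) {
  combos <- gridCombinations(grids)
  if (!is.null(screeningRepeats)) cfg$nRepeats <- as.integer(screeningRepeats)
  res <- lapply(seq_len(nrow(combos)), function(i) {
    row <- combos[i, ]
    hp <- hyperParams(lambda = row$lambda, alpha = row$alpha,
                      beta = row$beta, kCT = row$kCT, kCV = row$kCV,
                      eta = row$eta)
    metricMeans(runProtocol(aux, target, hp = hp, cfg = cfg,
                            protocol = protocol))
  })
  out <- cbind(combos, do.call(rbind, res))
  ord <- order(-out$acc, -out$auc, out$lambda, out$alpha, out$beta,
               out$kCT, out$kCV, out$eta)
  out[ord, , drop = FALSE]
}

#' Effect of auxiliary-set size on target accuracy
#'
#' For each size, draws class-balanced (1:1) auxiliary subsets without
#' replacement `nResamples` times, runs the auxiliary protocol on each, and
#' averages the mean CV accuracy over resamples. Deterministic given
#' `seed`.
#'
#' @inheritParams runProtocol
#' @param sizes total auxiliary subset sizes (must be even; half per
#'   class); default 50 to 250 by 50.
#' @param nResamples balanced resamples per size (default 10).
#' @param seed integer seed for the resampling.
#' @return data.frame with one row per size: mean, sd and standard error
#'   of accuracy over resamples.
#' @export
auxiliarySizeSweep <- function(aux, target, hp = hyperParams(),
                               cfg = cvConfig(),
                               sizes = c(50L, 100L, 150L, 200L, 250L),
                               nResamples = 10L, seed = 1L) {
  labels <- groupLabels(aux)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop("auxiliary cohort must contain exactly 2 classes", call. = FALSE)
  counts <- table(labels)
  out <- lapply(seq_along(sizes), function(si) {
    size <- as.integer(sizes[si])
    if (size %% 2L != 0L)
      stop("sizes must be even for a 1:1 class split", call. = FALSE)
    half <- size %/% 2L
    if (any(counts[classes] < half))
      stop("size ", size, " exceeds availability of a class (",
           paste(sprintf("%s=%d", classes, counts[classes]), collapse = ", "),
           ")", call. = FALSE)
    accs <- vapply(seq_len(nResamples), function(r) {
      idx <- withSeed(deriveSeed(seed, si, r), {
        unlist(lapply(classes, function(cl) {
          pool <- which(labels == cl)
          pool[sample.int(length(pool), half)]
        }))
      })
      res <- runProtocol(aux[, idx], target, hp = hp, cfg = cfg,
                         protocol = "auxiliary")
      unname(metricMeans(res)["acc"])
    }, numeric(1))
    data.frame(size = size, meanAcc = mean(accs), sdAcc = sd(accs),
               seAcc = sd(accs) / sqrt(length(accs)))
  })
  do.call(rbind, out)
}
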