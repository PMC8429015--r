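# internal helpers

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions never leak RNG
#' state into the caller's session.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# mixed-radix seed derivation; keeps derived seeds inside 32-bit range
deriveSeed <- function(base, ...) {
  idx <- c(...)
  s <- as.double(base)
  for (i in idx) s <- (s * 7919 + i) %% 2147483629
  as.integer(s)
}

stopIfNotFinite <- function(x, name) {
  if (!all(is.finite(x)))
    stop("non-finite values in '", name, "'", call. = FALSE)
  invisible(x)
}

checkSymmetric <- function(W, tol = 1e-8) {
  if (nrow(W) != ncol(W) || max(abs(W - t(W))) > tol)
    stop("matrix must be symmetric", call. = FALSE)
  invisible(W)
}
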