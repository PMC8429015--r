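#' Cross-validation configuration
#'
#' @param nFolds number of CV folds (>= 2); default 10.
#' @param nRepeats number of repeated CV rounds (>= 1); default 20.
#' @param baseSeed integer seed; fold assignments of repeat r are
#'   deterministic in `(baseSeed, r)`.
#' @param stratified stratify folds by class (default); set `FALSE` for
#'   plain random partitions.
#' @param classifier one of `"svm-linear"`, `"svm-rbf"`, `"decision-tree"`.
#' @param classifierParams optional list of classifier hyperparameters:
#'   `cost`/`gamma` for the SVMs, [rpart::rpart.control()] arguments for
#'   the tree.
#' @return a validated configuration list.
#' @export
cvConfig <- function(nFolds = 10L, nRepeats = 20L, baseSeed = 1L,
                     stratified = TRUE,
                     classifier = c("svm-linear", "svm-rbf", "decision-tree"),
                     classifierParams = list()) {
  nFolds <- as.integer(nFolds); nRepeats <- as.integer(nRepeats)
  if (nFolds < 2L) stop("nFolds must be >= 2", call. = FALSE)
  if (nRepeats < 1L) stop("nRepeats must be >= 1", call. = FALSE)
  list(nFolds = nFolds, nRepeats = nRepeats,
       baseSeed = as.integer(baseSeed), stratified = isTRUE(stratified),
       classifier = match.arg(classifier),
       classifierParams = classifierParams)
}

#' Assign samples to cross-validation folds
#'
#' Deterministic in `seed`. Under stratification, each class is shuffled
#' and dealt to folds through a rotating offset carried across classes, so
#' per-fold class counts differ by at most one and overall fold sizes stay
#' balanced. A class smaller than `nFolds` triggers a warning (best-effort
#' balance; some folds then lack that class).
#'
#' @param labels length-n class labels.
#' @param nFolds number of folds, `2 <= nFolds <= n`.
#' @param stratified stratify by class.
#' @param seed integer seed.
#' @return integer fold assignment of length n, values in `1:nFolds`.
#' @export
makeFolds <- function(labels, nFolds = 10L, stratified = TRUE, seed = 1L) {
  n <- length(labels)
  nFolds <- as.integer(nFolds)
  if (n < nFolds) stop("need at least nFolds samples", call. = FALSE)
  withSeed(seed, {
    folds <- integer(n)
    if (stratified) {
      labels <- as.character(labels)
      classes <- unique(labels)
      small <- classes[tabulate(factor(labels, classes)) < nFolds]
      if (length(small))
        warning("class(es) smaller than nFolds: ",
                paste(small, collapse = ", "), "; folds balanced best-effort")
      offset <- 0L
      for (cl in classes) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- ((offset + seq_along(idx) - 1L) %% nFolds) + 1L
        offset <- offset + length(idx)
      }
    } else {
      folds <- rep_len(seq_len(nFolds), n)[sample.int(n)]
    }
    folds
  })
}

# fit one classifier on training biomarkers and score the test block;
# score is oriented so larger = more positive-like
.fitPredict <- function(trainX, trainY, testX, classifier, params, positive) {
  trainY <- as.character(trainY)
  classes <- unique(trainY)
  if (length(classes) < 2L) {
    warning("degenerate training fold: single class '", classes, "'")
    return(list(pred = rep(classes, nrow(testX)),
                score = rep(if (classes == positive) 1 else -1, nrow(testX))))
  }
  negative <- setdiff(classes, positive)[1]
  yf <- factor(trainY, levels = c(positive, negative))
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  colnames(trainX) <- colnames(testX) <- paste0("f", seq_len(ncol(trainX)))
  if (classifier %in% c("svm-linear", "svm-rbf")) {
    fit <- e1071::svm(
      x = trainX, y = yf,
      kernel = if (classifier == "svm-linear") "linear" else "radial",
      cost = params$cost %||% 1,
      gamma = params$gamma %||% (1 / ncol(trainX)),
      scale = FALSE)
    pr <- predict(fit, testX, decision.values = TRUE)
    dv <- drop(attr(pr, "decision.values"))
    # orient the decision value toward the positive class
    lead <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
    if (lead != positive) dv <- -dv
    list(pred = as.character(pr), score = dv)
  } else {                           # decision tree
    ctl <- do.call(rpart::rpart.control, params)
    df <- data.frame(trainX, y = yf)
    fit <- rpart::rpart(y ~ ., data = df, method = "class", control = ctl)
    prob <- predict(fit, data.frame(testX), type = "prob")[, positive]
    cls <- as.character(predict(fit, data.frame(testX), type = "class"))
    list(pred = cls, score = prob)
  }
}

# learn a projection model on a subject subset of a two-view cohort
.learnOnSubset <- function(target, idx, hp, classOrder) {
  learnProjections(target[, idx], hp = hp, classOrder = classOrder)
}

#' Run the repeated cross-validation evaluation protocol
#'
#' Evaluates the fused subspace biomarkers on a binary target cohort
#' (pMCI vs sMCI analogue) by repeated stratified k-fold cross-validation.
#'
#' Under `protocol = "auxiliary"` the projections (and standardization) are
#' learned once from the full auxiliary cohort, biomarkers are computed for
#' every target subject, and cross-validation trains/tests only the
#' classifier. Under `protocol = "self"` the projections are relearned
#' inside every repeat and fold from the target *training* folds only, and
#' train- and test-fold biomarkers both come from that fold's model, so no
#' test-fold information enters model fitting.
#'
#' Per repeat, out-of-fold predictions are pooled into a single
#' accuracy/sensitivity/specificity/AUC panel.
#'
#' @param aux auxiliary [MultiViewCohort-class] (e.g. AD/NC); used only
#'   under the auxiliary protocol.
#' @param target binary-labeled target [MultiViewCohort-class].
#' @param hp hyperparameters from [hyperParams()].
#' @param cfg configuration from [cvConfig()].
#' @param protocol `"auxiliary"` or `"self"`.
#' @param positiveClass positive label; defaults to `"pMCI"` when present,
#'   otherwise the alphabetically first target class.
#' @param ... unused.
#' @return a [ProtocolResult-class].
#' @rdname runProtocol
#' @export
setMethod("runProtocol", signature("MultiViewCohort", "MultiViewCohort"),
  function(aux, target, hp = hyperParams(), cfg = cvConfig(),
           protocol = c("auxiliary", "self"), positiveClass = NULL, ...) {
    protocol <- match.arg(protocol)
    labels <- groupLabels(target)
    classes <- sort(unique(labels))
    if (length(classes) != 2L)
      stop("target cohort must contain exactly 2 classes", call. = FALSE)
    positiveClass <- positiveClass %||%
      (if ("pMCI" %in% classes) "pMCI" else classes[1])
    if (!(positiveClass %in% classes))
      stop("positiveClass not present in target labels", call. = FALSE)
    n <- length(labels)
    ids <- colnames(target) %||% as.character(seq_len(n))

    if (protocol == "auxiliary") {
      if (ncol(aux) == 0L)
        stop("auxiliary cohort is empty", call. = FALSE)
      model <- learnProjections(aux, hp = hp)
      B <- extractBiomarkers(model, target)
    }

    perRepeat <- data.frame(acc = numeric(0), sen = numeric(0),
                            spe = numeric(0), auc = numeric(0))
    recs <- vector("list", cfg$nRepeats)
    for (r in seq_len(cfg$nRepeats)) {
      folds <- makeFolds(labels, cfg$nFolds, cfg$stratified,
                         seed = deriveSeed(cfg$baseSeed, r))
      pred <- character(n)
      score <- numeric(n)
      for (f in seq_len(cfg$nFolds)) {
        test <- which(folds == f)
        train <- which(folds != f)
        if (!length(test)) next
        if (protocol == "self") {
          modF <- .learnOnSubset(target, train, hp, classes)
          Btr <- extractBiomarkers(modF, target[, train])
          Bte <- extractBiomarkers(modF, target[, test])
        } else {
          Btr <- B[train, , drop = FALSE]
          Bte <- B[test, , drop = FALSE]
        }
        fp <- .fitPredict(Btr, labels[train], Bte, cfg$classifier,
                          cfg$classifierParams, positiveClass)
        pred[test] <- fp$pred
        score[test] <- fp$score
      }
      m <- confusionMetrics(labels, pred, positiveClass)
      a <- aucScore(labels, score, positiveClass)
      perRepeat[r, ] <- c(m, auc = a)
      recs[[r]] <- data.frame(repeatIndex = r, fold = folds, subject = ids,
                              trueLabel = labels, pred = pred, score = score)
    }
    means <- colMeans(perRepeat)
    new("ProtocolResult", perRepeat = perRepeat, means = means,
        protocol = protocol, positiveClass = positiveClass,
        config = cfg, foldRecords = do.call(rbind, recs))
  })

#' Accessors for ProtocolResult
#'
#' `repeatMetrics` returns the per-repeat metric panel, `metricMeans` the
#' metric means over repeats, `foldRecords` the pooled per-subject
#' out-of-fold predictions.
#'
#' @param x a [ProtocolResult-class].
#' @name ProtocolResult-accessors
NULL

#' @rdname ProtocolResult-accessors
setMethod("repeatMetrics", "ProtocolResult", function(x) x@perRepeat)

#' @rdname ProtocolResult-accessors
setMethod("metricMeans", "ProtocolResult", function(x) x@means)

#' @rdname ProtocolResult-accessors
setMethod("foldRecords", "ProtocolResult", function(x) x@foldRecords)

#' Write protocol results to disk
#'
#' One CSV row per repeat plus a JSON summary (metric means, protocol,
#' configuration, seed).
#'
#' @param result a [ProtocolResult-class].
#' @param csvPath,jsonPath output paths (`NULL` to skip either).
#' @return invisible list of written paths.
#' @export
writeProtocolResult <- function(result, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath))
    write.csv(cbind(repeatIndex = seq_len(nrow(result@perRepeat)),
                    result@perRepeat), csvPath, row.names = FALSE)
  if (!is.null(jsonPath))
    jsonlite::write_json(
      list(means = as.list(result@means), protocol = result@protocol,
           positiveClass = result@positiveClass,
           config = result@config[c("nFolds", "nRepeats", "baseSeed",
                                    "stratified", "classifier")]),
      jsonPath, digits = NA, auto_unbox = TRUE)
  invisible(list(csv = csvPath, json = jsonPath))
}
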