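makeEvalCohort <- function(delta = 2, seed = 5,
                           n = c(AD = 40L, NC = 40L, pMCI = 30L, sMCI = 30L),
                           d = 10) {
  splitCohort(generateCohort(cohortSpec(nPerGroup = n, d = d, delta = delta,
                                        seed = seed)))
}

test_that("fold assignment is deterministic, exhaustive and stratified", {
  labels <- rep(c("p", "s"), c(12, 8))
  # the 8-member class is smaller than nFolds: warned, balanced best-effort
  f1 <- suppressWarnings(makeFolds(labels, nFolds = 10, seed = 4))
  f2 <- suppressWarnings(makeFolds(labels, nFolds = 10, seed = 4))
  expect_identical(f1, f2)
  expect_true(all(f1 %in% 1:10))
  expect_length(f1, 20)
  # 20 samples in 10 folds: every fold exactly 2
  expect_true(all(table(f1) == 2))
  # stratified: per-fold positive counts differ by at most 1
  posPerFold <- tapply(labels == "p", f1, sum)
  expect_lte(diff(range(posPerFold)), 1)
  f3 <- suppressWarnings(makeFolds(labels, nFolds = 10, seed = 5))
  expect_false(identical(f1, f3))
  expect_error(makeFolds(labels[1:5], nFolds = 10), "at least")
  expect_warning(makeFolds(rep(c("p", "s"), c(3, 17)), nFolds = 10, seed = 1),
                 "smaller than nFolds")
  # unstratified folds still balanced in size
  fu <- makeFolds(labels, nFolds = 4, stratified = FALSE, seed = 7)
  expect_true(all(table(fu) == 5))
})

test_that("protocol runs are deterministic and internally consistent", {
  sp <- makeEvalCohort()
  cfg <- cvConfig(nFolds = 5, nRepeats = 4, baseSeed = 11)
  hp <- hyperParams(kCT = 5, kCV = 5)
  r1 <- runProtocol(sp$aux, sp$target, hp, cfg, "auxiliary")
  r2 <- runProtocol(sp$aux, sp$target, hp, cfg, "auxiliary")
  expect_identical(repeatMetrics(r1), repeatMetrics(r2))
  expect_identical(foldRecords(r1), foldRecords(r2))
  expect_equal(nrow(repeatMetrics(r1)), 4L)
  # means equal arithmetic means of per-repeat values
  expect_equal(unname(metricMeans(r1)),
               unname(colMeans(repeatMetrics(r1))), tolerance = 1e-12)
  # pooled-per-repeat accuracy recomputes from the fold records
  fr <- foldRecords(r1)
  for (r in unique(fr$repeatIndex)) {
    sub <- fr[fr$repeatIndex == r, ]
    expect_equal(mean(sub$pred == sub$trueLabel),
                 repeatMetrics(r1)$acc[r], tolerance = 1e-12)
    expect_equal(aucScore(sub$trueLabel, sub$score, "pMCI"),
                 repeatMetrics(r1)$auc[r], tolerance = 1e-12)
  }
})

test_that("all three classifier families run and beat chance on signal", {
  sp <- makeEvalCohort(delta = 3, seed = 21)
  for (clf in c("svm-linear", "svm-rbf", "decision-tree")) {
    res <- runProtocol(sp$aux, sp$target, hyperParams(kCT = 5, kCV = 5),
                       cvConfig(nRepeats = 3, classifier = clf), "auxiliary")
    expect_gt(metricMeans(res)["acc"], 0.6)
    expect_true(all(repeatMetrics(res)$auc >= 0 &
                    repeatMetrics(res)$auc <= 1))
  }
})

test_that("self protocol learns projections from training folds only", {
  sp <- makeEvalCohort(delta = 2, seed = 8)
  cfg <- cvConfig(nFolds = 5, nRepeats = 2, baseSeed = 3)
  hp <- hyperParams(kCT = 5, kCV = 5)
  rs <- runProtocol(sp$aux, sp$target, hp, cfg, "self")
  expect_s4_class(rs, "ProtocolResult")
  expect_equal(rs@protocol, "self")

  # leakage audit by instrumentation: corrupting the held-out fold's
  # features before fitting leaves the fold's model (projections,
  # standardization) and the training-fold biomarkers bit-identical
  labels <- groupLabels(sp$target)
  folds <- makeFolds(labels, cfg$nFolds, TRUE,
                     mvslearn:::deriveSeed(cfg$baseSeed, 1L))
  corrupt <- which(folds == 1L)
  train <- which(folds != 1L)
  tgt2 <- sp$target
  SummarizedExperiment::assay(tgt2, "thickness")[, corrupt] <- 999
  SummarizedExperiment::assay(tgt2, "volume")[, corrupt] <- -999
  m1 <- learnProjections(sp$target[, train], hp, classOrder = c("pMCI", "sMCI"))
  m2 <- learnProjections(tgt2[, train], hp, classOrder = c("pMCI", "sMCI"))
  expect_identical(projectionU(m1), projectionU(m2))
  expect_identical(projectionV(m1), projectionV(m2))
  expect_identical(m1@scaleCT, m2@scaleCT)
  expect_identical(m1@centerCV, m2@centerCV)
  expect_identical(extractBiomarkers(m1, sp$target[, train]),
                   extractBiomarkers(m2, tgt2[, train]))
})

test_that("protocol rejects degenerate targets and unknown positives", {
  sp <- makeEvalCohort()
  onlyP <- sp$target[, groupLabels(sp$target) == "pMCI"]
  expect_error(runProtocol(sp$aux, onlyP, cvConfig()), "2 classes")
  expect_error(runProtocol(sp$aux, sp$target, hyperParams(kCT = 5, kCV = 5),
                           cvConfig(), positiveClass = "AD"),
               "positiveClass")
  empty <- sp$aux[, 0]
  expect_error(runProtocol(empty, sp$target, hyperParams(kCT = 5, kCV = 5),
                           cvConfig(), "auxiliary"), "empty")
})

test_that("grid enumeration and ranking behave as specified", {
  expect_equal(nrow(gridCombinations()), 119070L)
  expect_equal(prod(lengths(defaultGrids())), 119070)
  expect_error(gridCombinations(list(lambda = numeric(0), alpha = 1,
                                     beta = 1, kCT = 1, kCV = 1, eta = 1)),
               "empty grid")
  sp <- makeEvalCohort(delta = 2.5, seed = 31)
  cfg <- cvConfig(nFolds = 5, nRepeats = 2, baseSeed = 2)
  singleton <- list(lambda = 0.5, alpha = 0.1, beta = 1, kCT = 5L,
                    kCV = 5L, eta = 0.5)
  tab <- gridSearch(sp$aux, sp$target, singleton, cfg,
                    screeningRepeats = NULL)
  expect_equal(nrow(tab), 1L)
  direct <- runProtocol(sp$aux, sp$target,
                        hyperParams(0.5, 0.1, 1, 5L, 5L, 0.5), cfg,
                        "auxiliary")
  expect_equal(tab$acc, unname(metricMeans(direct)["acc"]))
  # a small 2x2 grid comes back sorted by accuracy then AUC
  grids <- list(lambda = c(0.1, 0.5), alpha = 0.1, beta = c(1, 10),
                kCT = 5L, kCV = 5L, eta = 0.5)
  tab2 <- gridSearch(sp$aux, sp$target, grids, cfg, screeningRepeats = 2)
  expect_equal(nrow(tab2), 4L)
  expect_true(all(diff(tab2$acc) <= 0))
})

test_that("auxiliary size sweep draws balanced subsets deterministically", {
  sp <- makeEvalCohort(delta = 2, seed = 41,
                       n = c(AD = 30L, NC = 30L, pMCI = 20L, sMCI = 20L))
  cfg <- cvConfig(nFolds = 5, nRepeats = 2, baseSeed = 6)
  hp <- hyperParams(kCT = 5, kCV = 5)
  sw <- auxiliarySizeSweep(sp$aux, sp$target, hp, cfg,
                           sizes = c(20L, 40L), nResamples = 2, seed = 3)
  expect_equal(sw$size, c(20L, 40L))
  expect_true(all(sw$meanAcc >= 0 & sw$meanAcc <= 1))
  sw2 <- auxiliarySizeSweep(sp$aux, sp$target, hp, cfg,
                            sizes = c(20L, 40L), nResamples = 2, seed = 3)
  expect_identical(sw, sw2)
  expect_error(auxiliarySizeSweep(sp$aux, sp$target, hp, cfg,
                                  sizes = 100L, nResamples = 1),
               "exceeds")
  # full balanced set with one resample equals a direct protocol run
  sw3 <- auxiliarySizeSweep(sp$aux, sp$target, hp, cfg, sizes = 60L,
                            nResamples = 1, seed = 1)
  direct <- runProtocol(sp$aux, sp$target, hp, cfg, "auxiliary")
  expect_equal(sw3$meanAcc, unname(metricMeans(direct)["acc"]))
})
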