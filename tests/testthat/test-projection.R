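test_that("label encoding is one-hot with the declared class order", {
  Y <- encodeLabels(c("AD", "NC", "AD"), c("AD", "NC"))
  expect_equal(unname(Y), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_equal(rowSums(Y), rep(1, 3))
  expect_error(encodeLabels(c("AD", "XX"), c("AD", "NC")), "unknown")
  expect_error(encodeLabels(character(0), c("AD", "NC")), "no class")
  # degenerate: a declared class with no members is accepted with a warning
  expect_warning(Y2 <- encodeLabels(c("NC", "NC"), c("AD", "NC")),
                 "zero members")
  expect_equal(unname(Y2), rbind(c(0, 1), c(0, 1)))
})

test_that("objective closed form matches hand values at zero projections", {
  d <- 3; n <- 5
  Y <- encodeLabels(c("a", "b", "a", "b", "a"), c("a", "b"))
  Z <- matrix(0, d, 2)
  L <- buildLaplacian(randomW(n, 1))
  hp <- hyperParams(lambda = 0.1, alpha = 1, beta = 1, kCT = 1, kCV = 1)
  X <- matrix(rnorm(d * n), d, n)
  expect_equal(objectiveQ(Z, Z, X, X, Y, L, L, hp), 2 * 0.1 * n)
  # only the ridge term survives with zero data and labels
  U <- matrix(rnorm(d * 2), d, 2)
  X0 <- matrix(0, d, n)
  expect_equal(objectiveQ(U, U, X0, X0, matrix(0, n, 2), L, L, hp),
               hp$beta * 2 * sum(U^2))
})

test_that("objective agrees with the scalar-loop oracle on random instances", {
  for (s in 1:20) {
    inst <- randomInstance(d = sample(3:8, 1), n = sample(5:12, 1), seed = s)
    U <- matrix(rnorm(inst$d * inst$cc), inst$d, inst$cc)
    V <- matrix(rnorm(inst$d * inst$cc), inst$d, inst$cc)
    q <- objectiveQ(U, V, inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$Lcv,
                    inst$hp)
    qo <- oracleObjective(U, V, inst$Xct, inst$Xcv, inst$Y, inst$Lct,
                          inst$Lcv, inst$hp)
    expect_equal(q, qo, tolerance = 1e-10)
    expect_gte(q, 0)
  }
})

test_that("updates zero out with zero data and respect symmetry", {
  inst <- randomInstance(seed = 3)
  z <- matrix(0, inst$d, inst$n)
  V <- matrix(rnorm(inst$d * inst$cc), inst$d, inst$cc)
  expect_equal(updateU(V, z, inst$Xcv, inst$Y, inst$Lct, inst$hp),
               matrix(0, inst$d, inst$cc))
  # mirrored arguments: identical views and Laplacians give identical blocks
  U <- matrix(rnorm(inst$d * inst$cc), inst$d, inst$cc)
  expect_equal(updateV(U, inst$Xct, inst$Xct, inst$Y, inst$Lct, inst$hp),
               updateU(U, inst$Xct, inst$Xct, inst$Y, inst$Lct, inst$hp))
  expect_error(updateU(V, inst$Xct * NA, inst$Xcv, inst$Y, inst$Lct,
                       inst$hp), "non-finite")
})

test_that("with alpha = 0 and the cross term off, updates reduce to ridge", {
  for (s in 1:20) {
    inst <- randomInstance(d = 5, n = 9, seed = 40 + s)
    hp <- inst$hp
    hp$lambda <- 1            # cross-view weight (1 - lambda) zeroed
    hp$alpha <- 0
    U <- updateU(matrix(0, inst$d, inst$cc), inst$Xct, inst$Xcv, inst$Y,
                 inst$Lct, hp)
    expect_equal(U, oracleRidge(inst$Xct, inst$Y, hp$beta),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the block gradient of the objective vanishes at each update", {
  for (s in 1:8) {
    inst <- randomInstance(d = 4, n = 7, seed = 60 + s)
    V <- matrix(rnorm(inst$d * inst$cc), inst$d, inst$cc)
    U <- updateU(V, inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$hp)
    gU <- numGradient(function(M) objectiveQ(M, V, inst$Xct, inst$Xcv,
                                             inst$Y, inst$Lct, inst$Lcv,
                                             inst$hp), U)
    expect_lt(max(abs(gU)), 1e-5)
    V2 <- updateV(U, inst$Xct, inst$Xcv, inst$Y, inst$Lcv, inst$hp)
    gV <- numGradient(function(M) objectiveQ(U, M, inst$Xct, inst$Xcv,
                                             inst$Y, inst$Lct, inst$Lcv,
                                             inst$hp), V2)
    expect_lt(max(abs(gV)), 1e-5)
  }
})

test_that("alternating fit starts at zero, converges monotonically, and is a fixed point", {
  # all-zero data: fixed point at the start
  n <- 6; d <- 3
  Y <- encodeLabels(rep(c("a", "b"), 3), c("a", "b"))
  L <- buildLaplacian(matrix(0, n, n))
  hp <- hyperParams(kCT = 1, kCV = 1)
  z <- matrix(0, d, n)
  fit0 <- fitProjections(z, z, Y, L, L, hp)
  expect_equal(fit0$U, matrix(0, d, 2))
  expect_true(fit0$converged)
  expect_equal(fit0$nIter, 1L)

  for (s in 1:10) {
    inst <- randomInstance(d = 6, n = 12, seed = 80 + s)
    fit <- fitProjections(inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$Lcv,
                          inst$hp, tol = 1e-12, maxIter = 500)
    tr <- fit$trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, tr[-length(tr)])))
    # reapplying the updates at the solution barely moves it
    U2 <- updateU(fit$V, inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$hp)
    V2 <- updateV(U2, inst$Xct, inst$Xcv, inst$Y, inst$Lcv, inst$hp)
    expect_lt(max(abs(U2 - fit$U)), 1e-6)
    expect_lt(max(abs(V2 - fit$V)), 1e-6)
  }
})

test_that("fit is equivariant to a consistent subject permutation", {
  inst <- randomInstance(d = 5, n = 10, seed = 17)
  fit <- fitProjections(inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$Lcv,
                        inst$hp, tol = 1e-12)
  set.seed(18); p <- sample(inst$n)
  permL <- function(L) new("GraphLaplacian", L = L@L[p, p],
                           degree = L@degree[p])
  fitP <- fitProjections(inst$Xct[, p], inst$Xcv[, p], inst$Y[p, ],
                         permL(inst$Lct), permL(inst$Lcv), inst$hp,
                         tol = 1e-12)
  expect_equal(fit$U, fitP$U, tolerance = 1e-8)
  expect_equal(fit$V, fitP$V, tolerance = 1e-8)
})

test_that("growing the ridge weight shrinks the projections monotonically", {
  inst <- randomInstance(d = 5, n = 10, seed = 23)
  norms <- vapply(c(1e2, 1e4, 1e6, 1e8), function(b) {
    hp <- inst$hp; hp$beta <- b
    fit <- fitProjections(inst$Xct, inst$Xcv, inst$Y, inst$Lct, inst$Lcv, hp)
    sqrt(sum(fit$U^2) + sum(fit$V^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 1e-5)
})

test_that("learnProjections fits a cohort end to end and round-trips as JSON", {
  ch <- generateCohort(cohortSpec(
    nPerGroup = c(AD = 30L, NC = 30L, pMCI = 20L, sMCI = 20L),
    d = 10, delta = 2, seed = 5))
  sp <- splitCohort(ch)
  hp <- hyperParams(kCT = 5, kCV = 5)
  model <- learnProjections(sp$aux, hp)
  expect_s4_class(model, "ProjectionModel")
  expect_equal(dim(projectionU(model)), c(10L, 2L))
  expect_identical(classOrder(model), c("AD", "NC"))
  expect_true(all(diff(fitTrace(model)) <= 1e-9 * pmax(1, fitTrace(model)[-model@nIter])))

  path <- tempfile(fileext = ".json")
  writeProjectionModel(model, path)
  model2 <- readProjectionModel(path)
  expect_equal(projectionU(model2), unname(projectionU(model)))
  expect_equal(projectionV(model2), unname(projectionV(model)))
  B1 <- extractBiomarkers(model, sp$target)
  B2 <- extractBiomarkers(model2, sp$target)
  expect_equal(unname(B1), unname(B2), tolerance = 1e-12)
})
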