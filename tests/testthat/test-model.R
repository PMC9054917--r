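test_that("label mask puts labeled instances first and validates emptiness", {
  Y <- rbind(c(1, -1), c(0, 0), c(-1, 1), c(0, 0))
  m <- buildPsi(Y)
  expect_equal(m$labeled, c(1, 3))
  expect_equal(m$l, 2)
  expect_equal(m$u, 2)
  expect_equal(m$psi, c(1, 1, 0, 0))
  expect_equal(m$order[1:2], c(1, 3))
  expect_equal(m$order[m$inverse], 1:4)
  # all labeled -> identity selector
  expect_equal(buildPsi(matrix(1, 3, 2))$psi, rep(1, 3))
  expect_error(buildPsi(matrix(0, 3, 2)), "no labeled")
})

test_that("uniform reliance weights follow the labeled/unlabeled split", {
  m <- buildPsi(rbind(c(1, 1), c(1, -1), c(0, 0), c(0, 0)))
  expect_equal(relianceWeights(m, 1, 0.1), c(1, 1, 0.1, 0.1))
  expect_equal(relianceWeights(m, 1, 1), rep(1, 4))  # degenerates to unweighted
  expect_error(relianceWeights(m, 1, -0.5), "non-negative")
})

test_that("objective value matches an independent term-by-term summation", {
  set.seed(101)
  n <- 8; L <- 3
  Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
  m <- buildPsi(Y)
  W <- random_weights(n)
  Lp <- graphLaplacian(W)$L
  Fm <- matrix(rnorm(n * L), n, L)
  # fully labeled, F = Y, no regularization -> 0
  expect_equal(mlmrObjective(Y, Y, m, Lp, 0, 0, fNormSq = 0), 0)
  # constant rows kill the Laplacian term
  Fc <- matrix(rep(rnorm(L), each = n), n, L)
  expect_equal(mlmrObjective(Fc, matrix(0, n, L),
                             list(psi = rep(0, n), l = 1, n = n),
                             Lp, 0, 5, fNormSq = 0), 0, tolerance = 1e-10)
  # random instance vs scalar loops
  got <- mlmrObjective(Fm, Y, m, Lp, 0.3, 0.7, fNormSq = 2.5)
  loss <- 0
  for (i in seq_len(n)) for (j in seq_len(L))
    loss <- loss + (m$psi[i] * Fm[i, j] - Y[i, j])^2
  expected <- loss / m$l + 0.3 * 2.5 + 0.7 / n^2 * oracle_quadform(W, Fm)
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("closed-form fit reduces to ridge shrinkage for identity kernel", {
  # K = I, gammaI = 0, all labeled, Xi = I: system is (1 + l gammaA) I
  n <- 6; L <- 2
  Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
  fit <- mlmrFit(diag(n), matrix(0, n, n), Y, gammaA = 0.5, gammaI = 0,
                 nu1 = 1, nu2 = 1)
  expect_equal(fit$theta, Y / (1 + n * 0.5), tolerance = 1e-12)
})

test_that("closed-form solution attains the numerical minimizer's optimum (Xi = I)", {
  set.seed(111)
  for (rep in 1:4) {
    n <- sample(10:20, 1); L <- sample(2:3, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    U <- gaussianKernel(X, 1.5)
    attr(U, "sigma") <- NULL
    H <- kernelToDistance(U)
    Lp <- graphLaplacian(edgeWeights(H, U, sparsifyKnn(H, 3), "distance"))$L
    Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
    Y[sample(n, floor(n / 2)), ] <- 0
    gammaA <- 0.05; gammaI <- 0.2
    fit <- mlmrFit(U, Lp, Y, gammaA = gammaA, gammaI = gammaI,
                   nu1 = 1, nu2 = 1)
    objClosed <- objective_of_theta(fit$theta, U, Lp, Y, gammaA, gammaI)
    opt <- oracle_minimize(U, Lp, Y, gammaA, gammaI)
    gap <- (objClosed - opt$value) / abs(opt$value)
    expect_lt(gap, 1e-6)
  }
})

test_that("reliance-weighted fit matches the explicitly weighted linear system", {
  set.seed(121)
  n <- 12; L <- 2
  X <- matrix(rnorm(n * 2), n, 2)
  U <- unclass(gaussianKernel(X, 1)); attr(U, "sigma") <- NULL
  Lp <- graphLaplacian(random_weights(n))$L
  Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
  Y[7:12, ] <- 0
  # labeled instances already first, so caller order = internal order and
  # the system can be assembled directly
  xi <- c(rep(1, 6), rep(0.1, 6))
  psi <- c(rep(1, 6), rep(0, 6))
  A <- diag(psi) %*% U %*% diag(xi) + diag(6 * 0.01, n) +
    (6 * 0.1 / n^2) * Lp %*% U %*% diag(xi)
  expected <- solve(A, Y)
  fit <- mlmrFit(U, Lp, Y, gammaA = 0.01, gammaI = 0.1, nu1 = 1, nu2 = 0.1)
  expect_equal(fit$theta, expected, tolerance = 1e-10)
  # nu1 = nu2 = 1 equals the unweighted system (Xi omitted)
  A1 <- diag(psi) %*% U + diag(6 * 0.01, n) + (6 * 0.1 / n^2) * Lp %*% U
  fit1 <- mlmrFit(U, Lp, Y, gammaA = 0.01, gammaI = 0.1, nu1 = 1, nu2 = 1)
  expect_equal(fit1$theta, solve(A1, Y), tolerance = 1e-10)
})

test_that("labeled-first reordering is transparent to the caller", {
  set.seed(131)
  n <- 10; L <- 2
  X <- matrix(rnorm(n * 2), n, 2)
  U <- unclass(gaussianKernel(X, 1))
  Lp <- graphLaplacian(random_weights(n))$L
  Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
  unlab <- c(2, 5, 9)
  Y[unlab, ] <- 0
  fit <- mlmrFit(U, Lp, Y, gammaA = 0.01, gammaI = 0.1, nu1 = 1, nu2 = 0.3)
  # permuting instances permutes the solution identically
  p <- sample(n)
  fitp <- mlmrFit(U[p, p], Lp[p, p], Y[p, , drop = FALSE],
                  gammaA = 0.01, gammaI = 0.1, nu1 = 1, nu2 = 0.3)
  expect_equal(fitp$theta, fit$theta[p, , drop = FALSE], tolerance = 1e-8)
  expect_equal(fitp$xi, fit$xi[p])
})

test_that("supervised limit: nu2 = 0 makes predictions ignore unlabeled coefficients", {
  set.seed(141)
  n <- 15
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(sample(c(-1, 1), n * 2, TRUE), n, 2)
  Y[8:15, ] <- 0
  fit <- mlmr(X, Y, sigma = 1.5, nu1 = 1, nu2 = 0)
  Xt <- matrix(rnorm(12), 4, 3)
  S <- predictScores(fit, Xt)
  # perturb coefficients of unlabeled training instances arbitrarily
  fit2 <- fit
  fit2@theta[8:15, ] <- fit2@theta[8:15, ] + matrix(rnorm(16, sd = 100), 8, 2)
  expect_equal(predictScores(fit2, Xt), S, tolerance = 1e-12)
  # zero reliance everywhere annihilates all scores
  fit3 <- fit
  fit3@xi[] <- 0
  expect_true(all(predictScores(fit3, Xt) == 0))
})

test_that("predictions vary continuously in the unlabeled reliance weight", {
  set.seed(151)
  n <- 20
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- matrix(sample(c(-1, 1), n * 2, TRUE), n, 2)
  Y[11:20, ] <- 0
  Xt <- matrix(rnorm(9), 3, 3)
  sAt <- function(nu2) predictScores(mlmr(X, Y, sigma = 1.5, nu1 = 1,
                                          nu2 = nu2), Xt)
  for (nu2 in c(0.1, 0.3, 0.6)) {
    base <- sAt(nu2)
    d1 <- max(abs(sAt(nu2 + 1e-4) - base))
    expect_lt(d1, 1e-2)  # small parameter step -> small prediction step
  }
})

test_that("prediction applies the reliance-weighted cross kernel", {
  set.seed(161)
  n <- 8; L <- 2
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- matrix(sample(c(-1, 1), n * L, TRUE), n, L)
  fit <- mlmr(X, Y, sigma = 1.2, nu1 = 1, nu2 = 1)
  Xt <- matrix(rnorm(6), 3, 2)
  S <- predictScores(fit, Xt)
  Ke <- kernelCross(Xt, X, 1.2)
  # triple-loop oracle
  for (i in 1:3) for (j in 1:L) {
    s <- 0
    for (t in 1:n) s <- s + Ke[i, t] * fit@xi[t] * fit@theta[t, j]
    expect_equal(unname(S[i, j]), s, tolerance = 1e-10)
  }
  expect_error(predictScores(fit, matrix(0, 2, 5)), "dimension")
})

test_that("score thresholding maps 0 to absent and flips with sign", {
  S <- rbind(c(0.2, -0.3, 0), c(1, 2, 3))
  Yhat <- thresholdLabels(S)
  expect_equal(Yhat[1, ], c(1, -1, -1))
  expect_equal(Yhat[2, ], c(1, 1, 1))
  flip <- thresholdLabels(-S)
  nz <- S != 0
  expect_true(all(flip[nz] == -Yhat[nz]))
})

test_that("pipeline fit reproduces clean, fully labeled cluster data", {
  d <- generateMultiLabel(n = 60, d = 4, L = 4, C = 3,
                          centerSeparation = 20, clusterSpread = 0.5,
                          labelsPerCluster = 2, labelFlipProb = 0, seed = 7)
  X <- features(d)
  Y <- labelMatrix(d)
  fit <- mlmr(X, Y, gammaA = 1e-4, gammaI = 0, nu1 = 1, nu2 = 1)
  expect_equal(thresholdLabels(predictScores(fit, X)),
               unclass(Y), ignore_attr = TRUE)
  # determinism: identical config -> identical model
  fit2 <- mlmr(X, Y, gammaA = 1e-4, gammaI = 0, nu1 = 1, nu2 = 1)
  expect_identical(fit@theta, fit2@theta)
  expect_error(mlmr(X, matrix(0, 60, 4)), "no labeled")
})

test_that("weighted kernel quadratic form is non-negative on the proven domain", {
  # the positivity argument covers entrywise non-negative kernels and
  # non-negative v with non-negative weights
  set.seed(171)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    U <- unclass(gaussianKernel(matrix(rnorm(n * 2), n, 2), 1))
    xi <- runif(n)
    v <- runif(n)
    expect_gte(sum(v * (U %*% (xi * v))), 0)
  }
})

test_that("model archives round-trip through JSON", {
  set.seed(181)
  X <- matrix(rnorm(20), 10, 2)
  Y <- matrix(sample(c(-1, 1), 20, TRUE), 10, 2)
  Y[6:10, ] <- 0
  fit <- mlmr(X, Y, sigma = 1.1, nu1 = 1, nu2 = 0.2)
  tmp <- tempfile(fileext = ".json")
  writeModel(fit, tmp)
  back <- readModel(tmp)
  expect_equal(back@theta, fit@theta, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back@xi, fit@xi)
  expect_equal(back@sigma, fit@sigma)
  Xt <- matrix(rnorm(6), 3, 2)
  expect_equal(predictScores(back, Xt), predictScores(fit, Xt),
               tolerance = 1e-12)
})
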