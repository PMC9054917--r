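test_that("Gaussian kernel matches direct per-pair evaluation and analytic cases", {
  # analytically forced exponent: |x_i - x_j| = sigma * sqrt(2) -> exp(-1)
  for (sigma in c(0.5, 1, 3)) {
    U <- gaussianKernel(matrix(c(0, sigma * sqrt(2)), 2, 1), sigma = sigma)
    expect_equal(U[1, 2], exp(-1), tolerance = 1e-12)
    expect_equal(diag(U), c(1, 1))
  }
  set.seed(11)
  X <- matrix(rnorm(15), 5, 3)
  U <- gaussianKernel(X, sigma = 1)
  expect_equal(unclass(U), oracle_gaussian(X, 1),
               tolerance = 1e-12, ignore_attr = TRUE)
  # identical instances -> kernel 1
  Xdup <- rbind(X, X[1, ])
  expect_equal(gaussianKernel(Xdup, 1)[1, 6], 1, tolerance = 1e-12)
})

test_that("Gaussian kernel validates inputs and is permutation-consistent", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(gaussianKernel(X, sigma = 0), "positive")
  expect_error(gaussianKernel(X, sigma = -1), "positive")
  Xna <- X; Xna[2, 1] <- NA
  expect_error(gaussianKernel(Xna, 1), "finite")
  p <- c(3, 1, 4, 2)
  U <- gaussianKernel(X, 1)
  Up <- gaussianKernel(X[p, ], 1)
  expect_equal(unclass(Up), unclass(U[p, p]), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("kernel-to-distance conversion reproduces the sqrt(2 - 2U) form", {
  U <- matrix(c(1, exp(-1), 0,
                exp(-1), 1, 0.5,
                0, 0.5, 1), 3, 3)
  H <- kernelToDistance(U)
  expect_equal(H[1, 2], sqrt(2 - 2 * exp(-1)), tolerance = 1e-12)
  expect_equal(H[1, 3], sqrt(2))     # zero similarity -> max distance
  expect_equal(diag(H), c(0, 0, 0))  # identical points
  expect_true(all(H >= 0 & H <= sqrt(2) + 1e-12))
  # negative radicand clamps with a warning
  Ubad <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_warning(Hbad <- kernelToDistance(Ubad), "clamp")
  expect_equal(Hbad[1, 2], 0)
})

test_that("epsilon sparsifier honours both threshold modes", {
  H <- matrix(c(0, 0.2, 0.9,
                0.2, 0, 0.4,
                0.9, 0.4, 0), 3, 3)
  # printed rule keeps LARGE distances: 1 - H <= eps
  Bp <- sparsifyEps(H, 0.5, mode = "as_printed")
  expect_equal(Bp[1, 2], 0)  # 1 - 0.2 = 0.8 > 0.5
  expect_equal(Bp[1, 3], 1)  # 1 - 0.9 = 0.1 <= 0.5
  Bc <- sparsifyEps(H, 0.5, mode = "conventional")
  expect_equal(Bc[1, 2], 1)
  expect_equal(Bc[1, 3], 0)
  expect_equal(diag(Bp), rep(0, 3))
  expect_equal(diag(Bc), rep(0, 3))
  expect_error(sparsifyEps(H, 1.5, mode = "as_printed"), "\\[0, 1\\]")
})

test_that("kNN sparsifier selects nearest rows then max-symmetrizes", {
  # 1-D points {0, 1, 3}: nearest of 1 is 2, of 2 is 1, of 3 is 2
  H <- as.matrix(dist(c(0, 1, 3)))
  B <- sparsifyKnn(H, 1)
  expected <- matrix(c(0, 1, 0,
                       1, 0, 1,
                       0, 1, 0), 3, 3)
  expect_equal(B, expected)
  # raw row-wise selection has row sums exactly k
  set.seed(21)
  for (rep in 1:5) {
    H <- random_distances(8)
    k <- sample(1:6, 1)
    Braw <- sparsifyKnn(H, k, symmetrize = FALSE)
    expect_equal(rowSums(Braw), rep(k, 8))
    Bsym <- sparsifyKnn(H, k)
    expect_equal(Bsym, t(Bsym))
    expect_true(all(rowSums(Bsym) >= k))
    expect_equal(diag(Bsym), rep(0, 8))
  }
  # k = n - 1 -> complete graph
  H <- random_distances(5)
  expect_equal(sparsifyKnn(H, 4), 1 - diag(5))
  expect_error(sparsifyKnn(H, 5), "k must")
})

test_that("kNN distance ties break toward the smaller instance index", {
  # instance 1 is equidistant from 2 and 3; tie must pick index 2
  H <- matrix(c(0, 1, 1,
                1, 0, 2,
                1, 2, 0), 3, 3)
  B <- sparsifyKnn(H, 1, symmetrize = FALSE)
  expect_equal(B[1, ], c(0, 1, 0))
})

test_that("b-matching meets the exact degree constraint and the optimum", {
  # 4 nodes, b = 1: weights engineered so {1-2, 3-4} is the unique
  # minimum perfect matching among the 3 possibilities
  H <- matrix(c(0, 1, 5, 6,
                1, 0, 7, 8,
                5, 7, 0, 2,
                6, 8, 2, 0), 4, 4)
  B <- sparsifyBMatch(H, 1)
  expect_equal(B[1, 2], 1)
  expect_equal(B[3, 4], 1)
  expect_equal(sum(B), 4)
  expect_equal(attr(B, "solver"), "exact")
  # matches exhaustive enumeration
  expect_equal(sum(B * H) / 2, oracle_bmatch(H, 1)$cost)
  # b = n - 1 forces the complete graph
  H5 <- random_distances(5)
  expect_equal(unclass(sparsifyBMatch(H5, 4)), 1 - diag(5),
               ignore_attr = TRUE)
  # infeasible degree sum
  expect_error(sparsifyBMatch(random_distances(5), 1), "even")
  expect_error(sparsifyBMatch(H, 4), "b must")
})

test_that("exact b-matching equals exhaustive enumeration on random instances", {
  set.seed(31)
  for (rep in 1:10) {
    n <- 6
    b <- sample(1:2, 1)
    H <- random_distances(n)
    B <- sparsifyBMatch(H, b)
    expect_equal(rowSums(B), rep(b, n))
    expect_equal(unclass(B), t(unclass(B)), ignore_attr = TRUE)
    expect_equal(sum(B * H) / 2, oracle_bmatch(H, b)$cost,
                 tolerance = 1e-12)
  }
})

test_that("greedy b-matching heuristic always satisfies degree and symmetry", {
  set.seed(41)
  for (rep in 1:8) {
    n <- sample(c(12, 15, 20), 1)
    b <- sample(2:4, 1)
    if ((n * b) %% 2 == 1) b <- b + 1
    H <- random_distances(n)
    B <- sparsifyBMatch(H, b, exactMax = 10)  # forces the heuristic
    expect_equal(attr(B, "solver"), "greedy")
    expect_equal(rowSums(B), rep(b, n))
    expect_equal(unclass(B), t(unclass(B)), ignore_attr = TRUE)
    expect_equal(diag(B), rep(0, n))
  }
})

test_that("edge weights follow the chosen scheme and vanish off-graph", {
  H <- random_distances(6)
  U <- 1 - H / 2
  B <- sparsifyKnn(H, 2)
  Wd <- edgeWeights(H, U, B, "distance")
  Ws <- edgeWeights(H, U, B, "similarity")
  expect_equal(Wd[B == 1], H[B == 1])
  expect_equal(Ws[B == 1], U[B == 1])
  expect_true(all(Wd[B == 0] == 0))
  expect_true(all(Ws[B == 0] == 0))
})

test_that("Laplacian is D - W with zero row sums and PSD", {
  expect_equal(graphLaplacian(matrix(c(0, 1, 1, 0), 2, 2))$L,
               matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(graphLaplacian(matrix(0, 3, 3))$L, matrix(0, 3, 3))
  expect_error(graphLaplacian(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(4:12, 1)
    W <- random_weights(n)
    L <- graphLaplacian(W)$L
    expect_lt(max(abs(rowSums(L))), 1e-10)
    ev <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
    # all-ones vector in the null space
    expect_lt(max(abs(L %*% rep(1, n))), 1e-10)
    # quadratic-form identity against the double-sum oracle
    Fm <- matrix(rnorm(n * 3), n, 3)
    expect_equal(sum(Fm * (L %*% Fm)), oracle_quadform(W, Fm),
                 tolerance = 1e-10)
  }
})

test_that("cross kernel agrees with the symmetric kernel and per-pair loops", {
  set.seed(61)
  X <- matrix(rnorm(18), 6, 3)
  U <- gaussianKernel(X, 1.3)
  Ke <- kernelCross(X, X, 1.3)
  expect_equal(Ke, unclass(U), tolerance = 1e-10, ignore_attr = TRUE)
  # single test point equal to training point j
  Ke1 <- kernelCross(X[4, , drop = FALSE], X, 1.3)
  expect_equal(Ke1[1, 4], 1, tolerance = 1e-12)
  # brute-force oracle on a rectangular case
  Xt <- matrix(rnorm(9), 3, 3)
  Ke2 <- kernelCross(Xt, X, 0.8)
  for (i in 1:3) for (j in 1:6)
    expect_equal(Ke2[i, j], exp(-sum((Xt[i, ] - X[j, ])^2) / (2 * 0.8^2)),
                 tolerance = 1e-12)
  expect_error(kernelCross(matrix(0, 2, 2), X, 1), "dimension")
})

test_that("buildGraph composes a valid AffinityGraph and exports edges", {
  set.seed(71)
  X <- matrix(rnorm(40), 20, 2)
  g <- buildGraph(X, sparsifier = "knn", k = 3)
  expect_true(validObject(g))
  expect_s4_class(g, "AffinityGraph")
  expect_equal(laplacianMatrix(g),
               graphLaplacian(edgeWeightMatrix(g))$L)
  tmp <- tempfile(fileext = ".tsv")
  writeEdgeList(g, tmp)
  el <- read.table(tmp, header = TRUE, sep = "\t")
  expect_equal(nrow(el), sum(adjacency(g)) / 2)
  expect_true(all(el$i >= 0 & el$j > el$i))  # 0-based, upper triangle
  expect_equal(el$weight,
               edgeWeightMatrix(g)[cbind(el$i + 1, el$j + 1)])
  # b-matching provenance recorded
  gb <- buildGraph(X[1:8, ], sparsifier = "bmatch", b = 2)
  expect_equal(gb@sparsifier$solver, "exact")
})
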