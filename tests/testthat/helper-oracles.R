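# Independent reference implementations used as test oracles. These are
# deliberately written as naive scalar loops / exhaustive enumerations,
# separate from the vectorized package code paths they check.

# per-pair Gaussian kernel
oracle_gaussian <- function(X, sigma) {
  n <- nrow(X)
  U <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    U[i, j] <- exp(-sum((X[i, ] - X[j, ])^2) / (2 * sigma^2))
  U
}

# Laplacian quadratic form via the explicit double sum
oracle_quadform <- function(W, Fmat) {
  n <- nrow(W)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    s <- s + W[i, j] * sum((Fmat[i, ] - Fmat[j, ])^2)
  s / 2
}

# exhaustive minimum-weight b-matching by recursion over node slots;
# independent of the package's branch-and-bound edge search
oracle_bmatch <- function(H, b) {
  n <- nrow(H)
  best <- list(cost = Inf, B = NULL)
  B <- matrix(0L, n, n)
  deg <- integer(n)
  recurse <- function(i, j, cost) {
    if (cost >= best$cost) return(invisible(NULL))
    if (i > n) {
      if (all(deg == b)) best <<- list(cost = cost, B = B + 0)
      return(invisible(NULL))
    }
    if (j > n) {
      if (deg[i] != b) return(invisible(NULL))
      recurse(i + 1L, i + 2L, cost)
      return(invisible(NULL))
    }
    # option: no edge (i, j)
    recurse(i, j + 1L, cost)
    # option: edge (i, j)
    if (deg[i] < b && deg[j] < b) {
      B[i, j] <<- B[j, i] <<- 1L
      deg[i] <<- deg[i] + 1L
      deg[j] <<- deg[j] + 1L
      recurse(i, j + 1L, cost + H[i, j])
      B[i, j] <<- B[j, i] <<- 0L
      deg[i] <<- deg[i] - 1L
      deg[j] <<- deg[j] - 1L
    }
  }
  recurse(1L, 2L, 0)
  best
}

# scalar-loop multi-label average precision
oracle_avgprec <- function(S, Y) {
  n <- nrow(S)
  L <- ncol(S)
  vals <- c()
  for (i in seq_len(n)) {
    rel <- which(Y[i, ] == 1)
    if (length(rel) == 0) next
    rk <- integer(L)
    rk[order(-S[i, ], seq_len(L))] <- seq_len(L)
    acc <- 0
    for (j in rel) {
      cnt <- 0
      for (j2 in rel) if (rk[j2] <= rk[j]) cnt <- cnt + 1
      acc <- acc + cnt / rk[j]
    }
    vals <- c(vals, acc / length(rel))
  }
  mean(vals)
}

# scalar-loop confusion counts and F1s
oracle_f1 <- function(Ypred, Ytrue) {
  L <- ncol(Ytrue)
  tp <- fp <- fn <- numeric(L)
  for (l in seq_len(L)) for (i in seq_len(nrow(Ytrue))) {
    if (Ypred[i, l] == 1 && Ytrue[i, l] == 1) tp[l] <- tp[l] + 1
    if (Ypred[i, l] == 1 && Ytrue[i, l] == -1) fp[l] <- fp[l] + 1
    if (Ypred[i, l] == -1 && Ytrue[i, l] == 1) fn[l] <- fn[l] + 1
  }
  f1 <- function(tp, fp, fn) if (2 * tp + fp + fn == 0) 0
    else 2 * tp / (2 * tp + fp + fn)
  micro <- f1(sum(tp), sum(fp), sum(fn))
  macro <- mean(mapply(f1, tp, fp, fn))
  list(micro = micro, macro = macro)
}

# direct numerical minimization of the penalized multi-label objective
# over Theta (unweighted kernel expansion F = K Theta), by L-BFGS-B with
# the analytic gradient
oracle_minimize <- function(K, L_lap, Y, gammaA, gammaI, start = NULL,
                            maxit = 2000) {
  mask <- buildPsi(Y)
  ord <- mask$order
  Ko <- K[ord, ord]
  Lo <- L_lap[ord, ord]
  Yo <- Y[ord, , drop = FALSE]
  n <- nrow(Ko)
  L <- ncol(Yo)
  l <- mask$l
  psi <- mask$psi
  fn <- function(par) {
    Theta <- matrix(par, n, L)
    Fm <- Ko %*% Theta
    R <- psi * Fm - Yo
    sum(R^2) / l + gammaA * sum(Theta * (Ko %*% Theta)) +
      gammaI / n^2 * sum(Fm * (Lo %*% Fm))
  }
  gr <- function(par) {
    Theta <- matrix(par, n, L)
    Fm <- Ko %*% Theta
    R <- psi * Fm - Yo
    G <- 2 / l * (Ko %*% (psi * R)) + 2 * gammaA * (Ko %*% Theta) +
      2 * gammaI / n^2 * (Ko %*% (Lo %*% Fm))
    as.numeric(G)
  }
  if (is.null(start)) start <- rep(0, n * L)
  opt <- optim(start, fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 10))
  list(value = opt$value, theta = matrix(opt$par, n, L)[order(ord), ,
                                                        drop = FALSE],
       objective = fn, mask = mask)
}

# objective value of a coefficient matrix in caller order
objective_of_theta <- function(theta, K, L_lap, Y, gammaA, gammaI) {
  mask <- buildPsi(Y)
  Fm <- K %*% theta
  mlmrObjective(Fm[mask$order, , drop = FALSE],
                Y[mask$order, , drop = FALSE], mask,
                L_lap[mask$order, mask$order], gammaA, gammaI,
                fNormSq = sum(theta * (K %*% theta)))
}

# random symmetric non-negative weight matrix with zero diagonal
random_weights <- function(n) {
  W <- matrix(runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# random symmetric distance matrix with zero diagonal (triangle inequality
# not required by any of the sparsifiers)
random_distances <- function(n) {
  H <- matrix(runif(n * n, 0.05, 1), n, n)
  H <- (H + t(H)) / 2
  diag(H) <- 0
  H
}
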