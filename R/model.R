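#' Label-visibility mask
#'
#' Identifies labeled instances (rows of Y with at least one nonzero
#' entry), builds the internal labeled-first ordering that the closed-form
#' solver assumes, and the diagonal selector matrix with ones on the first
#' l internal positions.
#'
#' @param Y n x L label matrix; all-zero rows are unlabeled.
#' @return List with \code{order} (permutation putting labeled instances
#'   first), \code{inverse} (undoes it), \code{labeled} (original indices),
#'   \code{l}, \code{u}, \code{n}, and \code{psi} (the length-n 0/1
#'   diagonal in internal order).
#' @export
buildPsi <- function(Y) {
  Y <- as.matrix(Y)
  lab <- which(rowSums(Y != 0) > 0)
  if (length(lab) == 0) stop("no labeled instances (all label rows are zero)")
  n <- nrow(Y)
  ord <- c(lab, setdiff(seq_len(n), lab))
  inv <- order(ord)
  l <- length(lab)
  list(order = ord, inverse = inv, labeled = lab,
       l = l, u = n - l, n = n,
       psi = c(rep(1, l), rep(0, n - l)))
}

#' Uniform reliance weights
#'
#' Diagonal weights multiplying the kernel columns: labeled training
#' instances get \code{nu1}, unlabeled ones \code{nu2}. \code{nu1 = nu2}
#' recovers the unweighted model; \code{nu2 = 0} ignores unlabeled
#' instances at prediction time (the supervised limit). Weights must be
#' non-negative so the weighted kernel stays positive semi-definite.
#'
#' @param mask a mask from [buildPsi()].
#' @param nu1 weight on labeled instances, in \code{[0, 1]}.
#' @param nu2 weight on unlabeled instances, in \code{[0, 1]}.
#' @return Length-n vector (internal labeled-first order).
#' @export
relianceWeights <- function(mask, nu1 = 1, nu2 = 0.1) {
  if (nu1 < 0 || nu2 < 0)
    stop("reliance weights must be non-negative")
  c(rep(nu1, mask$l), rep(nu2, mask$u))
}

#' Regularized multi-label objective value
#'
#' Evaluates the penalized least-squares objective
#' \deqn{(1/l)\,\mathrm{tr}((\Psi F - Y)^T(\Psi F - Y)) + \gamma_A \|f\|_K^2
#'   + (\gamma_I/n^2)\,\mathrm{tr}(F^T L F)}
#' for a candidate score matrix. Intended as a reference quantity for
#' verifying the closed-form solver against direct numerical minimization.
#'
#' @param Fmat n x L score matrix (internal labeled-first order).
#' @param Y n x L label matrix (internal order, zero rows unlabeled).
#' @param mask mask from [buildPsi()] (already in internal order).
#' @param L_lap graph Laplacian (internal order).
#' @param gammaA,gammaI regularization coefficients.
#' @param fNormSq the RKHS norm term \eqn{\|f\|_K^2}; for a kernel
#'   expansion F = K Theta this is \eqn{\mathrm{tr}(\Theta^T K \Theta)}.
#' @return Scalar objective value.
#' @export
mlmrObjective <- function(Fmat, Y, mask, L_lap, gammaA, gammaI, fNormSq) {
  R <- mask$psi * Fmat - Y  # Psi F - Y with diagonal Psi
  sum(R^2) / mask$l + gammaA * fNormSq +
    gammaI / mask$n^2 * sum(Fmat * (L_lap %*% Fmat))
}

#' Closed-form multi-label Laplacian RLS fit
#'
#' Solves for the kernel-expansion coefficient matrix of the
#' reliance-weighted multi-label manifold regularization model:
#' \deqn{(\Psi K \Xi + l\gamma_A I + (l\gamma_I/n^2)\, L K \Xi)\,\Theta = Y,}
#' where K is the training kernel, \eqn{\Xi} the diagonal reliance-weight
#' matrix, \eqn{\Psi} selects labeled rows, and L the graph Laplacian.
#' With \eqn{\Xi = I} this is the standard multi-label LapRLS solution.
#' The system is solved directly (no explicit inverse) and its reciprocal
#' condition number is reported.
#'
#' @param K n x n training kernel matrix (caller order).
#' @param L_lap n x n graph Laplacian (caller order).
#' @param Y n x L label matrix; all-zero rows unlabeled (caller order).
#' @param xi length-n non-negative reliance weights in *caller* order, or
#'   \code{NULL} to derive uniform weights from \code{nu1}/\code{nu2}.
#' @param gammaA ambient regularization, must be > 0 (uniqueness).
#' @param gammaI intrinsic regularization, >= 0.
#' @param nu1,nu2 uniform reliance weights used when \code{xi} is NULL.
#' @param rcondMin minimum acceptable reciprocal condition number.
#' @return List with \code{theta} (n x L, caller order), \code{xi}
#'   (caller order), \code{mask}, and \code{rcond}.
#' @export
mlmrFit <- function(K, L_lap, Y, xi = NULL, gammaA = 0.01, gammaI = 0.1,
                    nu1 = 1, nu2 = 1, rcondMin = 1e-14) {
  K <- as.matrix(K)
  Y <- as.matrix(Y)
  n <- nrow(K)
  if (nrow(Y) != n || nrow(L_lap) != n) stop("dimension mismatch")
  if (!is.numeric(gammaA) || gammaA <= 0)
    stop("gammaA must be strictly positive")
  if (gammaI < 0) stop("gammaI must be non-negative")
  mask <- buildPsi(Y)
  ord <- mask$order
  if (is.null(xi)) {
    xiInt <- relianceWeights(mask, nu1, nu2)
  } else {
    if (length(xi) != n) stop("xi must have one entry per instance")
    if (any(xi < 0)) stop("reliance weights must be non-negative")
    xiInt <- xi[ord]
  }
  Ko <- K[ord, ord]
  Lo <- L_lap[ord, ord]
  Yo <- Y[ord, , drop = FALSE]
  l <- mask$l
  KXi <- sweep(Ko, 2, xiInt, "*")
  A <- mask$psi * KXi + diag(l * gammaA, n) +
    (l * gammaI / n^2) * (Lo %*% KXi)
  rc <- rcond(A)
  if (rc < rcondMin)
    stop(sprintf("linear system is numerically singular (rcond = %.3e)", rc))
  thetaInt <- solve(A, Yo)
  list(theta = thetaInt[mask$inverse, , drop = FALSE],
       xi = if (is.null(xi)) xiInt[mask$inverse] else xi,
       mask = mask, rcond = rc)
}

#' Fit a manifold-regularization model from features
#'
#' End-to-end pipeline: builds the Gaussian kernel and affinity graph from
#' the features (the kernel doubles as the training kernel K), then solves
#' the closed-form system of [mlmrFit()]. \code{nu1 = nu2 = 1} gives the
#' plain multi-label manifold regularization model (ML-MR); the default
#' \code{nu = [1, 0.1]} gives the reliance-weighted variant (ML-MRRW).
#'
#' @param X n x d training features, or a [MultiLabelSet-class] (in which
#'   case \code{Y} is taken from it).
#' @param Y n x L label matrix with all-zero rows for unlabeled instances.
#' @param sigma Gaussian bandwidth (\code{NULL} = median heuristic).
#' @param gammaA,gammaI regularization coefficients.
#' @param nu1,nu2 uniform reliance weights.
#' @param sparsifier,k,b,eps,epsMode,weightScheme graph options, see
#'   [buildGraph()].
#' @param graph optionally a prebuilt [AffinityGraph-class] for \code{X}.
#' @return A [ManifoldModel-class] object.
#' @examples
#' set.seed(1)
#' d <- generateMultiLabel(n = 60, d = 5, L = 3, C = 3, seed = 1)
#' Yp <- maskLabels(labelMatrix(d), eta = 0.3, seed = 2)$Y
#' fit <- mlmr(features(d), Yp, nu1 = 1, nu2 = 0.1)
#' fit
#' @export
mlmr <- function(X, Y = NULL, sigma = NULL, gammaA = 0.01, gammaI = 0.1,
                 nu1 = 1, nu2 = 0.1,
                 sparsifier = c("knn", "bmatch", "eps"),
                 k = 10, b = NULL, eps = NULL,
                 epsMode = c("conventional", "as_printed"),
                 weightScheme = c("distance", "similarity"),
                 graph = NULL) {
  if (is(X, "MultiLabelSet")) {
    if (is.null(Y)) Y <- labelMatrix(X)
    X <- features(X)
  }
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.null(graph)) {
    graph <- buildGraph(X, sigma = sigma, sparsifier = sparsifier, k = k,
                        b = b, eps = eps, epsMode = epsMode,
                        weightScheme = weightScheme)
  }
  fit <- mlmrFit(kernelMatrix(graph), laplacianMatrix(graph), Y,
                 gammaA = gammaA, gammaI = gammaI, nu1 = nu1, nu2 = nu2)
  ln <- colnames(Y)
  if (is.null(ln)) ln <- paste0("label", seq_len(ncol(Y)))
  new("ManifoldModel", theta = fit$theta, xi = fit$xi, Xtrain = X,
      sigma = graph@sigma, gammaA = gammaA, gammaI = gammaI,
      nu1 = nu1, nu2 = nu2, labeled = as.integer(fit$mask$labeled),
      labelNames = ln, rcond = fit$rcond)
}

#' Predict decision scores for new instances
#'
#' Inductive prediction: the e x n cross kernel between test and training
#' instances is weighted by the reliance diagonal and multiplied by the
#' fitted coefficients, \eqn{\tilde F = K_e\,\Xi\,\Theta^*}.
#'
#' @param model a [ManifoldModel-class].
#' @param Xtest e x d feature matrix.
#' @return e x L matrix of real-valued scores.
#' @export
predictScores <- function(model, Xtest) {
  Xtest <- as.matrix(Xtest)
  if (ncol(Xtest) != ncol(model@Xtrain))
    stop("feature dimension mismatch with training data")
  Ke <- kernelCross(Xtest, model@Xtrain, model@sigma)
  S <- sweep(Ke, 2, model@xi, "*") %*% model@theta
  colnames(S) <- model@labelNames
  S
}

#' Threshold scores into labels
#'
#' @param S score matrix.
#' @return Matrix in \{-1, +1\}: +1 where the score is strictly positive,
#'   -1 otherwise (a score of exactly 0 maps to -1, the conservative
#'   absent-label convention).
#' @export
thresholdLabels <- function(S) {
  S <- as.matrix(S)
  if (any(!is.finite(S))) stop("scores must be finite")
  ifelse(S > 0, 1, -1) * 1
}

#' @describeIn predictScores predict method; \code{type = "label"}
#'   thresholds the scores at 0.
#' @param object a [ManifoldModel-class].
#' @param newdata e x d feature matrix.
#' @param type \code{"score"} or \code{"label"}.
#' @param ... unused.
#' @export
setMethod("predict", "ManifoldModel",
  function(object, newdata, type = c("score", "label"), ...) {
    type <- match.arg(type)
    S <- predictScores(object, newdata)
    if (type == "label") thresholdLabels(S) else S
  })

#' Serialize a fitted model to a JSON archive
#'
#' Writes a format-versioned plain-text archive with the coefficients,
#' reliance diagonal, training features and hyperparameters, sufficient to
#' restore the model with [readModel()].
#'
#' @param model a [ManifoldModel-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(
    format = "mlmr-model", version = 1L,
    theta = model@theta, xi = model@xi, Xtrain = model@Xtrain,
    sigma = model@sigma, gammaA = model@gammaA, gammaI = model@gammaI,
    nu1 = model@nu1, nu2 = model@nu2, labeled = model@labeled,
    labelNames = model@labelNames, rcond = model@rcond
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Restore a model written by [writeModel()]
#'
#' @param path archive path.
#' @return A [ManifoldModel-class].
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mlmr-model"))
    stop("not an mlmr model archive: ", path)
  new("ManifoldModel", theta = as.matrix(obj$theta), xi = as.numeric(obj$xi),
      Xtrain = as.matrix(obj$Xtrain), sigma = obj$sigma,
      gammaA = obj$gammaA, gammaI = obj$gammaI, nu1 = obj$nu1,
      nu2 = obj$nu2, labeled = as.integer(obj$labeled),
      labelNames = as.character(obj$labelNames), rcond = obj$rcond)
}
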