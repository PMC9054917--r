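#' Gaussian kernel matrix
#'
#' Computes the n x n Gaussian (heat) kernel matrix
#' \deqn{U_{ij} = \exp(-\|x_i - x_j\|^2 / (2\sigma^2)),}
#' the similarity measure from which the affinity graph is built and which
#' also serves as the positive semi-definite training kernel K of the
#' manifold-regularization model.
#'
#' @param X numeric matrix, n instances x d features.
#' @param sigma positive bandwidth, in feature-space distance units. If
#'   \code{NULL}, the median of the pairwise Euclidean distances is used.
#' @return Symmetric n x n matrix with unit diagonal and entries in (0, 1].
#'   The bandwidth actually used is attached as attribute \code{"sigma"}.
#' @examples
#' U <- gaussianKernel(matrix(rnorm(15), 5, 3), sigma = 1)
#' diag(U)  # all 1
#' @export
gaussianKernel <- function(X, sigma = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 instances")
  if (anyNA(X) || any(!is.finite(X))) stop("features must be finite, no NAs")
  sq <- as.matrix(dist(X))^2
  if (is.null(sigma)) sigma <- medianHeuristic(X)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  U <- exp(-sq / (2 * sigma^2))
  U <- (U + t(U)) / 2
  diag(U) <- 1
  dimnames(U) <- NULL
  attr(U, "sigma") <- sigma
  U
}

#' Median-distance bandwidth heuristic
#'
#' @param X numeric feature matrix.
#' @return The median pairwise Euclidean distance (positive; falls back to 1
#'   when all points coincide).
#' @export
medianHeuristic <- function(X) {
  m <- stats::median(dist(as.matrix(X)))
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Cross kernel matrix between test and training instances
#'
#' Evaluates the Gaussian kernel between every test instance and every
#' training instance, giving the e x n matrix used for inductive,
#' out-of-sample prediction.
#'
#' @param Xtest e x d matrix of test features.
#' @param Xtrain n x d matrix of training features.
#' @param sigma positive bandwidth (same value used at training time).
#' @return e x n matrix with entry (i, j) = K(xtest_i, xtrain_j).
#' @export
kernelCross <- function(Xtest, Xtrain, sigma) {
  Xtest <- as.matrix(Xtest)
  Xtrain <- as.matrix(Xtrain)
  if (ncol(Xtest) != ncol(Xtrain)) stop("feature dimension mismatch")
  if (anyNA(Xtest) || anyNA(Xtrain)) stop("features must not contain NAs")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    stop("sigma must be a single positive number")
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clamped against roundoff
  sq <- outer(rowSums(Xtest^2), rowSums(Xtrain^2), "+") -
    2 * tcrossprod(Xtest, Xtrain)
  sq[sq < 0] <- 0
  exp(-sq / (2 * sigma^2))
}

#' Kernel-induced distance matrix
#'
#' Converts a kernel (similarity) matrix into the distance matrix
#' \eqn{H_{ij} = \sqrt{U_{ii} + U_{jj} - 2U_{ij}}}; for a Gaussian kernel
#' with unit diagonal this is \eqn{\sqrt{2 - 2U_{ij}} \in [0, \sqrt 2]}.
#'
#' @param U symmetric kernel matrix with unit diagonal.
#' @return Symmetric non-negative matrix H with zero diagonal. Negative
#'   radicands (possible for non-PSD input) are clamped to 0 with a warning.
#' @export
kernelToDistance <- function(U) {
  U <- as.matrix(U)
  if (!.is_symmetric(U)) stop("U must be symmetric")
  rad <- outer(diag(U), diag(U), "+") - 2 * U
  if (any(rad < -1e-10))
    warning("negative radicand in kernel-to-distance conversion; clamped to 0")
  rad[rad < 0] <- 0
  H <- sqrt(rad)
  diag(H) <- 0
  (H + t(H)) / 2
}

#' Epsilon-neighborhood sparsifier
#'
#' Thresholds the distance matrix into a binary adjacency. Two modes are
#' provided: \code{"conventional"} keeps an edge when the distance is small
#' (\eqn{H_{ij} \le \varepsilon}); \code{"as_printed"} keeps an edge when
#' \eqn{1 - H_{ij} \le \varepsilon}, i.e. when the distance is LARGE. The
#' second mode reproduces a published rule verbatim even though it inverts
#' the usual epsilon-neighborhood intent; see the package vignette.
#'
#' @param H symmetric distance matrix.
#' @param eps threshold; in \code{[0, 1]} for \code{"as_printed"}.
#' @param mode \code{"conventional"} (default) or \code{"as_printed"}.
#' @return Binary symmetric adjacency matrix with zero diagonal.
#' @export
sparsifyEps <- function(H, eps, mode = c("conventional", "as_printed")) {
  mode <- match.arg(mode)
  H <- as.matrix(H)
  if (!is.numeric(eps) || length(eps) != 1) stop("eps must be a single number")
  if (mode == "as_printed" && (eps < 0 || eps > 1))
    stop("eps must lie in [0, 1] for as_printed mode")
  B <- if (mode == "as_printed") (1 - H <= eps) else (H <= eps)
  B <- B * 1
  diag(B) <- 0
  B
}

#' k-nearest-neighbor sparsifier
#'
#' Row-wise selection of each instance's k nearest neighbors by distance,
#' followed by symmetrization \eqn{B_{ij} \leftarrow \max(B_{ij}, B_{ji})}.
#' Distance ties are broken deterministically toward the smaller instance
#' index.
#'
#' @param H symmetric distance matrix.
#' @param k neighbors per row, \code{1 <= k < n}.
#' @param symmetrize apply the max-merge (default \code{TRUE}); with
#'   \code{FALSE} the raw row-wise selection (row sums exactly k) is
#'   returned.
#' @return Binary adjacency with zero diagonal; symmetric when
#'   \code{symmetrize = TRUE}.
#' @export
sparsifyKnn <- function(H, k, symmetrize = TRUE) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k >= n)
    stop("k must satisfy 1 <= k < n")
  k <- as.integer(k)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- H[i, ]
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]  # ties -> smaller index first
    B[i, nb] <- 1
  }
  if (symmetrize) B <- pmax(B, t(B))
  B
}

#' b-matching sparsifier
#'
#' Finds a binary symmetric adjacency with zero diagonal in which every
#' node has exactly b neighbors, minimizing the total edge distance
#' \eqn{\sum_{ij} B_{ij} H_{ij}}. Unlike kNN-with-symmetrization, the
#' degree constraint holds exactly. Solved exactly by branch-and-bound for
#' small problems and by a deterministic greedy-with-repair heuristic above
#' \code{exactMax} nodes.
#'
#' @param H symmetric distance matrix.
#' @param b target degree, \code{1 <= b < n}; \code{n * b} must be even.
#' @param exactMax largest n for which the exact solver is used
#'   (default 10).
#' @return Binary symmetric adjacency with every row summing to b. The
#'   attribute \code{"solver"} records \code{"exact"} (optimality
#'   guaranteed) or \code{"greedy"}.
#' @export
sparsifyBMatch <- function(H, b, exactMax = 10) {
  H <- as.matrix(H)
  n <- nrow(H)
  if (!is.numeric(b) || length(b) != 1 || b < 1 || b >= n)
    stop("b must satisfy 1 <= b < n")
  b <- as.integer(b)
  if ((n * b) %% 2 != 0)
    stop("infeasible b-matching: n * b must be even")
  B <- if (n <= exactMax) .bmatchExact(H, b) else .bmatchGreedy(H, b)
  attr(B, "solver") <- if (n <= exactMax) "exact" else "greedy"
  B
}

# Exact minimum-weight b-matching by depth-first branch-and-bound over the
# edge list sorted by weight. Residual-degree feasibility pruning plus a
# simple lower bound keep n <= 10 instances fast.
.bmatchExact <- function(H, b) {
  n <- nrow(H)
  edges <- which(upper.tri(H), arr.ind = TRUE)
  w <- H[edges]
  o <- order(w, edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  w <- w[o]
  m <- nrow(edges)
  best <- list(cost = Inf, sel = NULL)
  # suffix count of edges incident to each node, for feasibility pruning
  incid <- matrix(0L, m + 1, n)
  for (e in m:1) {
    incid[e, ] <- incid[e + 1, ]
    incid[e, edges[e, 1]] <- incid[e, edges[e, 1]] + 1L
    incid[e, edges[e, 2]] <- incid[e, edges[e, 2]] + 1L
  }
  recurse <- function(e, deg, cost, sel) {
    if (cost >= best$cost) return(invisible(NULL))
    if (all(deg == b)) {
      best <<- list(cost = cost, sel = sel)
      return(invisible(NULL))
    }
    if (e > m) return(invisible(NULL))
    need <- b - deg
    if (any(need > incid[e, ])) return(invisible(NULL))
    # lower bound: half the remaining required degree times the cheapest
    # remaining edge weight
    lb <- cost + sum(need) / 2 * w[e]
    if (lb >= best$cost) return(invisible(NULL))
    i <- edges[e, 1]; j <- edges[e, 2]
    if (deg[i] < b && deg[j] < b) {
      deg2 <- deg
      deg2[i] <- deg2[i] + 1L
      deg2[j] <- deg2[j] + 1L
      recurse(e + 1L, deg2, cost + w[e], c(sel, e))
    }
    recurse(e + 1L, deg, cost, sel)
  }
  recurse(1L, integer(n), 0, integer(0))
  if (!is.finite(best$cost)) stop("infeasible b-matching instance")
  B <- matrix(0, n, n)
  for (e in best$sel) {
    B[edges[e, 1], edges[e, 2]] <- 1
    B[edges[e, 2], edges[e, 1]] <- 1
  }
  B
}

# Deterministic greedy-with-repair heuristic: take edges in increasing
# weight while both endpoints have residual degree, then repair remaining
# deficiencies by direct edges or 2-swaps.
.bmatchGreedy <- function(H, b) {
  n <- nrow(H)
  edges <- which(upper.tri(H), arr.ind = TRUE)
  w <- H[edges]
  o <- order(w, edges[, 1], edges[, 2])
  edges <- edges[o, , drop = FALSE]
  B <- matrix(0, n, n)
  deg <- integer(n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    if (deg[i] < b && deg[j] < b) {
      B[i, j] <- B[j, i] <- 1
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  # repair: greedy can leave nodes short when all their cheap partners are
  # saturated
  guard <- 0L
  while (any(deg < b) && guard < 10L * n * b) {
    guard <- guard + 1L
    short <- which(deg < b)
    u <- short[1]
    v <- short[short != u & B[u, short] == 0][1]
    if (!is.na(v)) {
      B[u, v] <- B[v, u] <- 1
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
      next
    }
    # single deficient node (or all deficient partners already adjacent):
    # break an existing edge (a, c) with a, c distinct from u and not yet
    # adjacent to u, then add (u, a) and (u, c)
    v <- if (length(short) > 1) short[2] else u
    done <- FALSE
    cand <- which(upper.tri(B) & B == 1, arr.ind = TRUE)
    for (r in seq_len(nrow(cand))) {
      a <- cand[r, 1]; cc <- cand[r, 2]
      if (u == v) {
        if (a != u && cc != u && B[u, a] == 0 && B[u, cc] == 0) {
          B[a, cc] <- B[cc, a] <- 0
          B[u, a] <- B[a, u] <- 1
          B[u, cc] <- B[cc, u] <- 1
          deg[u] <- deg[u] + 2L
          done <- TRUE
          break
        }
      } else {
        if (!(a %in% c(u, v)) && !(cc %in% c(u, v)) &&
            B[u, a] == 0 && B[v, cc] == 0) {
          B[a, cc] <- B[cc, a] <- 0
          B[u, a] <- B[a, u] <- 1
          B[v, cc] <- B[cc, v] <- 1
          deg[u] <- deg[u] + 1L
          deg[v] <- deg[v] + 1L
          done <- TRUE
          break
        }
      }
    }
    if (!done) stop("b-matching repair failed; instance may be infeasible")
  }
  if (any(deg != b)) stop("b-matching heuristic failed to meet degree b")
  B
}

#' Edge weights from a finalized adjacency
#'
#' Assigns weights to the retained edges. The \code{"distance"} scheme sets
#' \eqn{W_{ij} = H_{ij} B_{ij}} (the source formulation, which weights an
#' edge by its length); the \code{"similarity"} scheme sets
#' \eqn{W_{ij} = U_{ij} B_{ij}}, the standard kernel-weighted graph.
#'
#' @param H distance matrix.
#' @param U kernel matrix.
#' @param B finalized binary symmetric adjacency.
#' @param scheme \code{"distance"} (default) or \code{"similarity"}.
#' @return Symmetric non-negative weight matrix with zero diagonal.
#' @export
edgeWeights <- function(H, U, B, scheme = c("distance", "similarity")) {
  scheme <- match.arg(scheme)
  B <- as.matrix(B)
  if (!.is_symmetric(B)) stop("B must be finalized (symmetric)")
  W <- if (scheme == "distance") as.matrix(H) * B else as.matrix(U) * B
  diag(W) <- 0
  W
}

#' Unnormalized graph Laplacian
#'
#' @param W symmetric non-negative weight matrix with zero diagonal.
#' @return List with the diagonal degree matrix \code{D}
#'   (\eqn{D_{ii} = \sum_j W_{ij}}) and the Laplacian \code{L = D - W}.
#' @export
graphLaplacian <- function(W) {
  W <- as.matrix(W)
  if (!.is_symmetric(W)) stop("W must be symmetric")
  if (any(W < 0)) stop("W must be non-negative")
  D <- diag(rowSums(W), nrow(W))
  list(D = D, L = D - W)
}

#' Build the full affinity graph
#'
#' Convenience composition: Gaussian kernel, kernel-induced distance,
#' sparsification, edge weighting and Laplacian, returned as an
#' [AffinityGraph-class] object.
#'
#' @param X feature matrix.
#' @param sigma Gaussian bandwidth (\code{NULL} = median heuristic).
#' @param sparsifier \code{"knn"} (default), \code{"bmatch"} or \code{"eps"}.
#' @param k,b,eps sparsifier parameters (k defaults to 10).
#' @param epsMode epsilon mode, see [sparsifyEps()].
#' @param weightScheme see [edgeWeights()].
#' @param exactMax exact-solver size cap for b-matching.
#' @return An [AffinityGraph-class].
#' @examples
#' g <- buildGraph(matrix(rnorm(60), 20, 3), sparsifier = "knn", k = 3)
#' g
#' @export
buildGraph <- function(X, sigma = NULL,
                       sparsifier = c("knn", "bmatch", "eps"),
                       k = 10, b = NULL, eps = NULL,
                       epsMode = c("conventional", "as_printed"),
                       weightScheme = c("distance", "similarity"),
                       exactMax = 10) {
  sparsifier <- match.arg(sparsifier)
  epsMode <- match.arg(epsMode)
  weightScheme <- match.arg(weightScheme)
  U <- gaussianKernel(X, sigma)
  sigma <- attr(U, "sigma")
  attr(U, "sigma") <- NULL
  H <- kernelToDistance(U)
  prov <- list(method = sparsifier)
  if (sparsifier == "knn") {
    k <- min(k, nrow(U) - 1)
    B <- sparsifyKnn(H, k)
    prov$k <- k
  } else if (sparsifier == "bmatch") {
    if (is.null(b)) stop("b must be supplied for the bmatch sparsifier")
    B <- sparsifyBMatch(H, b, exactMax)
    prov$b <- b
    prov$solver <- attr(B, "solver")
    attr(B, "solver") <- NULL
  } else {
    if (is.null(eps)) stop("eps must be supplied for the eps sparsifier")
    B <- sparsifyEps(H, eps, epsMode)
    prov$eps <- eps
    prov$mode <- epsMode
  }
  W <- edgeWeights(H, U, B, weightScheme)
  lap <- graphLaplacian(W)
  new("AffinityGraph", kernel = U, dist = H, adjacency = B, weights = W,
      degree = lap$D, laplacian = lap$L, sigma = sigma,
      sparsifier = prov, weightScheme = weightScheme)
}

#' Export a graph as an edge-list TSV
#'
#' Writes one row per undirected edge with 0-based node indices and the
#' edge weight, for inspection in external tools.
#'
#' @param graph an [AffinityGraph-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeEdgeList <- function(graph, path) {
  W <- edgeWeightMatrix(graph)
  B <- adjacency(graph)
  idx <- which(upper.tri(B) & B == 1, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1] - 1L, j = idx[, 2] - 1L,
                   weight = W[idx])
  df <- df[order(df$i, df$j), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
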