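#' @import methods
#' @importFrom stats qchisq qnorm rnorm runif dist optim rbinom
#' @importFrom utils read.table write.table modifyList
NULL

.is_symmetric <- function(M, tol = 1e-8) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

#' Multi-label data set
#'
#' Container for an instance-by-feature matrix paired with an
#' instance-by-label matrix. Label entries are coded \code{+1} (label
#' present), \code{-1} (label absent) and \code{0}; an all-zero label row
#' marks an unlabeled instance, the convention used throughout the
#' semi-supervised fitting routines.
#'
#' @slot features numeric matrix, n instances x d features.
#' @slot labels numeric matrix, n instances x L labels, entries in
#'   \{-1, 0, +1\}.
#' @slot labelNames character vector of unique label names.
#' @slot instanceIds character vector of instance identifiers.
#' @slot metadata list of provenance information (generator config, file
#'   paths, seeds).
#'
#' @seealso [multiLabelSet()], [generateMultiLabel()], [readMultiLabel()]
#' @export
setClass("MultiLabelSet",
  representation(
    features = "matrix",
    labels = "matrix",
    labelNames = "character",
    instanceIds = "character",
    metadata = "list"
  )
)

setValidity("MultiLabelSet", function(object) {
  msg <- character()
  if (nrow(object@features) != nrow(object@labels))
    msg <- c(msg, "features and labels must have the same number of rows")
  if (!all(object@labels %in% c(-1, 0, 1)))
    msg <- c(msg, "label entries must be in {-1, 0, +1}")
  if (length(object@labelNames) != ncol(object@labels))
    msg <- c(msg, "labelNames length must equal the number of label columns")
  if (anyDuplicated(object@labelNames))
    msg <- c(msg, "labelNames must be unique")
  if (length(object@instanceIds) != nrow(object@features))
    msg <- c(msg, "instanceIds length must equal the number of instances")
  if (anyNA(object@features) || any(!is.finite(object@features)))
    msg <- c(msg, "features must be finite and non-missing")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiLabelSet
#'
#' @param features numeric matrix (n x d) of instance features.
#' @param labels numeric matrix (n x L) with entries in \{-1, 0, +1\};
#'   all-zero rows mark unlabeled instances.
#' @param labelNames optional label names; defaults to the column names of
#'   \code{labels} or \code{label1..labelL}.
#' @param instanceIds optional instance identifiers.
#' @param metadata optional provenance list.
#' @return A [MultiLabelSet-class] object.
#' @examples
#' X <- matrix(rnorm(20), 10, 2)
#' Y <- matrix(sample(c(-1, 1), 30, TRUE), 10, 3)
#' mls <- multiLabelSet(X, Y)
#' mls
#' @export
multiLabelSet <- function(features, labels, labelNames = NULL,
                          instanceIds = NULL, metadata = list()) {
  features <- as.matrix(features)
  labels <- as.matrix(labels)
  if (is.null(labelNames)) {
    labelNames <- colnames(labels)
    if (is.null(labelNames)) labelNames <- paste0("label", seq_len(ncol(labels)))
  }
  if (is.null(instanceIds)) {
    instanceIds <- rownames(features)
    if (is.null(instanceIds)) instanceIds <- paste0("i", seq_len(nrow(features)))
  }
  colnames(labels) <- labelNames
  new("MultiLabelSet", features = features, labels = labels,
      labelNames = as.character(labelNames),
      instanceIds = as.character(instanceIds), metadata = metadata)
}

#' Affinity graph over instances
#'
#' Bundle of the matrices produced by graph construction: the Gaussian
#' kernel matrix U, the kernel-induced distance matrix H, the binary
#' adjacency B chosen by a sparsifier, the edge weight matrix W, the
#' diagonal degree matrix D and the unnormalized Laplacian L = D - W.
#'
#' @slot kernel symmetric kernel matrix U with unit diagonal.
#' @slot dist symmetric non-negative distance matrix H with zero diagonal.
#' @slot adjacency binary symmetric adjacency B with zero diagonal.
#' @slot weights symmetric non-negative weight matrix W.
#' @slot degree diagonal degree matrix D.
#' @slot laplacian unnormalized Laplacian L = D - W.
#' @slot sigma Gaussian kernel bandwidth used.
#' @slot sparsifier list describing the sparsifier (method, parameters,
#'   solver provenance for b-matching).
#' @slot weightScheme "distance" or "similarity".
#' @seealso [buildGraph()]
#' @export
setClass("AffinityGraph",
  representation(
    kernel = "matrix",
    dist = "matrix",
    adjacency = "matrix",
    weights = "matrix",
    degree = "matrix",
    laplacian = "matrix",
    sigma = "numeric",
    sparsifier = "list",
    weightScheme = "character"
  )
)

setValidity("AffinityGraph", function(object) {
  msg <- character()
  n <- nrow(object@kernel)
  for (s in c("kernel", "dist", "adjacency", "weights", "degree", "laplacian")) {
    M <- slot(object, s)
    if (!all(dim(M) == c(n, n))) msg <- c(msg, paste(s, "must be n x n"))
  }
  if (!.is_symmetric(object@adjacency)) msg <- c(msg, "adjacency must be symmetric")
  if (any(diag(object@adjacency) != 0)) msg <- c(msg, "adjacency diagonal must be 0")
  if (!all(object@adjacency %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
  if (!.is_symmetric(object@weights)) msg <- c(msg, "weights must be symmetric")
  if (max(abs(object@laplacian - (object@degree - object@weights))) > 1e-8)
    msg <- c(msg, "laplacian must equal degree - weights")
  if (max(abs(rowSums(object@laplacian))) > 1e-8)
    msg <- c(msg, "laplacian rows must sum to 0")
  if (length(msg)) msg else TRUE
})

#' Fitted manifold-regularization model
#'
#' Holds the kernel-expansion coefficients of a multi-label Laplacian
#' regularized least squares fit together with everything needed for
#' inductive prediction: the training features, the kernel bandwidth, the
#' diagonal reliance weights and the hyperparameters.
#'
#' @slot theta n x L coefficient matrix.
#' @slot xi length-n diagonal of the reliance weight matrix.
#' @slot Xtrain training feature matrix (n x d).
#' @slot sigma Gaussian kernel bandwidth.
#' @slot gammaA ambient-space regularization coefficient (> 0).
#' @slot gammaI intrinsic (graph-smoothness) coefficient (>= 0).
#' @slot nu1 reliance weight on labeled instances.
#' @slot nu2 reliance weight on unlabeled instances.
#' @slot labeled integer indices (in the caller's ordering) of labeled
#'   instances.
#' @slot labelNames label names carried through to predictions.
#' @slot rcond reciprocal condition estimate of the linear system solved.
#' @seealso [mlmrFit()], [mlmr()], [predictScores()]
#' @export
setClass("ManifoldModel",
  representation(
    theta = "matrix",
    xi = "numeric",
    Xtrain = "matrix",
    sigma = "numeric",
    gammaA = "numeric",
    gammaI = "numeric",
    nu1 = "numeric",
    nu2 = "numeric",
    labeled = "integer",
    labelNames = "character",
    rcond = "numeric"
  )
)

setValidity("ManifoldModel", function(object) {
  msg <- character()
  if (nrow(object@theta) != nrow(object@Xtrain))
    msg <- c(msg, "theta must have one row per training instance")
  if (length(object@xi) != nrow(object@theta))
    msg <- c(msg, "xi must have one entry per training instance")
  if (any(object@xi < 0)) msg <- c(msg, "reliance weights must be non-negative")
  if (any(!is.finite(object@theta))) msg <- c(msg, "theta must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("show", "MultiLabelSet", function(object) {
  Y <- object@labels
  unlab <- sum(rowSums(Y != 0) == 0)
  card <- if (nrow(Y) > unlab)
    mean(rowSums(Y[rowSums(Y != 0) > 0, , drop = FALSE] == 1)) else NA_real_
  cat("MultiLabelSet with", nrow(object@features), "instances,",
      ncol(object@features), "features,", ncol(Y), "labels\n")
  cat("  unlabeled instances:", unlab, "\n")
  if (!is.na(card)) cat("  mean label cardinality (labeled rows):",
                        format(card, digits = 4), "\n")
})

setMethod("show", "AffinityGraph", function(object) {
  B <- object@adjacency
  cat("AffinityGraph on", nrow(B), "instances\n")
  cat("  sparsifier:", object@sparsifier$method,
      "| edges:", sum(B) / 2,
      "| weight scheme:", object@weightScheme,
      "| sigma:", format(object@sigma, digits = 4), "\n")
})

setMethod("show", "ManifoldModel", function(object) {
  l <- length(object@labeled)
  n <- nrow(object@theta)
  variant <- if (isTRUE(all.equal(object@nu1, object@nu2))) "ML-MR" else "ML-MRRW"
  cat(variant, "manifold regularization model\n")
  cat("  n =", n, "( labeled:", l, ", unlabeled:", n - l, "), labels:",
      ncol(object@theta), "\n")
  cat("  sigma =", format(object@sigma, digits = 4),
      " gammaA =", object@gammaA, " gammaI =", object@gammaI,
      " nu = [", object@nu1, ",", object@nu2, "]\n")
  cat("  linear-system rcond:", format(object@rcond, digits = 3), "\n")
})

#' @describeIn MultiLabelSet-class number of instances
#' @param x,object a \code{MultiLabelSet}
#' @export
setMethod("nrow", "MultiLabelSet", function(x) nrow(x@features))

#' Accessors for MultiLabelSet and AffinityGraph slots
#'
#' @param x a [MultiLabelSet-class], [AffinityGraph-class] or
#'   [ManifoldModel-class] object.
#' @return The requested matrix or vector.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setMethod("features", "MultiLabelSet", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setMethod("labelMatrix", "MultiLabelSet", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))
#' @rdname accessors
#' @export
setMethod("labelNames", "MultiLabelSet", function(x) x@labelNames)

#' @rdname accessors
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))
#' @rdname accessors
#' @export
setMethod("kernelMatrix", "AffinityGraph", function(x) x@kernel)

#' @rdname accessors
#' @export
setGeneric("distMatrix", function(x) standardGeneric("distMatrix"))
#' @rdname accessors
#' @export
setMethod("distMatrix", "AffinityGraph", function(x) x@dist)

#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setMethod("adjacency", "AffinityGraph", function(x) x@adjacency)

#' @rdname accessors
#' @export
setGeneric("edgeWeightMatrix", function(x) standardGeneric("edgeWeightMatrix"))
#' @rdname accessors
#' @export
setMethod("edgeWeightMatrix", "AffinityGraph", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("laplacianMatrix", function(x) standardGeneric("laplacianMatrix"))
#' @rdname accessors
#' @export
setMethod("laplacianMatrix", "AffinityGraph", function(x) x@laplacian)

#' @rdname accessors
#' @export
setGeneric("coefMatrix", function(x) standardGeneric("coefMatrix"))
#' @rdname accessors
#' @export
setMethod("coefMatrix", "ManifoldModel", function(x) x@theta)

#' @rdname accessors
#' @export
setGeneric("relianceDiag", function(x) standardGeneric("relianceDiag"))
#' @rdname accessors
#' @export
setMethod("relianceDiag", "ManifoldModel", function(x) x@xi)

#' Subset a MultiLabelSet by instances
#'
#' @param x a \code{MultiLabelSet}
#' @param i integer or logical instance index
#' @param j unused
#' @param ... unused
#' @param drop unused
#' @export
setMethod("[", c("MultiLabelSet", "ANY", "missing", "ANY"),
  function(x, i, j, ..., drop = FALSE) {
    new("MultiLabelSet",
        features = x@features[i, , drop = FALSE],
        labels = x@labels[i, , drop = FALSE],
        labelNames = x@labelNames,
        instanceIds = x@instanceIds[i],
        metadata = x@metadata)
  })
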