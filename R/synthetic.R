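#' Generate cluster-structured multi-label data
#'
#' Draws instances from C well-separated isotropic Gaussian clusters and
#' attaches a fixed label subset to each cluster, so that instances close
#' in feature space share labels — exactly the smoothness assumption a
#' graph-based semi-supervised learner exploits. Label noise is injected
#' by flipping each label entry independently with a small probability.
#'
#' Cluster label subsets are chosen by chunking a shuffled, recycled label
#' sequence, which guarantees every label is carried by at least one
#' cluster whenever \code{C * labelsPerCluster >= L}.
#'
#' @param n number of instances.
#' @param d feature dimension.
#' @param L number of labels.
#' @param C number of latent clusters (>= 2).
#' @param clusterSpread isotropic within-cluster standard deviation.
#' @param centerSeparation minimum pairwise Euclidean distance between
#'   cluster centers (centers are rescaled to enforce it).
#' @param labelsPerCluster labels attached to each cluster (<= L).
#' @param labelFlipProb per-entry flip probability in \code{[0, 0.5)}.
#' @param seed RNG seed; same seed gives bit-identical output.
#' @return A [MultiLabelSet-class] with fully observed labels in
#'   \{-1, +1\} and a provenance record (full config, cluster assignment)
#'   in its metadata.
#' @examples
#' d <- generateMultiLabel(n = 100, d = 10, L = 5, C = 4, seed = 1)
#' d
#' @export
generateMultiLabel <- function(n, d, L, C = 10,
                               clusterSpread = 1,
                               centerSeparation = 8,
                               labelsPerCluster = min(4, L),
                               labelFlipProb = 0.05,
                               seed = 1) {
  if (C < 2) stop("need at least 2 clusters")
  if (labelsPerCluster > L) stop("labelsPerCluster must not exceed L")
  if (labelFlipProb < 0 || labelFlipProb >= 0.5)
    stop("labelFlipProb must lie in [0, 0.5)")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  centers <- matrix(rnorm(C * d), C, d)
  dd <- as.matrix(dist(centers))
  minsep <- min(dd[upper.tri(dd)])
  if (minsep <= 0) stop("degenerate cluster centers; choose another seed")
  centers <- centers * (centerSeparation / minsep)

  # recycled shuffled label sequence chunked into per-cluster subsets;
  # duplicates inside a chunk (possible at recycle boundaries) are
  # replaced by labels missing from that chunk
  reps <- ceiling(C * labelsPerCluster / L)
  seq_lab <- unlist(lapply(seq_len(reps), function(r) sample.int(L)))
  clusterLabels <- lapply(seq_len(C), function(c) {
    chunk <- seq_lab[((c - 1) * labelsPerCluster + 1):(c * labelsPerCluster)]
    dup <- duplicated(chunk)
    if (any(dup)) {
      pool <- setdiff(seq_len(L), chunk)
      chunk[dup] <- pool[seq_len(sum(dup))]
    }
    sort(chunk)
  })

  z <- sample.int(C, n, replace = TRUE)
  X <- centers[z, , drop = FALSE] +
    matrix(rnorm(n * d, sd = clusterSpread), n, d)
  Y <- matrix(-1, n, L)
  for (c in seq_len(C)) Y[z == c, clusterLabels[[c]]] <- 1
  if (labelFlipProb > 0) {
    flips <- matrix(rbinom(n * L, 1, labelFlipProb), n, L)
    Y <- Y * (1 - 2 * flips)
  }
  colnames(Y) <- paste0("label", seq_len(L))
  multiLabelSet(X, Y, metadata = list(
    generator = "cluster-gaussian",
    config = list(n = n, d = d, L = L, C = C,
                  clusterSpread = clusterSpread,
                  centerSeparation = centerSeparation,
                  labelsPerCluster = labelsPerCluster,
                  labelFlipProb = labelFlipProb, seed = seed),
    cluster = z, clusterLabels = clusterLabels))
}

#' Yeast-shaped synthetic data set
#'
#' Preset of [generateMultiLabel()] with the shape of the classic yeast
#' gene function annotation benchmark: 2417 instances, 103 features and 14
#' functional-category labels. All other knobs keep the generator
#' defaults.
#'
#' @param seed RNG seed.
#' @param n optionally override the instance count (e.g. for subsampled
#'   runs); shape defaults to the full 2417.
#' @return A [MultiLabelSet-class].
#' @export
yeastLike <- function(seed = 1, n = 2417) {
  generateMultiLabel(n = n, d = 103, L = 14, seed = seed)
}
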