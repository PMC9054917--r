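#' Train/test split of instance indices
#'
#' @param n number of instances (>= 3).
#' @param trainFraction fraction assigned to training (default 2/3).
#' @param seed RNG seed; identical seed gives an identical split.
#' @return List with disjoint, exhaustive \code{train} and \code{test}
#'   index vectors; \code{|train| = round(trainFraction * n)}.
#' @export
splitTrainTest <- function(n, trainFraction = 2 / 3, seed = 1) {
  if (n < 3) stop("need at least 3 instances to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  ntr <- round(trainFraction * n)
  if (ntr < 1 || ntr >= n) stop("degenerate split sizes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tr <- sort(sample.int(n, ntr))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

#' Mask labels at a given labeling rate
#'
#' Keeps the full label vectors of a random fraction eta of the training
#' instances and zeroes all others, producing the partially labeled matrix
#' consumed by the semi-supervised fit. At least one instance always stays
#' labeled.
#'
#' @param Y fully observed n x L label matrix in \{-1, +1\}.
#' @param eta labeling rate in (0, 1).
#' @param seed RNG seed.
#' @return List: \code{Y} (masked matrix), \code{labeled} (indices kept).
#' @export
maskLabels <- function(Y, eta, seed = 1) {
  Y <- as.matrix(Y)
  if (eta <= 0 || eta >= 1) stop("eta must lie in (0, 1)")
  n <- nrow(Y)
  l <- max(1L, round(eta * n))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  keep <- sort(sample.int(n, l))
  Ym <- matrix(0, n, ncol(Y))
  colnames(Ym) <- colnames(Y)
  Ym[keep, ] <- Y[keep, ]
  list(Y = Ym, labeled = keep)
}

# Deterministic per-cell seed derived from the master seed and the cell
# coordinates; kept below 2^31 - 1.
.cellSeed <- function(master, rep, rateIdx, algIdx) {
  as.integer((as.numeric(master) * 2654435761 + rep * 97003 +
                rateIdx * 10007 + algIdx * 101) %% 2147483647)
}

#' Built-in learners for the protocol
#'
#' \code{"ml-mr"} is the unweighted multi-label manifold regularization
#' model (nu1 = nu2 = 1); \code{"ml-mrrw"} is the reliance-weighted
#' variant with nu = [1, 0.1].
#'
#' @return Named list of learner configurations (nu1, nu2).
#' @export
protocolAlgorithms <- function() {
  list("ml-mr" = list(nu1 = 1, nu2 = 1),
       "ml-mrrw" = list(nu1 = 1, nu2 = 0.1))
}

#' Repeated-resampling evaluation protocol
#'
#' Reproduces the standard semi-supervised evaluation loop: for each
#' repetition and labeling rate, (optionally) subsample the data, split
#' into training (default two thirds) and held-out test third, mask the
#' training labels down to the labeling rate, fit each algorithm on the
#' partially labeled training data, predict on the held-out test set and
#' record average precision, micro-F1 and macro-F1. Every cell's RNG seed
#' is derived deterministically from \code{masterSeed}, so any cell can be
#' reproduced in isolation.
#'
#' @param X feature matrix or a [MultiLabelSet-class].
#' @param Y fully observed label matrix (ignored when X is a
#'   \code{MultiLabelSet}).
#' @param rates labeling rates (default \code{seq(0.05, 0.5, by = 0.05)}).
#' @param reps repetitions per rate (default 100).
#' @param trainFraction training fraction (default 2/3).
#' @param subsampleFraction fraction of instances drawn (with a fresh draw
#'   every repetition) before splitting; default 1 = use all.
#' @param algorithms named list of learner configs as in
#'   [protocolAlgorithms()], or a character vector naming a subset.
#' @param masterSeed master seed.
#' @param sigma,gammaA,gammaI,sparsifier,k model/graph settings passed to
#'   [mlmr()].
#' @return Data frame of records: repetition, labeling_rate, algorithm,
#'   metric, value, seed; failed cells carry NA values and a message
#'   attribute rather than aborting the run.
#' @export
runProtocol <- function(X, Y = NULL,
                        rates = seq(0.05, 0.5, by = 0.05),
                        reps = 100,
                        trainFraction = 2 / 3,
                        subsampleFraction = 1,
                        algorithms = protocolAlgorithms(),
                        masterSeed = 1,
                        sigma = NULL, gammaA = 0.01, gammaI = 0.1,
                        sparsifier = "knn", k = 10) {
  if (is(X, "MultiLabelSet")) {
    Y <- labelMatrix(X)
    X <- features(X)
  }
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (is.character(algorithms)) algorithms <- protocolAlgorithms()[algorithms]
  if (any(rates <= 0 | rates >= 1)) stop("rates must lie in (0, 1)")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must lie in (0, 1]")
  out <- vector("list", reps * length(rates) * length(algorithms))
  ix <- 0L
  for (r in seq_len(reps)) {
    for (ri in seq_along(rates)) {
      for (ai in seq_along(algorithms)) {
        seed <- .cellSeed(masterSeed, r, ri, ai)
        alg <- names(algorithms)[ai]
        cfg <- algorithms[[ai]]
        vals <- tryCatch({
          old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
          set.seed(seed)
          idx <- if (subsampleFraction < 1)
            sort(sample.int(nrow(X), round(subsampleFraction * nrow(X))))
          else seq_len(nrow(X))
          Xs <- X[idx, , drop = FALSE]
          Ys <- Y[idx, , drop = FALSE]
          sp <- splitTrainTest(nrow(Xs), trainFraction, seed = seed + 1L)
          msk <- maskLabels(Ys[sp$train, , drop = FALSE], rates[ri],
                            seed = seed + 2L)
          fit <- mlmr(Xs[sp$train, , drop = FALSE], msk$Y, sigma = sigma,
                      gammaA = gammaA, gammaI = gammaI,
                      nu1 = cfg$nu1, nu2 = cfg$nu2,
                      sparsifier = sparsifier, k = k)
          S <- predictScores(fit, Xs[sp$test, , drop = FALSE])
          v <- evaluateScores(S, Ys[sp$test, , drop = FALSE])
          if (!is.null(old)) assign(".Random.seed", old, globalenv())
          v
        }, error = function(e) {
          warning("protocol cell failed (", alg, ", rep ", r, ", rate ",
                  rates[ri], "): ", conditionMessage(e))
          c(avgprec = NA_real_, micro_f1 = NA_real_, macro_f1 = NA_real_)
        })
        ix <- ix + 1L
        out[[ix]] <- data.frame(
          repetition = r, labeling_rate = rates[ri], algorithm = alg,
          metric = names(vals), value = unname(vals), seed = seed,
          row.names = NULL)
      }
    }
  }
  do.call(rbind, out)
}

#' Aggregate protocol records and run the significance machinery
#'
#' For each metric, averages the records over repetitions within every
#' labeling rate, treats the rates as blocks (N = number of rates) and the
#' algorithms as treatments (K), ranks within blocks, runs the Friedman
#' test, and — when the null is rejected — the post-hoc
#' critical-difference comparison.
#'
#' @param records record data frame from [runProtocol()].
#' @param alpha significance level.
#' @param cdN the N used inside the critical-difference formula
#'   (default 1; see [criticalDifference()]).
#' @param rankPerRepetition rank each repetition as its own block instead
#'   of pre-averaging (default \code{FALSE}: blocks are rate means).
#' @return Named list (one entry per metric) of lists with \code{blocks},
#'   \code{ranks}, \code{rankSums}, \code{friedman}, \code{posthoc}
#'   (\code{NULL} when the null is not rejected).
#' @export
aggregateAndTest <- function(records, alpha = 0.05, cdN = 1,
                             rankPerRepetition = FALSE) {
  records <- records[!is.na(records$value), ]
  algs <- sort(unique(records$algorithm))
  rates <- sort(unique(records$labeling_rate))
  if (length(algs) < 2) stop("need at least 2 algorithms")
  if (length(rates) < 2 && !rankPerRepetition)
    stop("need at least 2 labeling rates as blocks")
  metrics <- sort(unique(records$metric))
  res <- lapply(metrics, function(m) {
    rm_ <- records[records$metric == m, ]
    if (rankPerRepetition) {
      blocks <- do.call(rbind, lapply(split(rm_, list(rm_$labeling_rate, rm_$repetition), drop = TRUE),
        function(d) {
          v <- tapply(d$value, d$algorithm, mean)[algs]
          if (anyNA(v)) NULL else v
        }))
    } else {
      blocks <- t(vapply(rates, function(rt) {
        d <- rm_[rm_$labeling_rate == rt, ]
        tapply(d$value, d$algorithm, mean)[algs]
      }, numeric(length(algs))))
      rownames(blocks) <- paste0("rate_", rates)
    }
    colnames(blocks) <- algs
    rt <- rankBlocks(blocks, higherIsBetter = TRUE)
    names(rt$rankSums) <- algs
    ft <- friedmanTest(rt, alpha = alpha)
    ph <- if (ft$rejectNull)
      posthocCompare(rt$rankSums,
                     criticalDifference(K = rt$K, alpha = alpha, N = cdN,
                                        quiet = TRUE))
    else NULL
    list(blocks = blocks, ranks = rt$ranks, rankSums = rt$rankSums,
         friedman = ft, posthoc = ph)
  })
  names(res) <- metrics
  res
}

#' Plot metric-vs-labeling-rate curves
#'
#' Mean metric value per labeling rate and algorithm, with one-standard-
#' deviation error bars. Requires ggplot2.
#'
#' @param records record data frame from [runProtocol()].
#' @param file optional path to save the figure (pdf/png by extension).
#' @return The ggplot object, invisibly when written to file.
#' @export
plotMetricCurves <- function(records, file = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  agg <- stats::aggregate(value ~ labeling_rate + algorithm + metric,
                          data = records,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  agg <- cbind(agg[, 1:3], as.data.frame(agg$value))
  p <- ggplot2::ggplot(agg, ggplot2::aes(
        x = labeling_rate, y = mean,
        colour = algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd,
                                        ymax = mean + sd),
                           width = 0.01) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "labeling rate", y = "metric value")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 9, height = 3.2)
    return(invisible(p))
  }
  p
}
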