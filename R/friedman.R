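#' Within-block ranks of algorithm scores
#'
#' Ranks K algorithms within each of N blocks (data sets or
#' labeling-rate conditions): the best-performing algorithm receives rank
#' 1 and ties receive average ranks.
#'
#' @param scores N x K matrix of performance values (rows = blocks,
#'   columns = algorithms).
#' @param higherIsBetter if \code{TRUE} (default) larger scores rank
#'   better.
#' @param tol optional tolerance under which scores are treated as tied
#'   (default 0 = exact equality only).
#' @return List: \code{ranks} (N x K), \code{rankSums} (length K),
#'   \code{N}, \code{K}.
#' @export
rankBlocks <- function(scores, higherIsBetter = TRUE, tol = 0) {
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stop("scores must be finite (no NaN/NA)")
  if (ncol(scores) < 2)
    stop("need at least 2 algorithms to rank")
  s <- if (higherIsBetter) -scores else scores
  if (tol > 0) s <- round(s / tol) * tol
  ranks <- t(apply(s, 1, rank, ties.method = "average"))
  list(ranks = ranks, rankSums = colSums(ranks),
       N = nrow(scores), K = ncol(scores))
}

#' Friedman rank test
#'
#' Computes the Friedman statistic
#' \deqn{F_R = \frac{12}{NK(K+1)} \sum_i R_i^2 - 3N(K+1)}
#' from the per-algorithm rank sums \eqn{R_i} over N blocks and compares
#' it with the upper-\eqn{\alpha} chi-square critical value on K - 1
#' degrees of freedom. The null hypothesis is that all K algorithms
#' perform alike.
#'
#' @param rankSums length-K vector of rank sums, or the list returned by
#'   [rankBlocks()] (in which case N and K are taken from it).
#' @param N number of blocks.
#' @param K number of algorithms.
#' @param alpha significance level (default 0.05).
#' @return List: \code{FR}, \code{df = K - 1}, \code{chi2Critical},
#'   \code{rejectNull}, \code{alpha}, \code{rankSums}, \code{N}, \code{K}.
#' @examples
#' rt <- rankBlocks(rbind(c(0.9, 0.8, 0.7), c(0.95, 0.85, 0.6)))
#' friedmanTest(rt)$FR  # ranks (1,2,3) twice -> FR = 4
#' @export
friedmanTest <- function(rankSums, N = NULL, K = NULL, alpha = 0.05) {
  if (is.list(rankSums)) {
    N <- rankSums$N
    K <- rankSums$K
    rankSums <- rankSums$rankSums
  }
  if (is.null(N) || is.null(K) || N < 2 || K < 2)
    stop("N and K must both be at least 2")
  if (length(rankSums) != K) stop("rankSums must have length K")
  FR <- 12 / (N * K * (K + 1)) * sum(rankSums^2) - 3 * N * (K + 1)
  crit <- chisqCritical(K - 1, alpha)
  list(FR = FR, df = K - 1L, chi2Critical = crit,
       rejectNull = FR > crit, alpha = alpha,
       rankSums = rankSums, N = N, K = K)
}

#' Upper-tail chi-square critical value
#'
#' @param df degrees of freedom (>= 1).
#' @param alpha significance level in (0, 1).
#' @return The upper-\eqn{\alpha} quantile of the chi-square distribution.
#' @examples
#' chisqCritical(6, 0.05)  # 12.592
#' @export
chisqCritical <- function(df, alpha = 0.05) {
  if (df < 1) stop("df must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  qchisq(1 - alpha, df)
}

#' Critical difference for post-hoc rank-sum comparisons
#'
#' \deqn{CD = z \sqrt{N K (K+1) / 6},}
#' where z is the upper-tail standard-normal quantile at
#' \eqn{\alpha / (K(K-1))} (a Bonferroni-style correction over the ordered
#' algorithm pairs). Two algorithms differ significantly when their rank
#' sums differ by at least CD.
#'
#' Note the N in this formula is supplied separately from the Friedman
#' test's block count: published rank-sum analyses sometimes tabulate CD
#' at N = 1 while summing ranks over more blocks, so the default here is
#' \code{N = 1} and a warning is emitted when the default is used with no
#' explicit choice.
#'
#' @param K number of algorithms (>= 2).
#' @param alpha significance level.
#' @param N block-count factor inside the square root (default 1).
#' @param quiet suppress the default-N warning.
#' @return The critical difference.
#' @examples
#' criticalDifference(K = 7, alpha = 0.05, N = 1, quiet = TRUE)  # 9.2815
#' @export
criticalDifference <- function(K, alpha = 0.05, N = 1, quiet = FALSE) {
  if (K < 2) stop("K must be at least 2")
  if (N < 1) stop("N must be at least 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (missing(N) && !quiet)
    warning("using N = 1 in the critical difference; pass N explicitly ",
            "to scale CD with the number of blocks")
  z <- qnorm(1 - alpha / (K * (K - 1)))
  z * sqrt(N * K * (K + 1) / 6)
}

#' Post-hoc pairwise rank-sum comparisons
#'
#' Builds the antisymmetric difference matrix \eqn{D_{ij} = R_i - R_j} and
#' classifies each ordered pair: algorithm i is significantly
#' \emph{better} than j when \eqn{|D_{ij}| \ge CD} and \eqn{D_{ij} < 0}
#' (lower rank sum = better), \emph{worse} when \eqn{|D_{ij}| \ge CD} and
#' \eqn{D_{ij} > 0}, otherwise not significant.
#'
#' @param rankSums length-K vector of rank sums.
#' @param CD critical difference from [criticalDifference()].
#' @return List: \code{D} (K x K), \code{CD}, \code{decisions} (K x K
#'   character matrix in \{"better", "worse", "ns"\}).
#' @export
posthocCompare <- function(rankSums, CD) {
  K <- length(rankSums)
  D <- outer(rankSums, rankSums, "-")
  dec <- matrix("ns", K, K)
  dec[abs(D) >= CD & D < 0] <- "better"
  dec[abs(D) >= CD & D > 0] <- "worse"
  diag(dec) <- ""
  dimnames(D) <- dimnames(dec) <-
    list(names(rankSums), names(rankSums))
  list(D = D, CD = CD, decisions = dec)
}

#' Render a significance report
#'
#' Plain-text rendering of a Friedman test plus post-hoc comparison, in
#' the rank-sum-difference table style common in algorithm-comparison
#' studies.
#'
#' @param ft result of [friedmanTest()].
#' @param ph optional result of [posthocCompare()].
#' @param file optional path; when given the text is written there.
#' @return The report lines, invisibly when written to file.
#' @export
renderSignificance <- function(ft, ph = NULL, file = NULL) {
  lines <- c(
    sprintf("Friedman test: F_R = %.4f on df = %d (N = %d blocks, K = %d)",
            ft$FR, ft$df, ft$N, ft$K),
    sprintf("chi-square critical value at alpha = %.3f: %.3f", ft$alpha,
            ft$chi2Critical),
    sprintf("null hypothesis (all algorithms alike): %s",
            if (ft$rejectNull) "REJECTED" else "not rejected"),
    sprintf("rank sums: %s", paste(format(ft$rankSums, digits = 4),
                                   collapse = " "))
  )
  if (!is.null(ph)) {
    lines <- c(lines, sprintf("critical difference: %.4f", ph$CD),
               "pairwise rank-sum differences D[i,j] = R_i - R_j:",
               utils::capture.output(print(round(ph$D, 3))),
               "decisions (row vs column):",
               utils::capture.output(print(ph$decisions, quote = FALSE)))
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
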