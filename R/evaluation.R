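#' Random edge-removal split for link-prediction evaluation
#'
#' Removes a uniformly random fraction of the edges (`round(fraction * m)`,
#' at least 1) to serve as test positives; the remaining edges form the
#' training network presented to the predictors. All nodes are kept, so
#' removal can isolate nodes — connectivity is deliberately not enforced.
#'
#' @param g the ground-truth network.
#' @param fraction fraction of edges to remove, in `(0, 1)` (default 0.1).
#' @param seed integer seed; the same seed always yields the same split.
#' @return List with `train` (network), `test` (data frame of removed edges,
#'   canonical `i < j`), `seed` and `fraction`.
#' @export
split_edges <- function(g, fraction = 0.1, seed = 1L) {
  m <- igraph::ecount(g)
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  n_remove <- max(1L, as.integer(round(fraction * m)))
  if (m - n_remove < 1) stop("split would leave a training graph with no edges")
  eid <- withr::with_seed(seed, sample.int(m, n_remove))
  ends <- igraph::as_edgelist(g)[eid, , drop = FALSE]
  list(
    train = igraph::delete_edges(g, eid),
    test = data.frame(
      i = pmin(ends[, 1], ends[, 2]),
      j = pmax(ends[, 1], ends[, 2]),
      stringsAsFactors = FALSE
    ),
    seed = seed,
    fraction = fraction
  )
}

#' Top-precision of a ranked score table
#'
#' Fraction of the top-`k` ranked candidates that are test positives, with
#' `k` defaulting to the number of test positives (r-precision). The table's
#' stored tie-break order decides ties.
#'
#' @param scores a ranked [score_table()] over all candidate pairs.
#' @param test_positives data frame of removed edges.
#' @param k cut-off rank (default: number of test positives).
#' @return Numeric in `[0, 1]`.
#' @export
top_precision <- function(scores, test_positives, k = NULL) {
  pos <- pair_key(test_positives[[1]], test_positives[[2]])
  keys <- pair_key(scores$i, scores$j)
  if (!all(pos %in% keys)) {
    stop("every test positive must appear among the scored candidates")
  }
  if (is.null(k)) k <- length(pos)
  if (k < 1 || k > nrow(scores)) stop("`k` must be in [1, number of candidates]")
  mean(keys[seq_len(k)] %in% pos)
}

#' Area under the ROC curve of a ranked score table
#'
#' Probability that a uniformly drawn test positive receives a higher score
#' than a uniformly drawn true negative; score ties count one half
#' (the Mann-Whitney formulation).
#'
#' @inheritParams top_precision
#' @return Numeric in `[0, 1]`.
#' @export
auroc <- function(scores, test_positives) {
  lab <- score_labels(scores, test_positives)
  np <- sum(lab)
  nn <- sum(!lab)
  if (np == 0 || nn == 0) {
    stop("AUROC needs at least one positive and one negative candidate")
  }
  r <- rank(scores$score)
  (sum(r[lab]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Computed as average precision over the positives' ranks — the step-wise
#' integral of the PR curve, standard in ranked retrieval and stable for
#' small positive sets. The table's stored tie-break order decides ties.
#'
#' @inheritParams top_precision
#' @return Numeric in `(0, 1]`.
#' @export
aupr <- function(scores, test_positives) {
  lab <- score_labels(scores, test_positives)
  np <- sum(lab)
  if (np == 0 || np == length(lab)) {
    stop("AUPR needs at least one positive and one negative candidate")
  }
  at <- which(lab)
  mean(seq_along(at) / at)
}

#' Top-precision relative to a uniform random ranker
#'
#' `tpr / (k / n_candidates)`: the analytic expected top-precision of a
#' uniform random ranking is `k / n_candidates`, so a random predictor has
#' relative top-precision 1 by construction. Useful when the test-set size
#' varies across comparisons (e.g. predicting network snapshots separated by
#' growing time intervals).
#'
#' @param tpr observed top-precision.
#' @param k cut-off rank used for `tpr` (> 0).
#' @param n_candidates total number of scored candidate pairs.
#' @return Nonnegative numeric.
#' @export
relative_top_precision <- function(tpr, k, n_candidates) {
  if (k <= 0) stop("`k` must be positive")
  if (k > n_candidates) stop("`k` cannot exceed `n_candidates`")
  tpr / (k / n_candidates)
}

#' Per-network significant scores and ranks of competing algorithms
#'
#' For one network evaluated over repeated paired runs (same splits for all
#' algorithms), performs a two-tailed paired t-test for every algorithm pair
#' on the per-run metric. A pair that is not significantly different at level
#' `p` contributes 0 to both; otherwise the better algorithm gets +1 and the
#' worse -1. Pairwise scores are summed into a network score per algorithm,
#' and algorithms are ranked by decreasing score with ties replaced by the
#' average rank. Zero-variance differences with equal means are treated as
#' non-significant; a constant nonzero difference is significant.
#'
#' @param per_run_metric numeric matrix, runs x algorithms, with column
#'   names; each row is one paired evaluation run.
#' @param p significance level of the paired t-tests (default 0.05).
#' @return List with `pairwise` (antisymmetric +1/0/-1 matrix), `scores`
#'   (row sums) and `ranks` (average-rank ties; lower is better).
#' @export
network_significant_scores <- function(per_run_metric, p = 0.05) {
  x <- as.matrix(per_run_metric)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("need >= 2 paired runs and >= 2 algorithms")
  }
  algs <- colnames(x)
  if (is.null(algs)) algs <- paste0("alg", seq_len(ncol(x)))
  A <- ncol(x)
  pm <- matrix(0, A, A, dimnames = list(algs, algs))
  for (a in seq_len(A - 1)) {
    for (b in (a + 1):A) {
      d <- x[, a] - x[, b]
      sig <- if (stats::sd(d) == 0) {
        mean(d) != 0
      } else {
        stats::t.test(x[, a], x[, b], paired = TRUE)$p.value < p
      }
      if (sig) {
        pm[a, b] <- sign(mean(d))
        pm[b, a] <- -pm[a, b]
      }
    }
  }
  scores <- rowSums(pm)
  list(
    pairwise = pm,
    scores = scores,
    ranks = rank(-scores, ties.method = "average")
  )
}

#' Average significant rank across networks
#'
#' Column means of a networks x algorithms matrix of per-network significant
#' ranks (see [network_significant_scores()]); lower is better.
#'
#' @param per_network_ranks numeric matrix, networks x algorithms.
#' @return Named numeric vector, one mean rank per algorithm.
#' @export
average_significant_rank <- function(per_network_ranks) {
  colMeans(as.matrix(per_network_ranks))
}

#' Pairwise comparison of algorithms over per-network significant ranks
#'
#' For every algorithm pair, a one-tailed two-sample Mann-Whitney-Wilcoxon
#' test on the per-network significant ranks (alternative oriented towards
#' the observed mean-rank order), with all pairwise p-values jointly adjusted
#' by the Benjamini-Hochberg-Yekutieli procedure. Directions are reported
#' only where the adjusted p-value clears `level`: `"<"` in row a, column b
#' means a has significantly smaller (better) ranks than b.
#'
#' @param significant_ranks numeric matrix, networks x algorithms, with
#'   column names.
#' @param level significance level for reporting directions (default 0.05).
#' @return List with `p_adjusted` (symmetric matrix of BY-adjusted p-values,
#'   `NA` diagonal) and `direction` (character matrix, `"<"`, `">"` or `""`).
#' @export
pairwise_method_comparison <- function(significant_ranks, level = 0.05) {
  x <- as.matrix(significant_ranks)
  if (nrow(x) < 2) stop("need >= 2 networks")
  if (ncol(x) < 2) stop("need >= 2 algorithms")
  algs <- colnames(x)
  if (is.null(algs)) algs <- paste0("alg", seq_len(ncol(x)))
  A <- ncol(x)
  idx <- which(upper.tri(matrix(0, A, A)), arr.ind = TRUE)
  praw <- numeric(nrow(idx))
  better <- logical(nrow(idx)) # row (a) better than column (b)?
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]
    b <- idx[r, 2]
    better[r] <- mean(x[, a]) <= mean(x[, b])
    alt <- if (better[r]) "less" else "greater"
    praw[r] <- stats::wilcox.test(x[, a], x[, b], alternative = alt,
                                  exact = FALSE, correct = TRUE)$p.value
  }
  padj <- stats::p.adjust(praw, method = "BY")
  P <- matrix(NA_real_, A, A, dimnames = list(algs, algs))
  D <- matrix("", A, A, dimnames = list(algs, algs))
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]
    b <- idx[r, 2]
    P[a, b] <- P[b, a] <- padj[r]
    if (padj[r] < level) {
      D[a, b] <- if (better[r]) "<" else ">"
      D[b, a] <- if (better[r]) ">" else "<"
    }
  }
  list(p_adjusted = P, direction = D)
}

#' Ordered snapshot couples for temporal link prediction
#'
#' Given time-ordered network snapshot labels, enumerates every ordered
#' couple (earlier, later): the earlier snapshot predicts the edges that are
#' new in the later one. `T` snapshots yield `T(T-1)/2` couples.
#'
#' @param labels vector of snapshot labels, already in temporal order.
#' @return Data frame with columns `earlier`, `later`.
#' @export
temporal_pairs <- function(labels) {
  labels <- as.character(labels)
  ts <- length(labels)
  if (ts < 2) {
    return(data.frame(earlier = character(), later = character(),
                      stringsAsFactors = FALSE))
  }
  ii <- rep.int(seq_len(ts - 1L), (ts - 1L):1L)
  jj <- sequence((ts - 1L):1L, from = 2:ts)
  data.frame(earlier = labels[ii], later = labels[jj],
             stringsAsFactors = FALSE)
}

# logical positive labels aligned with a score table's rows
score_labels <- function(scores, test_positives) {
  pos <- pair_key(test_positives[[1]], test_positives[[2]])
  keys <- pair_key(scores$i, scores$j)
  if (!all(pos %in% keys)) {
    stop("every test positive must appear among the scored candidates")
  }
  keys %in% pos
}
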