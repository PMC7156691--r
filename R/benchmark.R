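#' Deterministic sub-seed for one (network, run) cell
#'
#' The benchmark expands a single master seed into per-cell seeds with a
#' fixed arithmetic scheme, so any subset of a benchmark can be reproduced in
#' isolation: `(master * 1000003 + network_index * 10007 + run_index * 101)
#' mod 2147483399`, kept within the 32-bit integer range.
#'
#' @param master master seed (integer).
#' @param network_index 1-based network index.
#' @param run_index 1-based run index.
#' @return An integer seed.
#' @export
run_seed <- function(master, network_index, run_index = 1L) {
  as.integer((as.numeric(master) * 1000003 + network_index * 10007 +
                run_index * 101) %% 2147483399)
}

#' Evaluate prediction methods on one network over repeated splits
#'
#' For each run, removes a fraction of the edges, scores the training
#' graph's full candidate set with every method on the *same* split (paired
#' design), and computes top-precision, AUROC and AUPR against the removed
#' edges.
#'
#' @param g the ground-truth network.
#' @param methods character vector of method names (see
#'   [prediction_methods()]).
#' @param runs number of removal trials (>= 1).
#' @param fraction edge-removal fraction.
#' @param h horizon cut-off for `"ALG1"`.
#' @param seed master seed; run `r` uses [run_seed()]`(seed, network_index, r)`.
#' @param network_index index used in the sub-seed scheme.
#' @return Long data frame: `run`, `method`, `tpr`, `auroc`, `aupr`.
#' @export
evaluate_methods <- function(g, methods = prediction_methods(), runs = 10,
                             fraction = 0.1, h = 2, seed = 1L,
                             network_index = 1L) {
  out <- vector("list", runs * length(methods))
  z <- 0L
  for (r in seq_len(runs)) {
    s <- run_seed(seed, network_index, r)
    sp <- split_edges(g, fraction, seed = s)
    cands <- all_candidates(sp$train)
    for (meth in methods) {
      tbl <- score_candidates(sp$train, cands, method = meth, h = h,
                              tie_seed = s)
      z <- z + 1L
      out[[z]] <- data.frame(
        run = r, method = meth,
        tpr = top_precision(tbl, sp$test),
        auroc = auroc(tbl, sp$test),
        aupr = aupr(tbl, sp$test),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Run the full benchmark over several networks
#'
#' Reproduces the evaluation design at whatever scale the inputs dictate:
#' per (network, run) one edge-removal split shared by all methods, the
#' three ranking metrics per method, per-network significant scores and
#' ranks from paired t-tests, cross-network average significant ranks, and —
#' given at least two networks — the pairwise one-tailed
#' Mann-Whitney-Wilcoxon comparison with Benjamini-Yekutieli adjustment.
#' Everything is reproducible byte-for-byte from `seed`.
#'
#' @param networks named list of networks.
#' @param methods methods to compare (>= 2 for the significance machinery).
#' @param runs removal trials per network (>= 2).
#' @param fraction edge-removal fraction.
#' @param h horizon cut-off for `"ALG1"`.
#' @param p significance level of the per-network paired t-tests.
#' @param metric which per-run metric drives ranks: `"tpr"`, `"auroc"` or
#'   `"aupr"`.
#' @param seed master seed.
#' @param outdir optional directory; when given, writes `per_run.tsv`,
#'   `significant_ranks.tsv`, `average_ranks.tsv`, `pairwise_p.tsv` and a
#'   `run_log.tsv` of sub-seeds.
#' @return List: `per_run` (long data frame), `ranks` (networks x methods),
#'   `average_rank` (named vector), `pairwise` (from
#'   [pairwise_method_comparison()], or `NULL` with a single network).
#' @export
run_benchmark <- function(networks, methods = prediction_methods(),
                          runs = 10, fraction = 0.1, h = 2, p = 0.05,
                          metric = c("tpr", "auroc", "aupr"), seed = 1L,
                          outdir = NULL) {
  metric <- match.arg(metric)
  if (runs < 2) stop("significance ranking needs >= 2 runs")
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("network", seq_along(networks))
  }
  per_run <- vector("list", length(networks))
  ranks <- matrix(NA_real_, length(networks), length(methods),
                  dimnames = list(names(networks), methods))
  for (ni in seq_along(networks)) {
    res <- evaluate_methods(networks[[ni]], methods, runs, fraction, h,
                            seed = seed, network_index = ni)
    res$network <- names(networks)[ni]
    per_run[[ni]] <- res
    mat <- matrix(NA_real_, runs, length(methods),
                  dimnames = list(NULL, methods))
    for (meth in methods) {
      mat[, meth] <- res[res$method == meth, metric]
    }
    ranks[ni, ] <- network_significant_scores(mat, p = p)$ranks
  }
  per_run <- do.call(rbind, per_run)
  avg <- average_significant_rank(ranks)
  pw <- if (length(networks) >= 2) pairwise_method_comparison(ranks, p) else NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(per_run, file.path(outdir, "per_run.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(network = rownames(ranks), as.data.frame(ranks)),
                       file.path(outdir, "significant_ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(method = names(avg), average_rank = avg),
                       file.path(outdir, "average_ranks.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(pw)) {
      utils::write.table(cbind(method = rownames(pw$p_adjusted),
                               as.data.frame(pw$p_adjusted)),
                         file.path(outdir, "pairwise_p.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    log <- expand.grid(run = seq_len(runs),
                       network = names(networks), KEEP.OUT.ATTRS = FALSE)
    log$seed <- run_seed(seed, match(log$network, names(networks)), log$run)
    utils::write.table(log, file.path(outdir, "run_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(per_run = per_run, ranks = ranks, average_rank = avg, pairwise = pw)
}

#' Horizon cut-off study
#'
#' Runs the similarity-popularity predictor at several horizon values on
#' identical splits of the same networks and aggregates the per-horizon
#' metrics with the same significant-rank machinery as [run_benchmark()],
#' treating each horizon as a competing algorithm.
#'
#' @param networks named list of networks.
#' @param h_values numeric vector of horizons (use `Inf` for exact
#'   distances).
#' @param runs removal trials per network.
#' @param fraction edge-removal fraction.
#' @param p significance level.
#' @param metric metric driving the ranks.
#' @param seed master seed.
#' @return List as [run_benchmark()], with one "method" per horizon (named
#'   `"h=<value>"`), plus `per_run` carrying all three metrics.
#' @export
horizon_study <- function(networks, h_values = c(2, 3, Inf), runs = 10,
                          fraction = 0.1, p = 0.05,
                          metric = c("tpr", "auroc", "aupr"), seed = 1L) {
  metric <- match.arg(metric)
  if (length(h_values) < 1) stop("need at least one horizon value")
  if (is.null(names(networks)) || any(names(networks) == "")) {
    names(networks) <- paste0("network", seq_along(networks))
  }
  hl <- paste0("h=", h_values)
  per_run <- list()
  ranks <- matrix(NA_real_, length(networks), length(h_values),
                  dimnames = list(names(networks), hl))
  for (ni in seq_along(networks)) {
    g <- networks[[ni]]
    mat <- matrix(NA_real_, runs, length(h_values),
                  dimnames = list(NULL, hl))
    for (r in seq_len(runs)) {
      s <- run_seed(seed, ni, r)
      sp <- split_edges(g, fraction, seed = s)
      cands <- all_candidates(sp$train)
      for (hi in seq_along(h_values)) {
        tbl <- predict_scores(sp$train, cands, h = h_values[hi], tie_seed = s)
        row <- data.frame(
          network = names(networks)[ni], run = r, h = hl[hi],
          tpr = top_precision(tbl, sp$test),
          auroc = auroc(tbl, sp$test),
          aupr = aupr(tbl, sp$test),
          stringsAsFactors = FALSE
        )
        per_run[[length(per_run) + 1L]] <- row
        mat[r, hi] <- row[[metric]]
      }
    }
    ranks[ni, ] <- if (length(h_values) >= 2) {
      network_significant_scores(mat, p = p)$ranks
    } else {
      1
    }
  }
  per_run <- do.call(rbind, per_run)
  list(
    per_run = per_run,
    ranks = ranks,
    average_rank = average_significant_rank(ranks),
    pairwise = if (length(networks) >= 2 && length(h_values) >= 2) {
      pairwise_method_comparison(ranks, p)
    } else {
      NULL
    }
  )
}
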