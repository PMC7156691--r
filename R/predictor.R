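#' Degree transform used by the popularity and attraction terms
#'
#' `phi(x) = log(x + 1)` (natural logarithm). The `+1` keeps the transform
#' defined at degree 0, so isolated nodes — which routinely appear after
#' test-edge removal — need no special casing.
#'
#' @param x nonnegative numeric vector.
#' @return `log(x + 1)`, same length as `x`.
#' @examples
#' phi(0)      # 0
#' phi(exp(1) - 1) # 1
#' @export
phi <- function(x) {
  if (any(x < 0)) stop("phi() is defined for nonnegative arguments only")
  log1p(x)
}

#' Popularity term of a node pair
#'
#' The joint popularity of two nodes, `(phi(ki) + phi(kj)) / (2 phi(kmax))`:
#' the average log-degree of the pair normalised by the network's maximum
#' degree, so the value lies in `[0, 1]`, reaching 1 only when both nodes
#' have maximum degree and 0 only when both are isolated.
#'
#' @param ki,kj degrees of the two nodes.
#' @param kmax maximum degree in the network (must be >= 1 and >= `ki`, `kj`).
#' @return Numeric in `[0, 1]`; vectorised over `ki`, `kj`.
#' @export
popularity <- function(ki, kj, kmax) {
  if (length(kmax) != 1 || kmax < 1) {
    stop("`kmax` must be a single degree >= 1 (degenerate graph with no edges?)")
  }
  if (any(ki < 0) || any(kj < 0) || any(ki > kmax) || any(kj > kmax)) {
    stop("degrees must lie in [0, kmax]")
  }
  (phi(ki) + phi(kj)) / (2 * phi(kmax))
}

#' Local attraction term of a node pair
#'
#' The attraction induced by the pair's common neighbourhood:
#' `1 - prod_k phi(kappa_k) / phi(kmax)` over the degrees `kappa_k` of the
#' common neighbours. Low-degree common neighbours pull the value towards 1;
#' an empty common neighbourhood gives 0 by convention, as does a single
#' common neighbour of maximum degree. The term is weakly decreasing in each
#' common-neighbour degree.
#'
#' @param common_neighbour_degrees degrees of the common neighbours of the
#'   pair (each necessarily >= 2).
#' @param kmax maximum degree in the network.
#' @return Numeric in `[0, 1]`.
#' @export
local_attraction <- function(common_neighbour_degrees, kmax) {
  k <- common_neighbour_degrees
  if (length(k) == 0) return(0)
  if (any(k > kmax)) stop("common-neighbour degree exceeds `kmax`")
  if (any(k < 2)) {
    stop("a common neighbour of two distinct nodes has degree >= 2")
  }
  1 - exp(sum(log(phi(k) / phi(kmax))))
}

#' Induced edge length
#'
#' The length `2 * pi / (1 + eta)` assigned to an edge from its popularity
#' term `pi` and attraction term `eta`. Popular endpoints do not need a short
#' hidden distance to connect, so they get long edges; strong neighbourhood
#' attraction shortens the edge. Lengths lie in `(0, 2]` on graphs with
#' minimum degree 1.
#'
#' @param pi popularity term(s) in `[0, 1]`.
#' @param eta attraction term(s) in `[0, 1]`.
#' @return Numeric edge length(s).
#' @export
edge_weight <- function(pi, eta) {
  if (any(pi < 0 | pi > 1) || any(eta < 0 | eta > 1)) {
    stop("`pi` and `eta` must lie in [0, 1]")
  }
  2 * pi / (1 + eta)
}

#' Compute the induced edge-length map of a network
#'
#' Applies [popularity()], [local_attraction()] and [edge_weight()] to every
#' edge, using degrees, the maximum degree and common neighbourhoods of the
#' network itself (the observed graph — never any held-out edges). The
#' resulting lengths factor popularity and local attraction out of the
#' topology, so that shortest-path distances on them estimate hidden
#' dissimilarity.
#'
#' @param g a network with at least one edge.
#' @return Data frame with one row per edge of `g` (in `igraph::E(g)` order):
#'   columns `i`, `j`, `pi`, `eta`, `weight`.
#' @export
build_weight_map <- function(g) {
  ga <- graph_arrays(g)
  if (ga$m == 0) stop("degenerate graph: no edges, no weight map")
  ends <- ga$ends
  pi_e <- popularity(ga$deg[ends[, 1]], ga$deg[ends[, 2]], ga$kmax)
  eta_e <- pair_attraction(ga, ends[, 1], ends[, 2])
  data.frame(
    i = ga$names[ends[, 1]],
    j = ga$names[ends[, 2]],
    pi = pi_e,
    eta = eta_e,
    weight = edge_weight(pi_e, eta_e),
    stringsAsFactors = FALSE
  )
}

#' Hop-bounded weighted shortest-path distances
#'
#' Minimum total edge length over all paths with at most `h` edges, from each
#' source to every node. Pairs joined by no path of `<= h` edges get `Inf`.
#' `h = Inf` is the ordinary shortest-path distance (computed by Dijkstra's
#' algorithm). The horizon cut-off is what makes the predictor scale: with
#' small `h` only a small neighbourhood of each source is ever explored.
#'
#' Finite horizons use `h` rounds of edge relaxation over hop-indexed states
#' (the lightest path need not have the fewest hops, so plain early-stopped
#' relaxation would be wrong). All edge lengths must be positive, hence the
#' minimum over walks equals the minimum over paths.
#'
#' @param g a network.
#' @param weights positive edge lengths aligned with `igraph::E(g)`, e.g.
#'   `build_weight_map(g)$weight`.
#' @param sources character vector of source node names (default: all nodes).
#' @param h positive integer horizon, or `Inf`.
#' @return Numeric matrix, `length(sources)` rows, one column per node of
#'   `g`, with `dimnames`; entry `[s, v]` is the distance from `s` to `v`.
#' @export
horizon_shortest_paths <- function(g, weights, sources = igraph::V(g)$name,
                                   h = 2) {
  if (length(h) != 1 || is.na(h) || h < 1) {
    stop("`h` must be a positive integer or Inf")
  }
  m <- igraph::ecount(g)
  if (length(weights) != m) stop("`weights` must cover all edges of `g`")
  if (m > 0 && any(weights <= 0)) stop("edge lengths must be positive")
  vnames <- igraph::V(g)$name
  src <- match(sources, vnames)
  if (anyNA(src)) stop("unknown source node(s)")
  if (is.infinite(h)) {
    d <- igraph::distances(g, v = sources, weights = weights,
                           algorithm = "dijkstra")
    return(d[, vnames, drop = FALSE])
  }
  h <- as.integer(h)
  n <- length(vnames)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  from <- c(ends[, 1], ends[, 2])
  to <- c(ends[, 2], ends[, 1])
  wt <- rep(weights, 2L)
  ns <- length(src)
  D <- matrix(Inf, nrow = ns, ncol = n, dimnames = list(sources, vnames))
  D[cbind(seq_len(ns), src)] <- 0
  for (round in seq_len(h)) {
    Dn <- D
    for (e in seq_along(from)) {
      cand <- D[, from[e]] + wt[e]
      tgt <- to[e]
      Dn[, tgt] <- pmin(Dn[, tgt], cand)
    }
    if (identical(Dn, D)) break # no relaxation fired; longer horizons idle
    D <- Dn
  }
  D
}

#' Similarity-popularity link prediction scores
#'
#' The full predictor: each candidate non-adjacent pair `(i, j)` receives the
#' score `psi = (pi + eta) * s`, where `pi` is the pair's [popularity()],
#' `eta` its [local_attraction()], and `s = 1 / (1 + d)` its similarity, with
#' `d` the [horizon_shortest_paths()] distance on the induced edge-length map
#' of `g`. Pairs beyond the horizon (`d = Inf`) score exactly 0. Scores lie
#' in `[0, 2]`.
#'
#' @param g the observed (training) network.
#' @param candidates data frame of non-adjacent node pairs to score
#'   (default: [all_candidates()] of `g`).
#' @param h horizon cut-off (default 2; `Inf` for exact distances).
#' @param tie_seed seed for the ranked table's tie-breaking shuffle.
#' @return A ranked [score_table()].
#' @examples
#' g <- fixture_triangle_pendant()
#' predict_scores(g, h = 2)
#' @export
predict_scores <- function(g, candidates = NULL, h = 2, tie_seed = 1L) {
  if (is.null(candidates)) candidates <- all_candidates(g)
  ga <- graph_arrays(g)
  if (ga$m == 0) stop("degenerate graph: no edges")
  cand <- candidate_index(ga, candidates)
  if (nrow(cand) == 0) {
    return(score_table(candidates, numeric(0), tie_seed))
  }
  wm <- build_weight_map(g)
  pi_c <- popularity(ga$deg[cand[, 1]], ga$deg[cand[, 2]], ga$kmax)
  eta_c <- pair_attraction(ga, cand[, 1], cand[, 2])
  srcs <- unique(ga$names[cand[, 1]])
  D <- horizon_shortest_paths(g, wm$weight, sources = srcs, h = h)
  d_c <- D[cbind(
    match(ga$names[cand[, 1]], srcs),
    cand[, 2]
  )]
  s_c <- ifelse(is.infinite(d_c), 0, 1 / (1 + d_c))
  score_table(candidates, (pi_c + eta_c) * s_c, tie_seed)
}

# ---- internal helpers -----------------------------------------------------

# Precomputed index arrays for a network: vertex names, integer edge ends,
# degrees, kmax, sparse adjacency pattern.
graph_arrays <- function(g) {
  vnames <- igraph::V(g)$name
  n <- length(vnames)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  storage.mode(ends) <- "integer"
  deg <- as.numeric(igraph::degree(g))
  A <- Matrix::sparseMatrix(
    i = c(ends[, 1], ends[, 2]), j = c(ends[, 2], ends[, 1]),
    x = 1, dims = c(n, n)
  )
  list(names = vnames, n = n, m = nrow(ends), ends = ends, deg = deg,
       kmax = if (n > 0) max(deg) else 0, A = A)
}

# Map a candidate data frame to an integer pair matrix; errors if any pair is
# an existing edge or has unknown endpoints.
candidate_index <- function(ga, candidates) {
  ci <- match(as.character(candidates[[1]]), ga$names)
  cj <- match(as.character(candidates[[2]]), ga$names)
  if (anyNA(ci) || anyNA(cj)) stop("candidate refers to unknown node(s)")
  if (any(ci == cj)) stop("candidate pairs must join two distinct nodes")
  n <- ga$n
  ckey <- pmin(ci, cj) * (n + 1) + pmax(ci, cj)
  if (anyDuplicated(ckey)) stop("duplicated candidate pair")
  ekey <- pmin(ga$ends[, 1], ga$ends[, 2]) * (n + 1) +
    pmax(ga$ends[, 1], ga$ends[, 2])
  if (any(ckey %in% ekey)) {
    stop("contract violation: candidate pair is an existing edge")
  }
  cbind(ci, cj)
}

# Common-neighbour statistics for arbitrary node pairs via one sparse
# matrix product per weighting; returns NA-free vectors aligned with (ii, jj).
# Sums f(k) over common neighbours k, where f is a per-node weight vector.
pair_cn_sum <- function(ga, f, ii, jj) {
  M <- ga$A %*% (Matrix::Diagonal(x = f) %*% ga$A)
  M <- methods::as(M, "TsparseMatrix")
  n <- ga$n
  mi <- M@i + 1L
  mj <- M@j + 1L
  keys <- pmin(mi, mj) * (n + 1) + pmax(mi, mj)
  pos <- match(pmin(ii, jj) * (n + 1) + pmax(ii, jj), keys)
  out <- M@x[pos]
  out[is.na(out)] <- 0
  out
}

# eta for arbitrary pairs: 1 - prod phi(k)/phi(kmax) over common neighbours,
# 0 for pairs without common neighbours. Computed in log space so the whole
# candidate set is one sparse product.
pair_attraction <- function(ga, ii, jj) {
  cn <- pair_cn_sum(ga, rep(1, ga$n), ii, jj)
  logf <- ifelse(ga$deg >= 1, log(phi(ga$deg) / phi(ga$kmax)), 0)
  lsum <- pair_cn_sum(ga, logf, ii, jj)
  ifelse(cn > 0, 1 - exp(lsum), 0)
}
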