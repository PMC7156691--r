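#' Local topological baseline indices
#'
#' Seven classical local similarity indices used as comparison baselines for
#' link prediction. For a candidate pair `(i, j)` with common-neighbour set
#' `G_ij`, degrees `k_i`, `k_j` and common-neighbour degrees `k_k`:
#'
#' * `ADA` (Adamic-Adar): `sum_k 1 / log(k_k)`
#' * `CNE` (common neighbours): `|G_ij|`
#' * `CH`  (Cannistraci-Hebb): `sum_k |G_k intersect G_ij| / k_k` — rewards
#'   common neighbours that are themselves interlinked (local community)
#' * `HPI` (hub promoted): `|G_ij| / min(k_i, k_j)`
#' * `JID` (Jaccard): `|G_ij| / (k_i + k_j - |G_ij|)`
#' * `PAT` (preferential attachment): `k_i * k_j` — pure popularity
#' * `RAL` (resource allocation): `sum_k 1 / k_k`
#'
#' All logarithms are natural. A common neighbour always has degree >= 2, so
#' `log(k_k) > 0` and the ADA sum is well defined. `HPI` and `JID` return 0
#' when an endpoint is isolated (the pair then has no common neighbours, and
#' 0 is the natural limit of the ratio).
#'
#' @param g the observed (training) network.
#' @param candidates data frame of non-adjacent node pairs
#'   (default: [all_candidates()] of `g`).
#' @param method one of `"ADA"`, `"CNE"`, `"CH"`, `"HPI"`, `"JID"`, `"PAT"`,
#'   `"RAL"`.
#' @param tie_seed seed for the ranked table's tie-breaking shuffle.
#' @return A ranked [score_table()].
#' @examples
#' g <- fixture_triangle_pendant()
#' baseline_scores(g, method = "ADA")
#' @export
baseline_scores <- function(g, candidates = NULL,
                            method = c("ADA", "CNE", "CH", "HPI", "JID",
                                       "PAT", "RAL"),
                            tie_seed = 1L) {
  method <- match.arg(method)
  if (is.null(candidates)) candidates <- all_candidates(g)
  ga <- graph_arrays(g)
  cand <- candidate_index(ga, candidates)
  if (nrow(cand) == 0) return(score_table(candidates, numeric(0), tie_seed))
  ki <- ga$deg[cand[, 1]]
  kj <- ga$deg[cand[, 2]]
  s <- switch(method,
    PAT = ki * kj,
    CNE = pair_cn_sum(ga, rep(1, ga$n), cand[, 1], cand[, 2]),
    ADA = {
      w <- ifelse(ga$deg >= 2, 1 / log(pmax(ga$deg, 2)), 0)
      pair_cn_sum(ga, w, cand[, 1], cand[, 2])
    },
    RAL = {
      w <- ifelse(ga$deg >= 1, 1 / pmax(ga$deg, 1), 0)
      pair_cn_sum(ga, w, cand[, 1], cand[, 2])
    },
    HPI = {
      cn <- pair_cn_sum(ga, rep(1, ga$n), cand[, 1], cand[, 2])
      ifelse(cn > 0, cn / pmin(ki, kj), 0)
    },
    JID = {
      cn <- pair_cn_sum(ga, rep(1, ga$n), cand[, 1], cand[, 2])
      ifelse(cn > 0, cn / (ki + kj - cn), 0)
    },
    CH = ch_scores(ga, cand)
  )
  score_table(candidates, s, tie_seed)
}

# Cannistraci-Hebb: needs the explicit common-neighbour set of each pair.
# Only pairs with at least one common neighbour can score > 0, so the loop
# runs over those alone.
ch_scores <- function(ga, cand) {
  cn <- pair_cn_sum(ga, rep(1, ga$n), cand[, 1], cand[, 2])
  out <- numeric(nrow(cand))
  todo <- which(cn > 0)
  if (length(todo) == 0) return(out)
  adj <- adjacency_list(ga)
  deg <- ga$deg
  for (r in todo) {
    gij <- intersect(adj[[cand[r, 1]]], adj[[cand[r, 2]]])
    tot <- 0
    for (k in gij) {
      tot <- tot + length(intersect(adj[[k]], gij)) / deg[k]
    }
    out[r] <- tot
  }
  out
}

# integer adjacency list from the precomputed arrays
adjacency_list <- function(ga) {
  adj <- rep(list(integer(0)), ga$n)
  if (ga$m == 0) return(adj)
  nb <- split(
    c(ga$ends[, 2], ga$ends[, 1]),
    factor(c(ga$ends[, 1], ga$ends[, 2]), levels = seq_len(ga$n))
  )
  lapply(nb, as.integer)
}

#' Score candidate pairs with any implemented method
#'
#' Uniform front door over the similarity-popularity predictor (`"ALG1"`)
#' and the seven local baselines: every method sees the same candidates and
#' the same tie-break contract, which is what makes paired evaluation runs
#' meaningful.
#'
#' @param g the observed (training) network.
#' @param candidates data frame of non-adjacent pairs (default: all).
#' @param method `"ALG1"` or a baseline name (see [baseline_scores()]).
#' @param h horizon cut-off, used by `"ALG1"` only.
#' @param tie_seed seed for the tie-breaking shuffle.
#' @return A ranked [score_table()].
#' @export
score_candidates <- function(g, candidates = NULL, method = "ALG1", h = 2,
                             tie_seed = 1L) {
  method <- toupper(method)
  if (method == "ALG1") {
    predict_scores(g, candidates, h = h, tie_seed = tie_seed)
  } else {
    baseline_scores(g, candidates, method = method, tie_seed = tie_seed)
  }
}

#' Names of all implemented prediction methods
#' @return Character vector: `"ALG1"` plus the seven baseline indices.
#' @export
prediction_methods <- function() {
  c("ALG1", "ADA", "CNE", "CH", "HPI", "JID", "PAT", "RAL")
}
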