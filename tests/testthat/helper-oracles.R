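# Independent brute-force oracles and small random-graph builders.
# Everything here works from the edge list directly (base R sets and
# recursion) and shares no code with the package internals it checks.

# Erdos-Renyi-style random simple graph on n nodes with m edges.
random_graph <- function(n, m, seed) {
  withr::with_seed(seed, {
    npairs <- n * (n - 1) / 2
    m <- min(m, npairs)
    pick <- sample.int(npairs, m)
    ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
    jj <- sequence((n - 1L):1L, from = 2:n)
    as_network(cbind(as.character(ii[pick]), as.character(jj[pick])),
               nodes = as.character(seq_len(n)))
  })
}

# named adjacency list (character neighbours) straight from the edge table
bf_adjacency <- function(g) {
  e <- network_edges(g)
  nodes <- igraph::V(g)$name
  adj <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  for (r in seq_len(nrow(e))) {
    adj[[e$i[r]]] <- c(adj[[e$i[r]]], e$j[r])
    adj[[e$j[r]]] <- c(adj[[e$j[r]]], e$i[r])
  }
  adj
}

# brute-force local index for one pair, from the adjacency list alone
bf_baseline <- function(adj, i, j, method) {
  cn <- intersect(adj[[i]], adj[[j]])
  ki <- length(adj[[i]])
  kj <- length(adj[[j]])
  kk <- lengths(adj[cn])
  switch(method,
    ADA = if (length(cn)) sum(1 / log(kk)) else 0,
    CNE = length(cn),
    CH = if (length(cn)) {
      sum(vapply(cn, function(k) {
        length(intersect(adj[[k]], cn)) / length(adj[[k]])
      }, numeric(1)))
    } else 0,
    HPI = if (length(cn)) length(cn) / min(ki, kj) else 0,
    JID = if (length(cn)) length(cn) / (ki + kj - length(cn)) else 0,
    PAT = ki * kj,
    RAL = if (length(cn)) sum(1 / kk) else 0,
    stop("unknown method")
  )
}

# Exhaustive walk enumeration: minimum total weight over all walks with at
# most h edges from `from` to `to` (weights positive, so this equals the
# path minimum). Exponential; for tiny graphs only.
bf_horizon_dist <- function(g, weights, from, to, h) {
  e <- network_edges(g)
  nodes <- igraph::V(g)$name
  nbr <- stats::setNames(rep(list(NULL), length(nodes)), nodes)
  for (r in seq_len(nrow(e))) {
    nbr[[e$i[r]]] <- rbind(nbr[[e$i[r]]], data.frame(v = e$j[r], w = weights[r]))
    nbr[[e$j[r]]] <- rbind(nbr[[e$j[r]]], data.frame(v = e$i[r], w = weights[r]))
  }
  best <- Inf
  walk <- function(v, hops, acc) {
    if (acc >= best) return()
    if (v == to) best <<- min(best, acc)
    if (hops == 0L) return()
    nb <- nbr[[v]]
    if (is.null(nb)) return()
    for (r in seq_len(nrow(nb))) walk(nb$v[r], hops - 1L, acc + nb$w[r])
  }
  walk(from, as.integer(h), 0)
  best
}

# score table whose scores are the indicator of a positive set (a perfect
# oracle predictor, used to pin the metrics' upper end)
oracle_table <- function(candidates, positives, tie_seed = 1L) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  s <- as.numeric(key(candidates$i, candidates$j) %in%
                    key(positives$i, positives$j))
  score_table(candidates, s, tie_seed)
}
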