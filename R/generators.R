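#' Barabasi-Albert scale-free network
#'
#' Growth with preferential attachment: the process starts from a clique on
#' `k + 1` nodes, and every subsequent node attaches `k` edges to distinct
#' existing nodes chosen with probability proportional to their current
#' degree. With this seed-clique convention the edge count is the closed form
#' `m = k (n - k - 1) + k (k + 1) / 2` and every non-seed node has degree at
#' least `k`. The degree distribution develops the model's power-law tail
#' (exponent about 3).
#'
#' @param n number of nodes (`n > k`).
#' @param k edges attached by each incoming node (`k >= 1`).
#' @param seed integer seed; generation is fully reproducible.
#' @return A network with nodes named `"1" ... "n"`.
#' @export
generate_ba <- function(n, k, seed = 1L) {
  if (k < 1 || n <= k) stop("need n > k >= 1")
  n <- as.integer(n)
  k <- as.integer(k)
  withr::with_seed(seed, {
    m_total <- k * (n - k - 1L) + (k * (k + 1L)) %/% 2L
    edges <- matrix(0L, nrow = m_total, ncol = 2)
    deg <- numeric(n)
    # seed clique
    e <- 0L
    for (a in seq_len(k)) {
      for (b in (a + 1L):(k + 1L)) {
        e <- e + 1L
        edges[e, ] <- c(a, b)
      }
    }
    deg[seq_len(k + 1L)] <- k
    if (n > k + 1L) {
      for (t in (k + 2L):n) {
        targets <- sample.int(t - 1L, k, prob = deg[seq_len(t - 1L)])
        edges[e + seq_len(k), 1] <- t
        edges[e + seq_len(k), 2] <- targets
        e <- e + k
        deg[targets] <- deg[targets] + 1
        deg[t] <- k
      }
    }
    as_network(matrix(as.character(edges), ncol = 2),
               nodes = as.character(seq_len(n)))
  })
}

#' Watts-Strogatz small-world network
#'
#' A ring lattice of `n` nodes, each linked to its `k` previous and `k` next
#' neighbours, followed by one pass of random rewiring: each lattice edge is,
#' with probability `p`, reconnected from its far endpoint to a uniformly
#' chosen node — skipped if the move would create a self-loop or a duplicate
#' edge, so the edge count is always exactly `n * k`.
#'
#' @param n number of nodes (`n > 2k`).
#' @param k lattice half-degree (each node starts with degree `2k`).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed integer seed.
#' @return A network with nodes named `"1" ... "n"` and `m = n * k` edges.
#' @export
generate_ws <- function(n, k, p, seed = 1L) {
  if (n <= 2 * k) stop("need n > 2k")
  if (p < 0 || p > 1) stop("`p` must be in [0, 1]")
  n <- as.integer(n)
  k <- as.integer(k)
  withr::with_seed(seed, {
    u <- rep(seq_len(n), k)
    d <- rep(seq_len(k), each = n)
    v <- ((u + d - 1L) %% n) + 1L
    present <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * n * k)
    ekey <- function(a, b) paste(min(a, b), max(a, b))
    for (e in seq_along(u)) assign(ekey(u[e], v[e]), TRUE, envir = present)
    rewire <- stats::runif(length(u)) < p
    for (e in which(rewire)) {
      w <- sample.int(n, 1L)
      if (w == u[e]) next
      key_new <- ekey(u[e], w)
      if (exists(key_new, envir = present, inherits = FALSE)) next
      rm(list = ekey(u[e], v[e]), envir = present)
      assign(key_new, TRUE, envir = present)
      v[e] <- w
    }
    as_network(cbind(as.character(u), as.character(v)),
               nodes = as.character(seq_len(n)))
  })
}

#' Nonuniform popularity-similarity optimisation (nPSO) network
#'
#' Growth in the hyperbolic disk: node `t` is born at radial coordinate
#' `r_t = 2 log t` with an angular coordinate drawn from a `C`-component
#' Gaussian mixture (equally spaced means, equal weights), which shapes `C`
#' angular communities. Earlier nodes drift outward by popularity fading,
#' `r_s(t) = beta r_s + (1 - beta) r_t` with `beta = 1 / (gamma - 1)`. Each
#' new node links to `k` existing nodes — all of them while fewer than `k`
#' exist — chosen, at temperature `T > 0`, by weighted sampling without
#' replacement with Fermi connection probabilities
#' `1 / (1 + exp((x_st - R_t) / (2T)))` of the hyperbolic distances `x_st`;
#' at `T = 0` the `k` hyperbolically closest nodes are chosen. `k` is half
#' the average degree, so the realised mean degree is about `2k`; higher `T`
#' mixes communities and lowers clustering.
#'
#' The radial schedule, fading law, cut-off radius `R_t` and the default
#' mixture spread `sigma = (2 pi / C) / 6` are the standard
#' popularity-similarity-optimisation growth constants; all are arguments so
#' variants can be explored.
#'
#' @param n number of nodes.
#' @param k half of the target average degree (`>= 1`).
#' @param T temperature (`>= 0`, `< 1`); controls clustering.
#' @param gamma power-law exponent of the target degree distribution (> 2).
#' @param C number of mixture components / communities (>= 1).
#' @param seed integer seed.
#' @param sigma angular standard deviation of each mixture component.
#' @return A network with nodes `"1" ... "n"` and vertex attributes `theta`
#'   (angular coordinate), `radius` (birth radial coordinate) and
#'   `community` (mixture component, `1 ... C`).
#' @export
generate_npso <- function(n, k, T = 0.3, gamma = 3, C = 8, seed = 1L,
                          sigma = (2 * pi / C) / 6) {
  if (k < 1) stop("need k >= 1")
  if (T < 0 || T >= 1) stop("`T` must be in [0, 1)")
  if (gamma <= 2) stop("`gamma` must exceed 2")
  if (C < 1) stop("need C >= 1")
  n <- as.integer(n)
  k <- as.integer(k)
  beta <- 1 / (gamma - 1)
  withr::with_seed(seed, {
    comp <- sample.int(C, n, replace = TRUE)
    mu <- 2 * pi * (comp - 1) / C
    theta <- (stats::rnorm(n, mean = mu, sd = sigma)) %% (2 * pi)
    r_birth <- 2 * log(seq_len(n))
    edges_i <- integer(0)
    edges_j <- integer(0)
    for (t in 2:n) {
      s <- seq_len(t - 1L)
      if (t <= k + 1L) {
        targets <- s
      } else {
        r_faded <- beta * r_birth[s] + (1 - beta) * r_birth[t]
        dth <- abs(theta[s] - theta[t])
        dth <- pmin(dth, 2 * pi - dth)
        x <- r_faded + r_birth[t] + 2 * log(pmax(dth, 1e-12) / 2)
        if (T == 0) {
          targets <- s[order(x)[seq_len(k)]]
        } else {
          Rt <- r_birth[t] - 2 * log(
            2 * T * (1 - exp(-(1 - beta) * log(t))) /
              (sin(T * pi) * k * (1 - beta))
          )
          prob <- 1 / (1 + exp((x - Rt) / (2 * T)))
          targets <- sample(s, k, prob = prob + 1e-15)
        }
      }
      edges_i <- c(edges_i, rep.int(t, length(targets)))
      edges_j <- c(edges_j, targets)
    }
    g <- as_network(cbind(as.character(edges_i), as.character(edges_j)),
                    nodes = as.character(seq_len(n)))
    ord <- match(igraph::V(g)$name, as.character(seq_len(n)))
    igraph::set_vertex_attr(
      igraph::set_vertex_attr(
        igraph::set_vertex_attr(g, "theta", value = theta[ord]),
        "radius", value = r_birth[ord]
      ),
      "community", value = comp[ord]
    )
  })
}

#' Standard synthetic benchmark parameter grids
#'
#' The parameter combinations over which the synthetic-network experiments
#' are run: sizes `n` in {1000, 5000, 10000} and half-degrees `k` in
#' {4, 6, ..., 14} for all three models, crossed with temperatures
#' `T` in {0.3, 0.5, 0.7} (at `gamma = 3`, `C = 8`) for nPSO and rewiring
#' probabilities `p` in {0.001, 0.01, 0.1} for Watts-Strogatz — 54 parameter
#' combinations each; 18 for Barabasi-Albert.
#'
#' @param model `"nPSO"`, `"WS"` or `"BA"`.
#' @return Data frame, one row per parameter combination.
#' @export
benchmark_grid <- function(model = c("nPSO", "WS", "BA")) {
  model <- match.arg(model)
  n <- c(1000, 5000, 10000)
  k <- seq(4, 14, by = 2)
  switch(model,
    nPSO = cbind(expand.grid(n = n, k = k, T = c(0.3, 0.5, 0.7),
                             KEEP.OUT.ATTRS = FALSE),
                 gamma = 3, C = 8),
    WS = expand.grid(n = n, k = k, p = c(0.001, 0.01, 0.1),
                     KEEP.OUT.ATTRS = FALSE),
    BA = expand.grid(n = n, k = k, KEEP.OUT.ATTRS = FALSE)
  )
}

#' Mean local clustering coefficient
#'
#' Average of the nodes' local clustering coefficients, with nodes of degree
#' below 2 counted as 0.
#'
#' @param g a network.
#' @return Numeric in `[0, 1]`.
#' @export
mean_clustering <- function(g) {
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}
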