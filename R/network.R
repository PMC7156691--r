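#' Build an undirected simple network from an edge table
#'
#' Networks are represented as undirected [igraph][igraph::igraph-package]
#' graphs with character vertex names. Construction enforces the simple-graph
#' contract used throughout the package: self-loops are dropped (with a
#' warning) and duplicate edges are collapsed, so every unordered node pair
#' appears at most once.
#'
#' @param edges two-column character matrix or data frame of endpoints; extra
#'   columns are ignored.
#' @param nodes optional character vector of node identifiers; must contain
#'   every endpoint. Nodes absent from `edges` become isolated nodes.
#' @return An undirected simple `igraph` object with `name` vertex attribute.
#' @examples
#' g <- as_network(cbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(g)
#' @export
as_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("`edges` needs at least two columns")
  a <- as.character(edges[, 1])
  b <- as.character(edges[, 2])
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    a <- a[!loops]
    b <- b[!loops]
  }
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[!dup]
  hi <- hi[!dup]
  ids <- unique(c(nodes, lo, hi))
  if (!is.null(nodes) && !all(c(lo, hi) %in% nodes)) {
    stop("`nodes` must contain every endpoint in `edges`")
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  g
}

#' Read a network from a plain-text edge list
#'
#' Parses the common two-column whitespace-delimited edge-list format (as
#' exported by most network and protein-interaction databases). Lines starting
#' with `#` and blank lines are skipped; columns beyond the first two are
#' ignored; the graph is always symmetrised. Node identifiers are kept as
#' opaque strings (gene symbols, accession numbers, ...), never coerced to
#' integers.
#'
#' @param path path to a readable text file.
#' @return An undirected simple `igraph` network.
#' @seealso [write_edge_list()], [as_network()]
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2)) {
    stop("parse error: line ", lineno[which(nt < 2)[1]],
         " has fewer than 2 fields")
  }
  if (length(toks) == 0) stop("edge list is empty: ", path)
  edges <- cbind(
    vapply(toks, `[[`, character(1), 1L),
    vapply(toks, `[[`, character(1), 2L)
  )
  as_network(edges)
}

#' Write a network as a two-column edge list
#'
#' Edges are written as `node_i<TAB>node_j` with the lexicographically smaller
#' endpoint first, sorted, so the output is canonical for a given edge set.
#'
#' @param g a network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  e <- network_edges(g)
  o <- order(e$i, e$j)
  utils::write.table(e[o, , drop = FALSE], path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Edge set of a network as a canonical data frame
#'
#' @param g a network.
#' @return Data frame with character columns `i`, `j`, one row per edge,
#'   `i < j` lexicographically.
#' @export
network_edges <- function(g) {
  ends <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(ends) == 0) {
    return(data.frame(i = character(), j = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    i = pmin(ends[, 1], ends[, 2]),
    j = pmax(ends[, 1], ends[, 2]),
    stringsAsFactors = FALSE
  )
}

#' Enumerate all candidate (non-adjacent) node pairs
#'
#' The candidate universe for link prediction: every unordered node pair that
#' is not an edge. Order is deterministic — lexicographic by `(i, j)` with
#' `i < j` — which fixes downstream tie handling and makes reruns
#' reproducible.
#'
#' @param g a network.
#' @return Data frame with character columns `i`, `j`; exactly
#'   `n(n-1)/2 - m` rows.
#' @examples
#' g <- fixture_triangle_pendant()
#' all_candidates(g) # pairs (1,4) and (2,4)
#' @export
all_candidates <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  n <- length(nodes)
  if (n < 2) {
    return(data.frame(i = character(), j = character(),
                      stringsAsFactors = FALSE))
  }
  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L, from = 2:n)
  e <- network_edges(g)
  ei <- match(e$i, nodes)
  ej <- match(e$j, nodes)
  ekey <- pmin(ei, ej) * (n + 1) + pmax(ei, ej) # numeric keys, no overflow
  keep <- !((ii * (n + 1) + jj) %in% ekey)
  data.frame(i = nodes[ii[keep]], j = nodes[jj[keep]],
             stringsAsFactors = FALSE)
}

#' Assemble a ranked score table
#'
#' A score table maps candidate node pairs to real-valued prediction scores
#' and carries an explicit ranking: rows are ordered by decreasing score, and
#' ties are broken by a seeded random shuffle so that no method gains a
#' systematic advantage from input order in top-k metrics. The row order *is*
#' the tie-break order used by [top_precision()] and [aupr()].
#'
#' @param pairs data frame or two-column matrix of node pairs.
#' @param scores numeric vector, one score per pair.
#' @param tie_seed integer seed for the tie-breaking shuffle.
#' @return Data frame of class `score_table` with columns `i`, `j`, `score`,
#'   ranked.
#' @export
score_table <- function(pairs, scores, tie_seed = 1L) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) != length(scores)) {
    stop("`scores` must have one value per pair")
  }
  if (any(!is.finite(scores))) stop("scores must be finite")
  tbl <- data.frame(
    i = pmin(as.character(pairs[[1]]), as.character(pairs[[2]])),
    j = pmax(as.character(pairs[[1]]), as.character(pairs[[2]])),
    score = as.numeric(scores),
    stringsAsFactors = FALSE
  )
  shuffle <- withr::with_seed(tie_seed, sample.int(nrow(tbl)))
  tbl <- tbl[order(-tbl$score, shuffle), , drop = FALSE]
  rownames(tbl) <- NULL
  class(tbl) <- c("score_table", "data.frame")
  tbl
}

#' Write a score table as tab-separated text
#'
#' One line per candidate pair, `node_i<TAB>node_j<TAB>score`, in the table's
#' ranked order (descending score, stored tie-break order).
#'
#' @param table a [score_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  utils::write.table(table[, c("i", "j", "score")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Deterministic fixture: triangle with a pendant node
#'
#' Four nodes `1..4`, edges 1-2, 1-3, 2-3, 3-4. The smallest graph on which
#' every ingredient of the predictor (popularity, neighbourhood attraction,
#' weighted horizon distances) is non-trivial; used throughout the tests.
#'
#' @return A network with n = 4, m = 4.
#' @export
fixture_triangle_pendant <- function() {
  as_network(cbind(c("1", "1", "2", "3"), c("2", "3", "3", "4")))
}

#' Deterministic fixture: star graph
#'
#' @param leaves number of leaf nodes attached to the hub `"0"`.
#' @return A star network; leaves are named `"1"`, `"2"`, ...
#' @export
fixture_star <- function(leaves = 3) {
  as_network(cbind("0", as.character(seq_len(leaves))))
}

# canonical "i\rj" key for unordered pairs given as character vectors
pair_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "\r")
}
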