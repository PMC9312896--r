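# Interactome handling: read BioGRID-style edge lists, reduce to a clean
# undirected simple graph on the largest connected component, and expose the
# normalized linear operators that drive diffusion.

#' Construct an interactome from an edge table
#'
#' Uppercases symbols, drops self-loops and duplicate (including reversed)
#' edges, and restricts to the largest connected component. Node order is
#' lexicographic, so the operator matrices are reproducible.
#'
#' @param edges two-column character matrix/data.frame of symbol pairs.
#' @return object of class `pbcnet_interactome` with fields `graph`
#'   (igraph), `nodes` (ordered symbols), `n_removed_self`,
#'   `n_removed_dup`, `n_removed_disconnected`.
#' @export
interactome <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop_validation("edge table must have two columns")
  if (!nrow(edges)) stop_validation("empty edge list")
  a <- toupper(trimws(edges[, 1]))
  b <- toupper(trimws(edges[, 2]))
  self <- a == b
  lo <- pmin(a, b)[!self]
  hi <- pmax(a, b)[!self]
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  lo <- lo[!dup]; hi <- hi[!dup]

  g <- igraph::graph_from_edgelist(cbind(lo, hi), directed = FALSE)
  comp <- igraph::components(g)
  biggest <- which.max(comp$csize)
  n_disc <- sum(comp$membership != biggest)
  g <- igraph::induced_subgraph(g, which(comp$membership == biggest))

  nodes <- sort(igraph::V(g)$name)
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))

  pbc_log("interactome", nodes = length(nodes), edges = igraph::ecount(g),
          self_loops = sum(self), dups = sum(dup), disconnected = n_disc)
  structure(
    list(graph = g, nodes = nodes,
         n_removed_self = sum(self), n_removed_dup = sum(dup),
         n_removed_disconnected = n_disc),
    class = "pbcnet_interactome"
  )
}

#' @export
print.pbcnet_interactome <- function(x, ...) {
  cat(sprintf("<pbcnet interactome: %d nodes, %d edges (largest component)>\n",
              length(x$nodes), igraph::ecount(x$graph)))
  invisible(x)
}

#' Read a tab-delimited PPI edge list
#'
#' Handles both the minimal fixture dialect (`symbol_a`/`symbol_b` header)
#' and real BioGRID TAB exports through `column_map`.
#'
#' @param path tab-delimited file with a header row.
#' @param column_map length-2 character vector naming the interactor
#'   columns; default the fixture dialect. For BioGRID TAB3 use
#'   `c("Official.Symbol.Interactor.A", "Official.Symbol.Interactor.B")`.
#' @return `pbcnet_interactome`.
#' @export
read_edge_list <- function(path, column_map = c("symbol_a", "symbol_b")) {
  if (!file.exists(path)) stop_validation(sprintf("edge file not found: %s", path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = TRUE)
  cols <- make.names(column_map)
  miss <- setdiff(cols, names(tab))
  if (length(miss)) {
    stop_validation(sprintf("edge list is missing column(s): %s",
                            paste(miss, collapse = ", ")))
  }
  interactome(tab[, cols])
}

#' Degree-normalized propagation operator
#'
#' Column-stochastic mode returns \eqn{W = A D^{-1}} (every column sums to
#' 1: a random-walk transition matrix), symmetric-degree mode returns
#' \eqn{D^{-1/2} A D^{-1/2}}. Sparse `Matrix` either way, rows/columns in
#' the interactome's node order.
#'
#' @param net `pbcnet_interactome`.
#' @param mode `"column-stochastic"` (default) or `"symmetric-degree"`.
#' @return `dgCMatrix` with attribute `normalization`.
#' @export
build_operator <- function(net, mode = c("column-stochastic", "symmetric-degree")) {
  stopifnot(inherits(net, "pbcnet_interactome"))
  mode <- match.arg(mode)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) stop_validation("isolated node in interactome")  # unreachable: connected
  W <- if (mode == "column-stochastic") {
    A %*% Matrix::Diagonal(x = 1 / deg)
  } else {
    d <- Matrix::Diagonal(x = 1 / sqrt(deg))
    d %*% A %*% d
  }
  W <- methods::as(W, "CsparseMatrix")
  dimnames(W) <- list(net$nodes, net$nodes)
  attr(W, "normalization") <- mode
  W
}

#' Write an interactome as a fixture-dialect edge list
#'
#' @param net `pbcnet_interactome`.
#' @param path output path (TSV, header `symbol_a<TAB>symbol_b`).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net$graph)
  el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("symbol_a\tsymbol_b", con)
  writeLines(paste(el[, 1], el[, 2], sep = "\t"), con)
  invisible(path)
}
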