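#' Social networks for cascade simulation
#'
#' A `social_network` is an undirected simple graph (no self-loops, no
#' multi-edges) stored as a sparse symmetric adjacency matrix together with
#' node degrees and generation metadata. `er_network()` draws an
#' Erdos-Renyi graph `G(N, ell)` in which every unordered node pair is
#' linked independently with probability `ell`; the mean degree is
#' `K = ell * (N - 1)`. Either `ell` or the target mean degree `K` may be
#' supplied (the two parameterisations differ slightly: e.g. `ell = 9e-5`
#' with `N = 1e5` gives `K = 9.0`, not 10).
#'
#' @param N number of nodes, at least 2.
#' @param K target mean degree, `0 < K < N - 1`; converted to
#'   `ell = K / (N - 1)`.
#' @param ell linking probability in `(0, 1]`; supply exactly one of `K`,
#'   `ell`.
#' @param seed RNG seed recorded in the metadata; `NULL` uses (and advances)
#'   the current RNG state.
#' @return an object of class `"social_network"` with fields `N`, `adj`
#'   (sparse symmetric 0/1 matrix), `degree` and `meta`.
#' @examples
#' net <- er_network(100, K = 5, seed = 1)
#' mean(net$degree)
#' @export
er_network <- function(N, K = NULL, ell = NULL, seed = NULL) {
  if (!is.numeric(N) || length(N) != 1L || N < 2)
    stop_tip("N must be a single count >= 2", "parameter_error")
  if (is.null(ell) == is.null(K))
    stop_tip("supply exactly one of K or ell", "parameter_error")
  if (is.null(ell)) {
    if (K <= 0 || K >= N) stop_tip("need 0 < K < N - 1", "parameter_error")
    ell <- K / (N - 1)
  }
  if (ell <= 0 || ell > 1)
    stop_tip("ell must lie in (0, 1]", "parameter_error")
  g <- with_seed(seed, igraph::sample_gnp(N, ell))
  net <- as_social_network(g)
  net$meta <- list(kind = "erdos-renyi", ell = ell, K = ell * (N - 1),
                   seed = seed)
  net
}

#' @rdname er_network
#' @param g an igraph graph (made undirected and simplified if necessary).
#' @export
as_social_network <- function(g) {
  g <- igraph::simplify(igraph::as_undirected(g, mode = "collapse"))
  adj <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  structure(list(N = igraph::vcount(g), adj = adj,
                 degree = Matrix::colSums(adj),
                 meta = list(kind = "custom")),
            class = "social_network")
}

#' @rdname er_network
#' @param edges two-column matrix of node ids (1-based) defining undirected
#'   edges; self-loops and duplicated edges are rejected.
#' @export
network_from_edges <- function(N, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > N))
      stop_tip("edge endpoints must lie in 1..N", "parameter_error")
    if (any(edges[, 1L] == edges[, 2L]))
      stop_tip("self-loops are not allowed", "parameter_error")
    key <- paste(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
    if (anyDuplicated(key))
      stop_tip("multi-edges are not allowed", "parameter_error")
  }
  adj <- Matrix::sparseMatrix(i = c(edges[, 1L], edges[, 2L]),
                              j = c(edges[, 2L], edges[, 1L]),
                              x = 1, dims = c(N, N))
  structure(list(N = N, adj = adj, degree = Matrix::colSums(adj),
                 meta = list(kind = "edge-list")),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  m <- sum(x$degree) / 2
  cat(sprintf("Social network: %d nodes, %d edges, mean degree %.3f (%s)\n",
              x$N, as.integer(m), mean(x$degree), x$meta$kind))
  invisible(x)
}

#' @rdname er_network
#' @param net a `social_network`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "social_network"))
  igraph::graph_from_adjacency_matrix(net$adj, mode = "undirected")
}

#' Read and write networks as plain-text edge lists
#'
#' The exchange format is a whitespace-delimited undirected edge list with
#' 0-based node ids, preceded by a one-line header `N <count>` (so isolated
#' nodes survive the round trip). `write_network()` can alternatively emit
#' GraphML via igraph.
#'
#' @param path file path.
#' @return `read_network()` returns a [social_network][er_network];
#'   `write_network()` returns `path`, invisibly.
#' @export
read_network <- function(path) {
  header <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1L]]
  if (length(header) != 2L || header[1L] != "N")
    stop_tip("edge-list file must start with a header line 'N <count>'",
             "parameter_error")
  N <- as.integer(header[2L])
  e <- utils::read.table(path, skip = 1L,
                         col.names = c("from", "to"),
                         colClasses = "integer")
  network_from_edges(N, as.matrix(e) + 1L)
}

#' @rdname read_network
#' @param net a [social_network][er_network].
#' @param format `"edgelist"` (default) or `"graphml"`.
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "social_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  tr <- as(Matrix::triu(net$adj), "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("N %d", net$N), con)
  if (length(tr@i))
    writeLines(paste(tr@i, tr@j), con)  # @i/@j are already 0-based
  invisible(path)
}
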