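#' Build an undirected protein interaction network from an edge table
#'
#' A `ppi_network` is a simple undirected graph over protein identifiers.
#' The first two columns of `x` are taken as interaction endpoints; any
#' further columns are carried along as per-edge metadata.  Duplicate pairs
#' (in either orientation) collapse to a single edge, keeping the metadata
#' of the first occurrence.  Self-pairs (a protein listed as interacting
#' with itself) are not stored as edges: they are kept in a separate
#' `self_pairs` table and excluded from degrees and from all overlap-score
#' sums, so that a protein's neighbourhood never contains the protein
#' itself.
#'
#' @param x A data frame whose first two columns hold protein IDs.
#'   IDs are treated as case-sensitive strings; surrounding whitespace is
#'   stripped.
#' @param nodes Optional character vector of additional node IDs to include
#'   (e.g. isolated proteins).  Endpoint IDs are always included.
#' @return A `ppi_network`: a list with elements `nodes` (character),
#'   `edges` (tibble with columns `from`, `to`, metadata), and
#'   `self_pairs` (tibble with column `protein`, metadata).  Edges are
#'   stored with `from < to` lexicographically.
#' @examples
#' as_ppi_network(data.frame(a = c("A", "B", "A"), b = c("B", "A", "C")))
#' @export
as_ppi_network <- function(x, nodes = NULL) {
  if (inherits(x, "ppi_network")) return(x)
  stopifnot(is.data.frame(x))
  if (ncol(x) < 2) {
    rlang::abort("edge table must have at least two ID columns")
  }
  from0 <- stringr::str_trim(as.character(x[[1]]))
  to0 <- stringr::str_trim(as.character(x[[2]]))
  if (anyNA(from0) || anyNA(to0) || any(from0 == "") || any(to0 == "")) {
    bad <- which(is.na(from0) | is.na(to0) | from0 == "" | to0 == "")[1]
    rlang::abort(paste0("missing protein ID in edge row ", bad))
  }
  meta <- tibble::as_tibble(x[, -(1:2), drop = FALSE])

  is_self <- from0 == to0
  self_pairs <- dplyr::bind_cols(
    tibble::tibble(protein = from0[is_self]),
    meta[is_self, , drop = FALSE]
  )
  self_pairs <- self_pairs[!duplicated(self_pairs$protein), , drop = FALSE]

  a <- pmin(from0[!is_self], to0[!is_self])
  b <- pmax(from0[!is_self], to0[!is_self])
  keep <- !duplicated(paste0(a, "\r", b))
  edges <- dplyr::bind_cols(
    tibble::tibble(from = a[keep], to = b[keep]),
    meta[!is_self, , drop = FALSE][keep, , drop = FALSE]
  )

  all_nodes <- sort(unique(c(from0, to0, as.character(nodes))))
  new_ppi_network(all_nodes, edges, self_pairs)
}

new_ppi_network <- function(nodes, edges, self_pairs = NULL) {
  if (is.null(self_pairs)) self_pairs <- tibble::tibble(protein = character())
  structure(
    list(nodes = nodes, edges = tibble::as_tibble(edges),
         self_pairs = tibble::as_tibble(self_pairs)),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("<ppi_network> ", length(x$nodes), " proteins, ", nrow(x$edges),
      " interactions", sep = "")
  if (nrow(x$self_pairs) > 0) {
    cat(" (+", nrow(x$self_pairs), " self-pairs)", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.ppi_network <- function(x, ...) x$edges

#' Number of nodes / edges of a network
#' @param net A `ppi_network`.
#' @return An integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Dense 0/1 adjacency matrix of a network
#'
#' Symmetric with a zero diagonal (self-pairs are never edges); rows and
#' columns follow `net$nodes` order.
#'
#' @param net A `ppi_network`.
#' @return A base numeric matrix with dimnames.
#' @export
adjacency_matrix <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (n_edges(net) > 0) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
}

#' Node degrees
#'
#' Self-pairs do not contribute to degree.
#'
#' @param net A `ppi_network`.
#' @return Named integer vector in `net$nodes` order; the sum equals twice
#'   the edge count.
#' @export
node_degrees <- function(net) {
  idx <- c(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
  deg <- tabulate(idx, nbins = n_nodes(net))
  names(deg) <- net$nodes
  deg
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("from", "to"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}

#' Global network statistics
#'
#' Density is `2|E| / (|V|(|V|-1))`.  The clustering coefficient is the
#' local clustering coefficient averaged over all nodes, with nodes of
#' degree < 2 contributing 0.  The average path length is the mean
#' shortest-path distance over connected ordered pairs only; on a
#' disconnected network unreachable pairs are excluded from the average
#' and the component count is reported alongside.
#'
#' @param net A `ppi_network` with at least one node (two for density).
#' @return A fraction (`network_density`, `avg_clustering`) or a positive
#'   number (`avg_path_length`).
#' @export
network_density <- function(net) {
  n <- n_nodes(net)
  if (n < 2) rlang::abort("density undefined for networks with < 2 nodes")
  2 * n_edges(net) / (n * (n - 1))
}

#' @rdname network_density
#' @export
avg_clustering <- function(net) {
  if (n_nodes(net) == 0) rlang::abort("empty network")
  cc <- igraph::transitivity(as_igraph(net), type = "local", isolates = "zero")
  mean(cc)
}

#' @rdname network_density
#' @export
avg_path_length <- function(net) {
  if (n_nodes(net) == 0) rlang::abort("empty network")
  igraph::mean_distance(as_igraph(net), directed = FALSE, unconnected = TRUE)
}

#' One-row summary of a network (Table-2-style)
#'
#' @param net A `ppi_network`.
#' @param fit_degree_exponent Fit the scale-free degree exponent as well?
#'   Needs at least three distinct positive degrees; `NA` if the fit is
#'   not possible.
#' @return A one-row tibble: protein and interaction counts, average path
#'   length, average clustering coefficient, density, component count and,
#'   optionally, the degree exponent.
#' @export
network_stats <- function(net, fit_degree_exponent = FALSE) {
  g <- as_igraph(net)
  out <- tibble::tibble(
    n_proteins = n_nodes(net),
    n_interactions = n_edges(net),
    avg_path_length = avg_path_length(net),
    avg_clustering = avg_clustering(net),
    density = network_density(net),
    n_components = igraph::count_components(g)
  )
  if (fit_degree_exponent) {
    deg <- node_degrees(net)
    out$degree_exponent <- tryCatch(
      fit_power_law(deg)$gamma,
      error = function(e) NA_real_
    )
  }
  out
}

#' @export
glance.ppi_network <- function(x, ...) network_stats(x)

#' @export
tidy.ppi_network <- function(x, ...) x$edges
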