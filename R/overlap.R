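#' Topological overlap matrix (TOM)
#'
#' For proteins i and j with adjacency `a_ij` and degrees `k_i`, `k_j`,
#'
#'   `TOM(i,j) = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#'
#' the number of shared interaction partners plus the direct interaction,
#' normalized by the smaller degree so that scores fall in \[0, 1\].  The
#' sum index excludes i and j themselves (self-pairs are never counted).
#' The diagonal is set to 1 by convention; a pair involving a
#' degree-zero protein scores 0.
#'
#' @param net A `ppi_network`.
#' @return A symmetric numeric matrix of class `overlap_matrix` in
#'   `net$nodes` order, entries in \[0, 1\], with attribute
#'   `model = "TOM"`.
#' @export
tom_matrix <- function(net) {
  A <- adjacency_matrix(net)
  k <- rowSums(A)
  # zero diagonal means A %*% A already sums over u outside {i, j}
  num <- A %*% A + A
  den <- outer(k, k, pmin) + 1 - A
  stopifnot(all(den >= 1))
  scores <- num / den
  diag(scores) <- 1
  new_overlap_matrix(scores, "TOM")
}

new_overlap_matrix <- function(scores, model) {
  stopifnot(isSymmetric(unname(scores)), all(scores >= 0), all(scores <= 1))
  structure(scores, class = c("overlap_matrix", "matrix", "array"),
            model = model)
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("<overlap_matrix> model=", attr(x, "model"), ", ", nrow(x),
      " proteins\n", sep = "")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Locational and topological overlap matrix (LTOM)
#'
#' Location-aware TOM: a shared partner u of proteins i and j only counts
#' if all three proteins are annotated to a common major location
#' (`sigma(i,u,j) = 1`), and the direct interaction only counts if i and
#' j co-localize (`sigma_prime(i,j) = 1`):
#'
#'   `LTOM(i,j) = (sum_u a_iu a_uj sigma(i,u,j) + a_ij sigma'(i,j)) /
#'                (min(k_i, k_j) + 1 - a_ij)`
#'
#' The denominator is unchanged from TOM, so `LTOM <= TOM` pointwise and
#' the two coincide when every protein shares every location.
#'
#' @param net A `ppi_network`.
#' @param loc A `localization_table`.
#' @param strict If `TRUE`, error when a network node has no location
#'   annotation.  Default `FALSE`: unannotated proteins get an empty
#'   location set, so every sigma involving them is 0 (co-localization is
#'   never fabricated).
#' @return A symmetric `overlap_matrix` with attribute `model = "LTOM"`.
#' @export
ltom_matrix <- function(net, loc, strict = FALSE) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  B <- location_matrix(loc, net$nodes)
  if (strict && any(rowSums(B) == 0)) {
    bad <- net$nodes[rowSums(B) == 0]
    rlang::abort(paste0("unannotated protein(s): ",
                        paste(utils::head(bad, 5), collapse = ", ")))
  }
  k <- rowSums(A)

  num <- matrix(0, n, n, dimnames = dimnames(A))
  # shared-partner term: for each candidate partner u, pairs of its
  # neighbours that co-localize with u and with each other
  for (u in seq_len(n)) {
    nb <- which(A[u, ] > 0)
    if (length(nb) < 2) next
    Bu <- B[nb, , drop = FALSE] & rep(B[u, ], each = length(nb))
    P <- (Bu %*% t(Bu)) > 0
    num[nb, nb] <- num[nb, nb] + P
  }
  diag(num) <- 0
  sig2 <- (B %*% t(B)) > 0
  num <- num + A * sig2

  den <- outer(k, k, pmin) + 1 - A
  stopifnot(all(den >= 1))
  scores <- num / den
  diag(scores) <- 1
  new_overlap_matrix(scores, "LTOM")
}

#' Three-way and pairwise co-localization indicators
#'
#' `sigma(i, u, j)` is 1 when proteins i, u and j are all annotated to at
#' least one common major location; `sigma_prime(i, j)` is the two-protein
#' special case.  Both are symmetric in i and j.
#'
#' @param i,u,j Protein IDs.
#' @param loc A `localization_table`.
#' @param strict Error on proteins missing from `loc` (default `FALSE`:
#'   missing proteins have empty location sets, hence sigma 0).
#' @return 0 or 1.
#' @export
sigma <- function(i, u, j, loc, strict = FALSE) {
  s <- location_sets(loc)
  get <- function(p) {
    v <- s[[p]]
    if (is.null(v)) {
      if (strict) rlang::abort(paste0("protein not annotated: ", p))
      character()
    } else v
  }
  common <- intersect(intersect(get(i), get(u)), get(j))
  as.integer(length(common) > 0)
}

#' @rdname sigma
#' @export
sigma_prime <- function(i, j, loc, strict = FALSE) {
  sigma(i, i, j, loc, strict = strict)
}

#' Impute high-overlap candidate interactions into a network
#'
#' Adds, as new edges, every non-adjacent protein pair whose overlap
#' score reaches `tau` (or the `top_k` highest-scoring non-adjacent
#' pairs).  No new proteins are recruited: the node set is unchanged.
#' Added edges carry `imputed = TRUE`; original edges `imputed = FALSE`.
#' Applying TOM scores yields the topologically imputed network (TOPIN),
#' LTOM scores the location-aware one (LTOPIN).
#'
#' @param net A `ppi_network` whose nodes index `scores`.
#' @param scores An `overlap_matrix` from [tom_matrix()] or
#'   [ltom_matrix()].
#' @param tau Score threshold in (0, 1]; default 0.5.  Ignored when
#'   `top_k` is given.
#' @param top_k Optionally, add exactly the k highest-scoring
#'   non-adjacent pairs instead of thresholding (ties broken by protein
#'   ID for determinism).
#' @param keep_base_edges Keep all original edges (default `TRUE`).
#' @return A `ppi_network` with an `imputed` edge metadata column.
#' @export
impute_network <- function(net, scores, tau = 0.5, top_k = NULL,
                           keep_base_edges = TRUE) {
  stopifnot(nrow(scores) == n_nodes(net),
            identical(rownames(scores), net$nodes))
  if (is.null(top_k) && tau <= 0) {
    rlang::abort("tau must be positive (tau <= 0 would add every pair sharing a neighbor)")
  }
  A <- adjacency_matrix(net)
  S <- unclass(scores)
  cand <- which(upper.tri(S) & A == 0, arr.ind = TRUE)
  sc <- S[cand]
  if (is.null(top_k)) {
    take <- sc >= tau
  } else {
    take <- rep(FALSE, length(sc))
    ord <- order(-sc, net$nodes[cand[, 1]], net$nodes[cand[, 2]])
    take[ord[seq_len(min(top_k, length(ord)))]] <- TRUE
  }
  added <- tibble::tibble(
    from = pmin(net$nodes[cand[take, 1]], net$nodes[cand[take, 2]]),
    to = pmax(net$nodes[cand[take, 1]], net$nodes[cand[take, 2]]),
    score = sc[take],
    imputed = TRUE
  )
  base <- if (keep_base_edges) net$edges else net$edges[0, , drop = FALSE]
  if (nrow(base) > 0) {
    base$score <- S[cbind(match(base$from, net$nodes), match(base$to, net$nodes))]
    base$imputed <- FALSE
  }
  edges <- dplyr::bind_rows(base, added)
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  new_ppi_network(net$nodes, edges, net$self_pairs)
}

#' Export an overlap matrix as TSV
#'
#' @param scores An `overlap_matrix`.
#' @param path Output path.
#' @param shape `"long"` (node1, node2, score; upper triangle only) or
#'   `"square"` (full matrix with header row and column).
#' @return `path`, invisibly.
#' @export
write_overlap_tsv <- function(scores, path, shape = c("long", "square")) {
  shape <- match.arg(shape)
  if (shape == "square") {
    df <- data.frame(protein = rownames(scores), unclass(scores),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(scores), arr.ind = TRUE)
    df <- data.frame(
      node1 = rownames(scores)[idx[, 1]],
      node2 = colnames(scores)[idx[, 2]],
      score = scores[idx]
    )
    df <- df[order(df$node1, df$node2), , drop = FALSE]
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
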