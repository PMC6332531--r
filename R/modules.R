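#' Cohesiveness of a candidate module
#'
#' `f(V) = w_in(V) / (w_in(V) + w_bound(V) + p * |V|)` where `w_in`
#' counts edges with both endpoints inside V, `w_bound` counts edges with
#' exactly one endpoint inside, and `p * |V|` penalizes each member for
#' interactions that may simply not have been observed yet (network
#' incompleteness).
#'
#' @param members Character vector of protein IDs (nonempty, all network
#'   nodes).
#' @param net A `ppi_network`.
#' @param p Per-member penalty, `>= 0` (default 2, the usual greedy
#'   clusterer default).
#' @return Cohesiveness in \[0, 1\].
#' @examples
#' tri <- as_ppi_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
#' cohesiveness(c("A", "B", "C"), tri, p = 2)  # 3 / (3 + 0 + 6)
#' @export
cohesiveness <- function(members, net, p = 2) {
  if (length(members) == 0) rlang::abort("empty member set")
  stopifnot(p >= 0, all(members %in% net$nodes))
  inside <- net$edges$from %in% members
  inside_to <- net$edges$to %in% members
  w_in <- sum(inside & inside_to)
  w_bound <- sum(xor(inside, inside_to))
  w_in / (w_in + w_bound + p * length(members))
}

#' Internal edge density of a member set
#' @inheritParams cohesiveness
#' @return Fraction of the `|V|(|V|-1)/2` possible internal edges
#'   present; 0 for singletons.
#' @export
module_density <- function(members, net) {
  m <- length(members)
  if (m < 2) return(0)
  w_in <- sum(net$edges$from %in% members & net$edges$to %in% members)
  w_in / (m * (m - 1) / 2)
}

new_module_set <- function(members, net, p, algorithm, parameters) {
  members <- lapply(members, function(m) sort(m))
  out <- tibble::tibble(
    module_id = paste0("M", seq_along(members)),
    members = members,
    size = lengths(members),
    density = vapply(members, module_density, numeric(1), net = net),
    cohesiveness = vapply(members, cohesiveness, numeric(1), net = net, p = p)
  )
  class(out) <- c("module_set", class(out))
  attr(out, "algorithm") <- algorithm
  attr(out, "parameters") <- parameters
  out
}

#' Detect modules by cohesiveness-guided greedy growth
#'
#' A simplified overlapping-neighbourhood clusterer: each node not yet
#' covered by a module seeds a cluster (seeds processed in descending
#' degree, ties broken lexicographically by ID); the cluster repeatedly
#' takes the single vertex addition or removal that most increases its
#' cohesiveness, stopping at a local maximum; finally, clusters whose
#' overlap score `omega = |A\&B|^2 / (|A||B|)` reaches
#' `overlap_merge_threshold` are merged.  Output modules may overlap and
#' always have at least two members.  The procedure is fully
#' deterministic.
#'
#' @param net A nonempty `ppi_network`.
#' @param p Cohesiveness penalty (default 2).
#' @param overlap_merge_threshold Merge threshold for omega (default 0.8).
#' @return A `module_set`: tibble with `module_id`, `members`
#'   (list-column), `size`, `density`, `cohesiveness`; attributes
#'   `algorithm` and `parameters`.
#' @export
detect_modules_greedy <- function(net, p = 2, overlap_merge_threshold = 0.8) {
  if (n_nodes(net) == 0) rlang::abort("empty network")
  nodes <- net$nodes
  n <- length(nodes)
  A <- adjacency_matrix(net)
  deg <- rowSums(A)
  seed_order <- order(-deg, nodes)

  covered <- rep(FALSE, n)
  clusters <- list()
  for (s in seed_order) {
    if (covered[s]) next
    cl <- grow_cluster(s, A, deg, p)
    covered[cl] <- TRUE
    if (length(cl) >= 2) clusters[[length(clusters) + 1]] <- cl
  }
  clusters <- merge_overlapping(clusters, overlap_merge_threshold)
  members <- unique(lapply(clusters, function(ix) sort(nodes[ix])))
  new_module_set(members, net, p, "greedy",
                 list(p = p, overlap_merge_threshold = overlap_merge_threshold))
}

# greedy local search over single-vertex moves; returns node indices
grow_cluster <- function(seed, A, deg, p) {
  n <- nrow(A)
  in_cl <- rep(FALSE, n)
  in_cl[seed] <- TRUE
  # e_in[v]: edges from v into the current cluster
  e_in <- A[, seed]
  w_in <- 0
  w_bound <- deg[seed]
  size <- 1
  f <- function(wi, wb, sz) if (wi + wb + p * sz == 0) 0 else wi / (wi + wb + p * sz)
  cur <- f(w_in, w_bound, size)
  repeat {
    add_cand <- which(!in_cl & e_in > 0)
    best_f <- cur
    best_v <- 0L
    best_is_add <- TRUE
    consider <- function(v, is_add) {
      if (is_add) {
        val <- f(w_in + e_in[v], w_bound - e_in[v] + (deg[v] - e_in[v]), size + 1)
      } else {
        val <- f(w_in - e_in[v],
                 w_bound + e_in[v] - (deg[v] - e_in[v]), size - 1)
      }
      val
    }
    for (v in add_cand) {
      val <- consider(v, TRUE)
      if (val > best_f + 1e-12) { best_f <- val; best_v <- v; best_is_add <- TRUE }
    }
    if (size > 1) {
      for (v in which(in_cl)) {
        # e_in[v] includes v's own edges into the cluster (v excluded by
        # the zero diagonal of A)
        val <- consider(v, FALSE)
        if (val > best_f + 1e-12) { best_f <- val; best_v <- v; best_is_add <- FALSE }
      }
    }
    if (best_v == 0L) break
    v <- best_v
    if (best_is_add) {
      w_in <- w_in + e_in[v]
      w_bound <- w_bound - e_in[v] + (deg[v] - e_in[v])
      size <- size + 1
      in_cl[v] <- TRUE
      e_in <- e_in + A[, v]
    } else {
      w_in <- w_in - e_in[v]
      w_bound <- w_bound + e_in[v] - (deg[v] - e_in[v])
      size <- size - 1
      in_cl[v] <- FALSE
      e_in <- e_in - A[, v]
    }
    cur <- best_f
  }
  which(in_cl)
}

# iteratively merge index-set clusters whose overlap score reaches thr
merge_overlapping <- function(clusters, thr) {
  if (length(clusters) < 2) return(clusters)
  repeat {
    merged <- FALSE
    best <- c(0, 0)
    best_w <- thr - 1e-12
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        ov <- length(intersect(clusters[[i]], clusters[[j]]))
        w <- ov^2 / (length(clusters[[i]]) * length(clusters[[j]]))
        if (w > best_w) { best_w <- w; best <- c(j, i); merged <- TRUE }
      }
    }
    if (!merged) break
    u <- sort(union(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- u
    if (length(clusters) < 2) break
  }
  clusters
}

#' Detect modules by Markov clustering (MCL)
#'
#' Random-walk flow clustering on the column-stochastic transition matrix:
#' alternate expansion (matrix squaring) and inflation (entrywise power
#' `inflation` followed by column renormalization) until the matrix
#' changes by less than `tol`, then read the hard clusters off the
#' converged flow's connectivity.  Self-loops are added before
#' normalization, the standard device that prevents period-2 oscillation
#' on bipartite structures; entries below `prune` are zeroed after each
#' inflation for tractability.
#'
#' @param net A nonempty `ppi_network`.
#' @param inflation Inflation exponent, > 1 (default 2).
#' @param max_iter Iteration cap (default 100); hitting it raises a
#'   warning and returns the current clustering.
#' @param tol Convergence tolerance on the max entry change (default 1e-6).
#' @param prune Entries below this are zeroed after inflation (default 1e-8).
#' @param p Penalty used only to report cohesiveness of the clusters.
#' @return A `module_set` of hard, non-overlapping clusters (singleton
#'   clusters are not reported).
#' @export
detect_modules_mcl <- function(net, inflation = 2, max_iter = 100,
                               tol = 1e-6, prune = 1e-8, p = 2) {
  if (n_nodes(net) == 0) rlang::abort("empty network")
  if (inflation <= 1) rlang::abort("inflation must be > 1")
  A <- adjacency_matrix(net)
  M <- A + diag(nrow(A))
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < prune] <- 0
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    rlang::warn("MCL did not converge within max_iter; returning current clustering")
  }
  # clusters = connected components of the converged flow's support
  supp <- (M + t(M)) > sqrt(.Machine$double.eps)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  members <- split(net$nodes, comp)
  members <- members[lengths(members) >= 2]
  members <- unname(members[order(vapply(members, min, character(1)))])
  new_module_set(members, net, p, "mcl",
                 list(inflation = inflation, max_iter = max_iter,
                      tol = tol, prune = prune))
}

#' Filter a module set by size and density
#'
#' Keeps modules with at least `min_size` members and internal density at
#' least `min_density`.  The defaults (10 and 0.25) reproduce the usual
#' reporting convention for dense protein modules; both bounds are
#' inclusive.
#'
#' @param mods A `module_set`.
#' @param min_size Minimum member count (default 10).
#' @param min_density Minimum internal density (default 0.25).
#' @return The filtered `module_set` (attributes preserved).
#' @export
filter_modules <- function(mods, min_size = 10, min_density = 0.25) {
  keep <- mods$size >= min_size & mods$density >= min_density
  out <- mods[keep, , drop = FALSE]
  class(out) <- class(mods)
  attr(out, "algorithm") <- attr(mods, "algorithm")
  attr(out, "parameters") <- attr(mods, "parameters")
  out
}

#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x),
    median_size = if (nrow(x)) stats::median(x$size) else NA_real_,
    mean_density = if (nrow(x)) mean(x$density) else NA_real_,
    mean_cohesiveness = if (nrow(x)) mean(x$cohesiveness) else NA_real_,
    algorithm = attr(x, "algorithm") %||% NA_character_
  )
}

#' @export
tidy.module_set <- function(x, ...) {
  tidyr::unnest(x[, c("module_id", "members")], "members") |>
    dplyr::rename(protein = "members")
}

#' Plot module size against internal density
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot object (size vs density, coloured by cohesiveness).
#' @export
autoplot.module_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$size, y = .data$density,
                                       colour = .data$cohesiveness)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "module size", y = "internal density",
                  colour = "cohesiveness")
}
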