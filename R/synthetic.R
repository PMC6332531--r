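#' Specification for a synthetic localization-annotated network
#'
#' Describes a planted-module benchmark: dense location-coherent modules
#' on a sparse Bernoulli background, emulating the structure the
#' co-localization analysis assumes (interacting proteins tend to share a
#' compartment; complexes are dense and compartment-coherent).
#'
#' @param n_proteins Total proteins (default 300).
#' @param n_modules Planted (disjoint) modules (default 6).
#' @param module_size_range Inclusive size range per module (default
#'   10-15).
#' @param p_in Within-module edge probability (default 0.6).
#' @param p_out Background edge probability for all other pairs (default
#'   0.01); must not exceed `p_in`.
#' @param n_locations Number of major locations in play, at most 6
#'   (default 6).
#' @param loc_coherence Probability that a module member carries its
#'   module's home location (default 0.9).
#' @param labels_per_protein_range Range of location labels per protein
#'   (default 1-2).
#' @param scale_free_background If `TRUE`, background edges come from a
#'   preferential-attachment graph instead of Bernoulli pairs, giving a
#'   heavy-tailed degree distribution for power-law-fit tests.
#' @param seed RNG seed; fully determines the output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_proteins = 300, n_modules = 6,
                           module_size_range = c(10, 15),
                           p_in = 0.6, p_out = 0.01,
                           n_locations = 6, loc_coherence = 0.9,
                           labels_per_protein_range = c(1, 2),
                           scale_free_background = FALSE,
                           seed = 42) {
  stopifnot(p_out >= 0, p_in <= 1, p_out <= p_in,
            n_locations >= 1, n_locations <= length(major_locations),
            loc_coherence >= 0, loc_coherence <= 1,
            length(module_size_range) == 2,
            module_size_range[1] >= 2,
            module_size_range[1] <= module_size_range[2],
            labels_per_protein_range[1] >= 1,
            labels_per_protein_range[2] <= n_locations)
  if (n_modules * module_size_range[2] > n_proteins) {
    rlang::abort("module sizes exceed the number of proteins")
  }
  structure(
    list(n_proteins = n_proteins, n_modules = n_modules,
         module_size_range = module_size_range, p_in = p_in, p_out = p_out,
         n_locations = n_locations, loc_coherence = loc_coherence,
         labels_per_protein_range = labels_per_protein_range,
         scale_free_background = scale_free_background, seed = seed),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic network with planted, location-coherent modules
#'
#' Produces a network, its localization table, the planted modules as a
#' reference complex catalog (ground truth), and a gene set consisting of
#' the first planted module's members (for enrichment tests).  Every
#' protein is annotated with at least one location.  Output is a pure
#' function of the spec, including its seed (Mersenne-Twister, no global
#' RNG state disturbed).
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `network` (`ppi_network`), `localization`
#'   (`localization_table`), `catalog` (`complex_catalog` of the planted
#'   modules), `gene_set` (character), and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(
    spec$seed, .rng_kind = "Mersenne-Twister",
    .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection",
    {
      n <- spec$n_proteins
      ids <- sprintf("P%03d", seq_len(n))
      sizes <- sample(seq(spec$module_size_range[1],
                          spec$module_size_range[2]),
                      spec$n_modules, replace = TRUE)
      pool <- sample(ids, sum(sizes))
      members <- split(pool, rep(seq_along(sizes), sizes))
      module_of <- rep(0L, n)
      for (m in seq_along(members)) module_of[match(members[[m]], ids)] <- m

      # edges: within-module Bernoulli(p_in), everything else background
      pairs <- utils::combn(n, 2)
      same <- module_of[pairs[1, ]] == module_of[pairs[2, ]] &
        module_of[pairs[1, ]] > 0
      draw <- stats::runif(ncol(pairs))
      keep_in <- same & draw < spec$p_in
      if (spec$scale_free_background) {
        g <- igraph::sample_pa(n, m = 2, directed = FALSE)
        bg <- igraph::as_edgelist(g)
        bgkey <- paste(pmin(bg[, 1], bg[, 2]), pmax(bg[, 1], bg[, 2]))
        keep_out <- !same & paste(pairs[1, ], pairs[2, ]) %in% bgkey
      } else {
        keep_out <- !same & draw < spec$p_out
      }
      sel <- keep_in | keep_out
      edges <- tibble::tibble(from = ids[pairs[1, sel]],
                              to = ids[pairs[2, sel]])

      # locations: module members carry the module's home location with
      # probability loc_coherence; everyone gets labels_per_protein
      # labels in total, extras drawn uniformly
      locs <- major_locations[seq_len(spec$n_locations)]
      home <- locs[(seq_along(members) - 1L) %% length(locs) + 1L]
      n_labels <- sample(
        seq(spec$labels_per_protein_range[1],
            spec$labels_per_protein_range[2]),
        n, replace = TRUE
      )
      loc_list <- vector("list", n)
      for (v in seq_len(n)) {
        first <- if (module_of[v] > 0 &&
                     stats::runif(1) < spec$loc_coherence) {
          home[module_of[v]]
        } else {
          sample(locs, 1)
        }
        extra <- setdiff(locs, first)
        k <- min(n_labels[v] - 1L, length(extra))
        loc_list[[v]] <- c(first,
                           if (k > 0) sample(extra, k) else character())
      }
      loc <- localization_table(tibble::tibble(
        protein = rep(ids, lengths(loc_list)),
        location = unlist(loc_list)
      ))

      list(
        network = as_ppi_network(edges, nodes = ids),
        localization = loc,
        catalog = complex_catalog(
          paste0("planted", seq_along(members)), members
        ),
        gene_set = sort(members[[1]]),
        spec = spec
      )
    }
  )
}

#' Five-protein toy network illustrating the location-aware overlap score
#'
#' Proteins A and B interact and share three partners P1, P2, P3.  P1 and
#' P3 co-localize with both A and B (nucleus) but P2 does not: it shares
#' a compartment with A (cytoplasm) and with B (membrane) separately, yet
#' the three proteins have no common location.  Hence TOM(A,B) = 1 while
#' LTOM(A,B) = 3/4: the P2 shared-partner term is suppressed.
#'
#' @return List with `network` (`ppi_network`, 5 nodes / 7 edges) and
#'   `localization` (`localization_table`).
#' @export
fig2_fixture <- function() {
  edges <- tibble::tibble(
    from = c("A", "A", "A", "A", "B", "B", "B"),
    to = c("B", "P1", "P2", "P3", "P1", "P2", "P3")
  )
  loc <- localization_table(tibble::tibble(
    protein = c("A", "A", "B", "B", "P1", "P2", "P2", "P3"),
    location = c("nucleus", "cytoplasm", "nucleus", "membrane",
                 "nucleus", "cytoplasm", "membrane", "nucleus")
  ))
  list(network = as_ppi_network(edges), localization = loc)
}
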