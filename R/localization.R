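#' Canonical major subcellular locations
#'
#' The six compartments every localization table is reduced to:
#' nucleus, cytoplasm, membrane, extracellular, mitochondria and the
#' secretory pathway (Golgi apparatus, endoplasmic reticulum, endosome,
#' peroxisome, lysosome, vacuole and vesicles merged into one label).
#'
#' @format Character vector of length 6.
#' @export
major_locations <- c(
  "nucleus", "cytoplasm", "membrane", "extracellular",
  "mitochondria", "secretory-pathway"
)

#' Raw-to-major location merge map
#'
#' Reads the mapping from the 12 raw compartment labels to the six major
#' locations.  The map is shipped as YAML so alternative compartment
#' schemes can be supplied; major labels always map to themselves, making
#' re-application of the map a no-op.
#'
#' @param path Path to a YAML file mapping raw label -> major label.
#'   Default: the map shipped with the package.
#' @return Named character vector (names are raw labels, values major
#'   labels).
#' @export
location_merge_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "location_merge_map.yaml",
                        package = "loctom", mustWork = TRUE)
  }
  raw <- yaml::read_yaml(path)
  map <- vapply(raw, as.character, character(1))
  if (!all(map %in% major_locations)) {
    bad <- setdiff(unique(map), major_locations)
    rlang::abort(paste0("merge map targets unknown major location(s): ",
                        paste(bad, collapse = ", ")))
  }
  # majors are fixed points so the merge is idempotent
  map[major_locations] <- major_locations
  map
}

#' Build a localization table
#'
#' Normalizes a (protein, location) table to major locations.  Input may
#' list several rows per protein; the result has one row per distinct
#' (protein, major location) pair.
#'
#' @param x Data frame with columns `protein` and `location` (or the
#'   first two columns, in that order).
#' @param merge_map Named character vector from [location_merge_map()].
#' @param unknown What to do with a location label absent from the map:
#'   `"error"` (default; names the label) or `"drop"` (drops the rows with
#'   a warning counting them).
#' @return A tibble of class `localization_table` with columns `protein`
#'   and `location`, every `location` one of [major_locations].
#' @export
localization_table <- function(x, merge_map = location_merge_map(),
                               unknown = c("error", "drop")) {
  unknown <- match.arg(unknown)
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  nm <- names(x)
  pcol <- if ("protein" %in% nm) "protein" else nm[1]
  lcol <- if ("location" %in% nm) "location" else nm[2]
  tab <- tibble::tibble(
    protein = stringr::str_trim(as.character(x[[pcol]])),
    location = stringr::str_trim(as.character(x[[lcol]]))
  )
  hit <- tab$location %in% names(merge_map)
  if (!all(hit)) {
    bad <- unique(tab$location[!hit])
    if (unknown == "error") {
      rlang::abort(paste0("unknown location label(s): ",
                          paste(bad, collapse = ", ")))
    }
    rlang::warn(paste0("dropping ", sum(!hit),
                       " row(s) with unknown location label(s): ",
                       paste(bad, collapse = ", ")))
    tab <- tab[hit, , drop = FALSE]
  }
  tab$location <- unname(merge_map[tab$location])
  tab <- dplyr::distinct(tab)
  class(tab) <- c("localization_table", class(tab))
  tab
}

#' Per-protein location sets
#' @param loc A `localization_table`.
#' @return Named list mapping protein ID to a character vector of major
#'   locations.
#' @export
location_sets <- function(loc) {
  split(loc$location, loc$protein)
}

# proteins x locations logical membership matrix (the localization
# matrix L with entries b_ij); proteins absent from `loc` get all-FALSE
# rows (lenient policy: no co-localization is ever fabricated)
location_matrix <- function(loc, proteins) {
  B <- matrix(FALSE, length(proteins), length(major_locations),
              dimnames = list(proteins, major_locations))
  keep <- loc$protein %in% proteins
  B[cbind(match(loc$protein[keep], proteins),
          match(loc$location[keep], major_locations))] <- TRUE
  B
}

#' Restrict a network to co-localized interactions (CLPIN)
#'
#' Keeps exactly the edges whose two endpoints share at least one major
#' location.  Edges with one or both endpoints unannotated are removed
#' (an unannotated protein shares no location with anything).
#'
#' @param net A `ppi_network` (the global network, GPIN).
#' @param loc A `localization_table`; must be nonempty.
#' @param drop_unannotated If `TRUE` (default), nodes left without any
#'   edge are dropped, so the co-localized network shrinks in proteins as
#'   well as interactions; if `FALSE` the node set is preserved.
#' @return A `ppi_network` whose edge set is a subset of `net`'s.
#' @export
build_clpin <- function(net, loc, drop_unannotated = TRUE) {
  if (!is.data.frame(loc) || nrow(loc) == 0) {
    rlang::abort("localization table is empty")
  }
  sets <- location_sets(loc)
  f <- sets[net$edges$from]
  t <- sets[net$edges$to]
  keep <- purrr::map2_lgl(f, t, function(a, b) {
    !is.null(a) && !is.null(b) && any(a %in% b)
  })
  edges <- net$edges[keep, , drop = FALSE]
  nodes <- if (drop_unannotated) {
    sort(unique(c(edges$from, edges$to)))
  } else {
    net$nodes
  }
  self <- net$self_pairs[net$self_pairs$protein %in% nodes, , drop = FALSE]
  new_ppi_network(nodes, edges, self)
}

#' Fraction of co-localized interactions in a network
#'
#' @param net A `ppi_network` with at least one edge.
#' @param loc A `localization_table`.
#' @return Fraction in \[0, 1\]: edges whose endpoints share a major
#'   location, over all edges.
#' @export
coloc_ratio <- function(net, loc) {
  if (n_edges(net) == 0) rlang::abort("network has no edges")
  n_edges(build_clpin(net, loc, drop_unannotated = TRUE)) / n_edges(net)
}

#' Fraction of edges with a metadata flag set
#'
#' @param net A `ppi_network` with at least one edge.
#' @param flag_column Name of a logical/0-1 edge metadata column (e.g. an
#'   in-vivo evidence flag).
#' @return Fraction of edges whose flag is truthy.
#' @export
flag_ratio <- function(net, flag_column) {
  if (n_edges(net) == 0) rlang::abort("network has no edges")
  if (!flag_column %in% names(net$edges)) {
    rlang::abort(paste0("edge metadata column not found: ", flag_column))
  }
  mean(as.logical(as.numeric(net$edges[[flag_column]])))
}
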