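#' Read a protein interaction edge list
#'
#' Accepts whitespace- or tab-delimited files with two ID columns and any
#' number of trailing metadata columns (e.g. PubMed counts, in-vivo
#' flags, weights).  Lines starting with `#` and blank lines are skipped.
#'
#' @param path File path.
#' @param header Does the first (non-comment) line carry column names?
#' @param id_columns Indices of the two endpoint columns (default 1:2).
#' @return A [ppi_network][as_ppi_network] with metadata attached to edges.
#' @export
read_edge_list <- function(path, header = FALSE, id_columns = 1:2) {
  rows <- read_token_lines(path)
  if (length(rows$tokens) == 0) rlang::abort(paste0("empty edge list: ", path))
  col_names <- NULL
  if (header) {
    col_names <- rows$tokens[[1]]
    rows$tokens <- rows$tokens[-1]
    rows$lineno <- rows$lineno[-1]
  }
  nfield <- lengths(rows$tokens)
  if (any(nfield < max(id_columns))) {
    bad <- rows$lineno[which(nfield < max(id_columns))[1]]
    rlang::abort(paste0("malformed edge line ", bad, " in ", path,
                        ": fewer than ", max(id_columns), " columns"))
  }
  ncol <- min(nfield)
  df <- as.data.frame(
    lapply(seq_len(ncol), function(k) {
      vapply(rows$tokens, `[[`, character(1), k)
    }),
    stringsAsFactors = FALSE
  )
  names(df) <- if (!is.null(col_names)) {
    col_names[seq_len(ncol)]
  } else {
    c("node1", "node2", paste0("meta", seq_len(max(0, ncol - 2))))[seq_len(ncol)]
  }
  df <- df[, c(id_columns, setdiff(seq_len(ncol), id_columns)), drop = FALSE]
  meta_cols <- setdiff(seq_len(ncol(df)), 1:2)
  for (k in meta_cols) df[[k]] <- utils::type.convert(df[[k]], as.is = TRUE)
  as_ppi_network(df)
}

# shared line reader: drops comments/blanks, splits on runs of space/tab,
# keeps original line numbers for error messages
read_token_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  list(
    tokens = lapply(lines[keep], function(l) {
      strsplit(stringr::str_trim(l), "[ \t]+")[[1]]
    }),
    lineno = lineno[keep]
  )
}

#' Write a network as an edge list
#'
#' Tab-separated with a header; metadata columns (including the `imputed`
#' tag of imputed networks) are preserved.  Self-pairs are appended as
#' `protein TAB protein` rows so a read/write round trip preserves the
#' node and edge sets exactly.
#'
#' @param net A `ppi_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  ed <- net$edges
  if (nrow(net$self_pairs) > 0) {
    sp <- net$self_pairs
    names(sp)[1] <- "from"
    sp$to <- sp$from
    ed <- dplyr::bind_rows(ed, sp)
  }
  iso <- setdiff(net$nodes, unique(c(ed$from, ed$to)))
  if (length(iso) > 0) {
    ed <- dplyr::bind_rows(ed, tibble::tibble(from = iso, to = iso))
  }
  names(ed)[1:2] <- c("node1", "node2")
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein localization table
#'
#' Two columns per line: protein ID and a raw or major location label.
#' Multi-word labels ("plasma membrane", "Golgi apparatus", ...) must be
#' tab-separated from the protein ID.  Applies the merge map via
#' [localization_table()].
#'
#' @inheritParams localization_table
#' @param path File path.
#' @return A `localization_table` tibble.
#' @export
read_localization <- function(path, merge_map = location_merge_map(),
                              unknown = c("error", "drop")) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  if (length(lines) == 0) rlang::abort(paste0("empty localization file: ", path))
  # split on the first tab if present, otherwise the first whitespace run,
  # so multi-word labels survive
  has_tab <- grepl("\t", lines)
  protein <- ifelse(has_tab, sub("\t.*$", "", lines), sub("[ \t].*$", "", lines))
  location <- ifelse(has_tab, sub("^[^\t]*\t", "", lines), sub("^[^ \t]*[ \t]+", "", lines))
  df <- tibble::tibble(protein = protein, location = location)
  if (tolower(df$location[1]) == "location") df <- df[-1, , drop = FALSE]
  localization_table(df, merge_map = merge_map, unknown = unknown)
}

#' @export
write_localization <- function(loc, path) {
  utils::write.table(loc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a reference complex catalog
#'
#' One complex per line: an optional complex ID followed by the member
#' protein IDs, whitespace- or tab-separated.  Complexes outside the size
#' window are excluded; the defaults (3 to 100 members) match the usual
#' benchmark convention of ignoring trivial dimers and giant categories.
#'
#' @param path File path.
#' @param min_size,max_size Inclusive size window (defaults 3 and 100).
#' @param has_id Is the first token on each line a complex ID (default
#'   `TRUE`)?  If `FALSE`, complexes are numbered `C1`, `C2`, ...
#' @return A `complex_catalog`: tibble with columns `complex_id`,
#'   `members` (list of character vectors) and `size`.
#' @export
read_complex_catalog <- function(path, min_size = 3, max_size = 100,
                                 has_id = TRUE) {
  rows <- read_token_lines(path)
  if (length(rows$tokens) == 0) {
    rlang::abort(paste0("empty complex catalog: ", path))
  }
  ids <- if (has_id) {
    vapply(rows$tokens, `[[`, character(1), 1)
  } else {
    paste0("C", seq_along(rows$tokens))
  }
  members <- lapply(rows$tokens, function(tok) {
    unique(if (has_id) tok[-1] else tok)
  })
  complex_catalog(ids, members, min_size = min_size, max_size = max_size)
}

#' Construct a complex catalog from IDs and member sets
#' @param complex_id Character vector of complex IDs.
#' @param members List of character vectors (one per complex).
#' @inheritParams read_complex_catalog
#' @return A `complex_catalog` tibble.
#' @export
complex_catalog <- function(complex_id, members, min_size = 1,
                            max_size = Inf) {
  stopifnot(length(complex_id) == length(members))
  members <- lapply(members, function(m) unique(as.character(m)))
  if (any(lengths(members) == 0)) {
    rlang::abort("every complex needs at least one member")
  }
  out <- tibble::tibble(
    complex_id = as.character(complex_id),
    members = members,
    size = lengths(members)
  )
  out <- out[out$size >= min_size & out$size <= max_size, , drop = FALSE]
  class(out) <- c("complex_catalog", class(out))
  out
}

#' @export
write_complex_catalog <- function(catalog, path) {
  lines <- purrr::map2_chr(catalog$complex_id, catalog$members,
                           function(id, m) paste(c(id, m), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene/protein set (one ID per line)
#'
#' Blank lines and `#` comments are skipped; duplicates are removed.
#' An empty file yields an empty set with a warning.
#'
#' @param path File path.
#' @return Character vector of unique IDs.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- stringr::str_trim(lines)
  lines <- lines[!grepl("^(#|$)", lines)]
  ids <- unique(lines)
  if (length(ids) == 0) rlang::warn(paste0("gene set is empty: ", path))
  ids
}

#' Read / write a detected module set
#'
#' TSV with columns `module_id`, `size`, `density`, `cohesiveness` and
#' comma-joined `members`.
#'
#' @param path File path.
#' @return A `module_set` tibble (see [detect_modules_greedy()]).
#' @export
read_module_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- tibble::tibble(
    module_id = as.character(df$module_id),
    members = strsplit(df$members, ","),
    size = as.integer(df$size),
    density = as.numeric(df$density),
    cohesiveness = as.numeric(df$cohesiveness)
  )
  class(out) <- c("module_set", class(out))
  out
}

#' @rdname read_module_set
#' @param mods A `module_set`.
#' @export
write_module_set <- function(mods, path) {
  df <- data.frame(
    module_id = mods$module_id,
    size = mods$size,
    density = mods$density,
    cohesiveness = mods$cohesiveness,
    members = vapply(mods$members, paste, character(1), collapse = ",")
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
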