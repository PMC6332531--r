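#' Pipeline stage runners
#'
#' File-level wrappers chaining the package end to end: filter a global
#' network to its co-localized subnetwork, impute overlap-scored
#' candidate edges, cluster, then evaluate against a complex catalog and
#' test gene-set enrichment.  Each stage writes its primary artifact plus
#' a JSON provenance record (input checksums, effective parameters,
#' package version); primary outputs are byte-identical across re-runs
#' with the same inputs and configuration, timestamps live only in the
#' provenance files.
#'
#' `config` is a named list (or path to a YAML file) with any of:
#' `edge_list`, `localization`, `merge_map`, `complex_catalog`,
#' `gene_set` (input paths); `out_dir`; `model` ("ltom" or "tom");
#' `tau`; `algo` ("greedy" or "mcl"); `p`, `inflation`; `min_size`,
#' `min_density`; `min_complex_size`, `max_complex_size`; `cutoff`;
#' `seed`; `synth` (a list of [synthetic_spec()] arguments).  Unset keys
#' fall back to the package defaults documented on the underlying
#' functions.
#'
#' @param config Named list or YAML path.
#' @return Each runner returns its primary result invisibly;
#'   `loctom_run()` returns a named list of all stage results.
#' @name pipeline
NULL

default_config <- function() {
  list(model = "ltom", tau = 0.5, algo = "greedy", p = 2, inflation = 2,
       min_size = 10, min_density = 0.25, min_complex_size = 3,
       max_complex_size = 100, cutoff = 0.01, drop_unannotated = TRUE,
       seed = 42, out_dir = ".")
}

#' @rdname pipeline
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out <- utils::modifyList(default_config(), config)
  stopifnot(out$model %in% c("tom", "ltom"),
            out$algo %in% c("greedy", "mcl"),
            out$tau > 0)
  out
}

write_provenance <- function(cfg, inputs, outputs, stage) {
  inputs <- Filter(function(p) is.character(p) && all(file.exists(p)), inputs)
  rec <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("loctom")),
    timestamp = format(Sys.time(), tz = "UTC"),
    parameters = cfg,
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    outputs = outputs
  )
  path <- file.path(cfg$out_dir, paste0(stage, ".provenance.json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

prep_out <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg
}

load_inputs <- function(cfg) {
  net <- read_edge_list(cfg$edge_list, header = isTRUE(cfg$header))
  map <- if (!is.null(cfg$merge_map)) {
    location_merge_map(cfg$merge_map)
  } else {
    location_merge_map()
  }
  loc <- read_localization(cfg$localization, merge_map = map)
  list(net = net, loc = loc)
}

#' @rdname pipeline
#' @export
loctom_filter <- function(config) {
  cfg <- prep_out(read_run_config(config))
  inp <- load_inputs(cfg)
  clpin <- build_clpin(inp$net, inp$loc,
                       drop_unannotated = isTRUE(cfg$drop_unannotated))
  out <- file.path(cfg$out_dir, "clpin.tsv")
  write_edge_list(clpin, out)
  write_provenance(cfg, list(cfg$edge_list, cfg$localization), out, "filter")
  invisible(clpin)
}

#' @rdname pipeline
#' @export
loctom_impute <- function(config) {
  cfg <- prep_out(read_run_config(config))
  inp <- load_inputs(cfg)
  clpin <- build_clpin(inp$net, inp$loc,
                       drop_unannotated = isTRUE(cfg$drop_unannotated))
  scores <- if (cfg$model == "tom") {
    tom_matrix(clpin)
  } else {
    ltom_matrix(clpin, inp$loc)
  }
  net2 <- impute_network(clpin, scores, tau = cfg$tau, top_k = cfg$top_k)
  out <- file.path(cfg$out_dir, paste0(cfg$model, "_imputed.tsv"))
  write_edge_list(net2, out)
  write_provenance(cfg, list(cfg$edge_list, cfg$localization), out, "impute")
  invisible(net2)
}

cluster_network <- function(net, cfg) {
  if (cfg$algo == "mcl") {
    detect_modules_mcl(net, inflation = cfg$inflation, p = cfg$p)
  } else {
    detect_modules_greedy(net, p = cfg$p)
  }
}

#' @rdname pipeline
#' @export
loctom_cluster <- function(config) {
  cfg <- prep_out(read_run_config(config))
  net <- read_edge_list(cfg$edge_list, header = isTRUE(cfg$header))
  mods <- cluster_network(net, cfg)
  mods <- filter_modules(mods, cfg$min_size, cfg$min_density)
  out <- file.path(cfg$out_dir, "modules.tsv")
  write_module_set(mods, out)
  write_provenance(cfg, list(cfg$edge_list), out, "cluster")
  invisible(mods)
}

#' @rdname pipeline
#' @export
loctom_evaluate <- function(config) {
  cfg <- prep_out(read_run_config(config))
  mods <- read_module_set(cfg$modules)
  ref <- read_complex_catalog(cfg$complex_catalog,
                              min_size = cfg$min_complex_size,
                              max_size = cfg$max_complex_size)
  res <- sn_ppv_acc(mods, ref)
  out <- file.path(cfg$out_dir, "evaluation.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(res), file.path(cfg$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, list(cfg$modules, cfg$complex_catalog), out,
                   "evaluate")
  invisible(res)
}

#' @rdname pipeline
#' @export
loctom_enrich <- function(config) {
  cfg <- prep_out(read_run_config(config))
  mods <- read_module_set(cfg$modules)
  genes <- read_gene_set(cfg$gene_set)
  net <- read_edge_list(cfg$edge_list, header = isTRUE(cfg$header))
  enr <- module_enrichment(mods, genes, n_nodes(net), cutoff = cfg$cutoff)
  rep <- ors_report(mods, genes, net, cutoff = cfg$cutoff)
  out <- file.path(cfg$out_dir, "enrichment.tsv")
  utils::write.table(enr, out, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(rep), file.path(cfg$out_dir, "ors.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(cfg, list(cfg$modules, cfg$gene_set, cfg$edge_list),
                   out, "enrich")
  invisible(rep)
}

#' @rdname pipeline
#' @export
loctom_stats <- function(config) {
  cfg <- prep_out(read_run_config(config))
  net <- read_edge_list(cfg$edge_list, header = isTRUE(cfg$header))
  res <- network_stats(net, fit_degree_exponent = TRUE)
  out <- file.path(cfg$out_dir, "stats.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(cfg, list(cfg$edge_list), out, "stats")
  invisible(res)
}

#' @rdname pipeline
#' @export
loctom_synth <- function(config) {
  cfg <- prep_out(read_run_config(config))
  args <- cfg$synth %||% list()
  if (!is.null(cfg$seed) && is.null(args$seed)) args$seed <- cfg$seed
  spec <- do.call(synthetic_spec, args)
  syn <- generate_synthetic(spec)
  paths <- list(
    edge_list = file.path(cfg$out_dir, "synthetic_edges.tsv"),
    localization = file.path(cfg$out_dir, "synthetic_localization.tsv"),
    complex_catalog = file.path(cfg$out_dir, "synthetic_complexes.tsv"),
    gene_set = file.path(cfg$out_dir, "synthetic_gene_set.txt")
  )
  write_edge_list(syn$network, paths$edge_list)
  write_localization(syn$localization, paths$localization)
  write_complex_catalog(syn$catalog, paths$complex_catalog)
  writeLines(syn$gene_set, paths$gene_set)
  write_provenance(c(cfg, list(spec = unclass(spec))), list(), paths, "synth")
  invisible(syn)
}

#' @rdname pipeline
#' @export
loctom_run <- function(config) {
  cfg <- prep_out(read_run_config(config))
  inp <- load_inputs(cfg)
  clpin <- build_clpin(inp$net, inp$loc,
                       drop_unannotated = isTRUE(cfg$drop_unannotated))
  write_edge_list(clpin, file.path(cfg$out_dir, "clpin.tsv"))
  scores <- if (cfg$model == "tom") {
    tom_matrix(clpin)
  } else {
    ltom_matrix(clpin, inp$loc)
  }
  imputed <- impute_network(clpin, scores, tau = cfg$tau, top_k = cfg$top_k)
  write_edge_list(imputed, file.path(cfg$out_dir,
                                     paste0(cfg$model, "_imputed.tsv")))
  mods <- cluster_network(imputed, cfg)
  filtered <- filter_modules(mods, cfg$min_size, cfg$min_density)
  write_module_set(mods, file.path(cfg$out_dir, "modules_all.tsv"))
  write_module_set(filtered, file.path(cfg$out_dir, "modules.tsv"))
  results <- list(clpin = clpin, imputed = imputed, modules = mods,
                  modules_filtered = filtered)
  if (!is.null(cfg$complex_catalog)) {
    ref <- read_complex_catalog(cfg$complex_catalog,
                                min_size = cfg$min_complex_size,
                                max_size = cfg$max_complex_size)
    results$evaluation <- sn_ppv_acc(mods, ref)
    utils::write.table(results$evaluation,
                       file.path(cfg$out_dir, "evaluation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(cfg$gene_set)) {
    genes <- read_gene_set(cfg$gene_set)
    results$enrichment <- ors_report(mods, genes, imputed,
                                     cutoff = cfg$cutoff)
    jsonlite::write_json(as.list(results$enrichment),
                         file.path(cfg$out_dir, "ors.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_provenance(cfg,
                   list(cfg$edge_list, cfg$localization,
                        cfg$complex_catalog, cfg$gene_set),
                   list.files(cfg$out_dir, pattern = "\\.(tsv|json)$"),
                   "run")
  invisible(results)
}
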