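#' Pipeline run configuration
#'
#' Declarative description of one analysis run: input paths, walk parameters,
#' scoring and mechanism options, output directory, and the RNG seed. All
#' referenced paths are checked before any computation. A config can be built
#' in code or loaded from YAML with [load_run_config()].
#'
#' @param inputs named list of paths: `pp`, `pf`, `ff`, `herb_compound`,
#'   `compound_target`, `disease`; optionally `gmt`, `deg`, `similarity`,
#'   `gene_map`.
#' @param out_dir output directory.
#' @param params an [rwr_params()] or a named list of its fields.
#' @param min_components herb filter threshold (default 3).
#' @param method correlation method (default `"pearson"`).
#' @param alpha overlap significance threshold (default 0.05).
#' @param universe_N overlap universe size (default: network protein count).
#' @param overlap_from_top_n optional capped overlap denominator.
#' @param mechanism_k top-k for mechanism extraction (default 20).
#' @param lfc_min,deg_alpha DEG thresholds (defaults 1.0 and 0.05).
#' @param similarity_cutoff summary-score cutoff (default 80).
#' @param top_m compounds reported per herb (default 5).
#' @param excluded_association_types,excluded_evidence disease curation
#'   filters.
#' @param seed RNG seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(inputs = list(), out_dir = ".",
                       params = rwr_params(), min_components = 3,
                       method = "pearson", alpha = 0.05, universe_N = NULL,
                       overlap_from_top_n = NULL, mechanism_k = 20,
                       lfc_min = 1.0, deg_alpha = 0.05,
                       similarity_cutoff = 80, top_m = 5,
                       excluded_association_types = character(),
                       excluded_evidence = character(), seed = 1L) {
  if (!inherits(params, "rwr_params")) params <- do.call(rwr_params, params)
  structure(list(inputs = inputs, out_dir = out_dir, params = params,
                 min_components = min_components, method = method,
                 alpha = alpha, universe_N = universe_N,
                 overlap_from_top_n = overlap_from_top_n,
                 mechanism_k = mechanism_k, lfc_min = lfc_min,
                 deg_alpha = deg_alpha,
                 similarity_cutoff = similarity_cutoff, top_m = top_m,
                 excluded_association_types = excluded_association_types,
                 excluded_evidence = excluded_evidence,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file; keys mirror [run_config()] arguments, with `params`
#'   a mapping of [rwr_params()] fields.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), names(formals(run_config)))]
  do.call(run_config, args)
}

.require_inputs <- function(config, keys) {
  missing <- setdiff(keys, names(config$inputs))
  if (length(missing)) {
    stop("run_config is missing input paths: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (k in keys) {
    if (!file.exists(config$inputs[[k]])) {
      stop("input file not found: ", config$inputs[[k]], call. = FALSE)
    }
  }
  invisible(TRUE)
}

# manifest: config hash, package version, input checksums. No timestamps so
# identical runs produce byte-identical output trees.
.write_manifest <- function(config, out_dir, extra = list()) {
  cfg_json <- jsonlite::toJSON(
    list(inputs = config$inputs, params = unclass(config$params),
         options = config[setdiff(names(config),
                                  c("inputs", "params", "out_dir"))]),
    auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  inputs <- config$inputs[vapply(config$inputs, file.exists, logical(1))]
  manifest <- c(list(
    config_md5 = cfg_hash,
    package = "herbnet",
    version = as.character(utils::packageVersion("herbnet")),
    seed = config$seed,
    input_md5 = as.list(vapply(inputs, function(p) unname(tools::md5sum(p)),
                               character(1)))), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

.load_pipeline_inputs <- function(config) {
  .require_inputs(config, c("pp", "pf", "ff", "herb_compound",
                            "compound_target", "disease"))
  network <- load_network(config$inputs$pp, config$inputs$pf,
                          config$inputs$ff)
  catalog <- load_catalog(config$inputs$herb_compound,
                          config$inputs$compound_target,
                          gene_map_path = config$inputs$gene_map)
  catalog <- filter_herbs(catalog, config$min_components)
  disease <- load_disease_genes(
    config$inputs$disease,
    excluded_association_types = config$excluded_association_types,
    excluded_evidence = config$excluded_evidence)
  list(network = network, catalog = catalog, disease = disease)
}

#' Pipeline command: generate a synthetic fixture directory
#'
#' @param config a `run_config`; its seed feeds [synthetic_config()].
#' @param synth optional [synthetic_config()] overriding the default study
#'   conditions (the seed still comes from `config`).
#' @return invisibly, the [generate_fixtures()] result.
#' @export
cmd_simulate <- function(config, synth = NULL) {
  if (is.null(synth)) synth <- synthetic_config(seed = config$seed)
  synth$seed <- as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_fixtures(synth, config$out_dir)
  .write_manifest(config, config$out_dir,
                  extra = list(planted_herb = fx$planted))
  invisible(fx)
}

#' Pipeline command: prioritize herbs
#'
#' catalog -> diffusion -> scoring; writes `prioritization.tsv` (display
#' precision), `prioritization.json` (full precision), and a manifest.
#'
#' @param config a `run_config`.
#' @return the `prioritization` data frame, invisibly.
#' @export
cmd_prioritize <- function(config) {
  inp <- .load_pipeline_inputs(config)
  records <- prioritize(inp$catalog, inp$disease, inp$network,
                        params = config$params, method = config$method,
                        universe_N = config$universe_N, alpha = config$alpha,
                        overlap_from_top_n = config$overlap_from_top_n)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_prioritization(records,
                       file.path(config$out_dir, "prioritization.tsv"),
                       file.path(config$out_dir, "prioritization.json"))
  .write_manifest(config, config$out_dir)
  invisible(records)
}

#' Pipeline command: rank a herb's compounds
#'
#' @param config a `run_config`.
#' @param herb herb id.
#' @return the compound `prioritization` data frame, invisibly.
#' @export
cmd_compounds <- function(config, herb) {
  inp <- .load_pipeline_inputs(config)
  records <- prioritize_compounds(inp$catalog, herb, inp$disease,
                                  inp$network, params = config$params,
                                  method = config$method,
                                  universe_N = config$universe_N,
                                  alpha = config$alpha,
                                  top_m = config$top_m)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_prioritization(
    records, file.path(config$out_dir, paste0("compounds_", herb, ".tsv")),
    file.path(config$out_dir, paste0("compounds_", herb, ".json")))
  .write_manifest(config, config$out_dir)
  invisible(records)
}

#' Pipeline command: extract and export a mechanism subnetwork
#'
#' `entity` may be a herb (herb-level mechanism from its pooled targets) or a
#' compound id. Writes GraphML, Cytoscape JSON, and a TSV edge list.
#'
#' @param config a `run_config`.
#' @param entity herb or compound id.
#' @return the `mechanism_subnetwork`, invisibly.
#' @export
cmd_mechanism <- function(config, entity) {
  inp <- .load_pipeline_inputs(config)
  tr <- build_transition(inp$network, config$params)
  seeds <- if (entity %in% inp$catalog$herbs) {
    herb_seed(inp$catalog, entity, inp$network)
  } else {
    compound_seed(inp$catalog, entity, inp$network)
  }
  if (is.null(seeds)) stop("entity has no on-network targets", call. = FALSE)
  eprof <- diffusion_profile(inp$network, seeds, config$params,
                             transition = tr)
  dprof <- diffusion_profile(inp$network,
                             disease_seed(inp$disease, inp$network),
                             config$params, transition = tr)
  mech <- extract_mechanism(eprof, dprof, inp$network,
                            compound_targets = seeds$genes,
                            disease_genes = inp$disease$records$gene,
                            k = config$mechanism_k)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(config$out_dir, paste0("mechanism_", entity))
  export_subnetwork(mech, paste0(base, ".graphml"), "graphml")
  export_subnetwork(mech, paste0(base, ".cyjs"), "cytoscape-json")
  export_subnetwork(mech, paste0(base, ".tsv"), "tsv")
  .write_manifest(config, config$out_dir)
  invisible(mech)
}

#' Pipeline command: over-representation analysis of a gene list
#'
#' @param config a `run_config` with a `gmt` input.
#' @param gene_list_path one gene id per line.
#' @param universe optional background; defaults to the union of the
#'   library's genes.
#' @return the `enrichment` data frame, invisibly.
#' @export
cmd_enrich <- function(config, gene_list_path, universe = NULL) {
  .require_inputs(config, "gmt")
  lib <- read_gmt(config$inputs$gmt)
  genes <- readLines(gene_list_path, warn = FALSE)
  genes <- trimws(genes[nzchar(trimws(genes))])
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(lib$terms, `[[`, "genes")))
  }
  rec <- ora(intersect(genes, universe), lib, universe, alpha = config$alpha)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_enrichment(rec, file.path(config$out_dir, "enrichment.tsv"))
  .write_manifest(config, config$out_dir)
  invisible(rec)
}

#' Pipeline command: DEG filtering and enrichment
#'
#' @param config a `run_config` with a `deg` input (and optionally `gmt` and
#'   `similarity`).
#' @return list with `up`, `down`, optional `similar` (retained similarity
#'   records) and `enrichment`, invisibly.
#' @export
cmd_deg <- function(config) {
  .require_inputs(config, "deg")
  tab <- load_deg_table(config$inputs$deg)
  degs <- deg_filter(tab, lfc_min = config$lfc_min, alpha = config$deg_alpha)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(degs$up, file.path(config$out_dir, "deg_up.txt"))
  writeLines(degs$down, file.path(config$out_dir, "deg_down.txt"))
  out <- degs
  if (!is.null(config$inputs$similarity) &&
      file.exists(config$inputs$similarity)) {
    sim <- similarity_filter(load_similarity(config$inputs$similarity),
                             cutoff = config$similarity_cutoff)
    .write_tsv(sim, file.path(config$out_dir, "similar_compounds.tsv"))
    out$similar <- sim
  }
  if (!is.null(config$inputs$gmt) && file.exists(config$inputs$gmt)) {
    lib <- read_gmt(config$inputs$gmt)
    universe <- tab$gene
    enr <- deg_enrich(degs, lib, universe, alpha = config$alpha)
    write_enrichment(enr, file.path(config$out_dir, "deg_enrichment.tsv"))
    out$enrichment <- enr
  }
  .write_manifest(config, config$out_dir)
  invisible(out)
}

#' Pipeline command: validate the multiscale network inputs
#'
#' @param config a `run_config`.
#' @return the [validate_network()] report, invisibly; also written as JSON.
#' @export
cmd_validate_network <- function(config) {
  .require_inputs(config, c("pp", "pf", "ff"))
  net <- load_network(config$inputs$pp, config$inputs$pf, config$inputs$ff)
  rep <- validate_network(net)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(rep, file.path(config$out_dir, "network_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .write_manifest(config, config$out_dir)
  invisible(rep)
}
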