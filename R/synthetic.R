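#' Configuration of the synthetic benchmark generator
#'
#' Defines the study conditions the generator emulates: a scale-free
#' protein-protein layer, a layered function hierarchy with Poisson
#' annotations, a densified disease module planted in the protein layer, a
#' herb catalog with one graph-proximal "effective" herb among decoys, and a
#' DEG table with spiked genes. All randomness flows from the single `seed`
#' through named substreams (network / disease / catalog / deg) so each part
#' can be regenerated independently.
#'
#' @param n_proteins protein count (default 200).
#' @param pp_m edges added per node by preferential attachment (default 2).
#' @param pp_power preferential-attachment exponent (default 1, linear).
#' @param n_functions biological-function count (default 40).
#' @param hierarchy_depth number of hierarchy levels; 1 means no ff edges
#'   (default 3).
#' @param annotation_mean Poisson mean of annotations per protein (default 2).
#' @param disease_size disease module size (default 15).
#' @param disease_density target internal pp edge density of the module
#'   (default 0.30).
#' @param n_herbs herb count including the planted one (default 20).
#' @param compounds_per_herb compounds per herb (default 5).
#' @param targets_per_compound targets per compound (default 4).
#' @param p_in probability a planted-herb target falls in the disease module
#'   or its immediate pp neighborhood (default 0.8).
#' @param p_bg same probability for decoy herbs (default 0.05); `p_in > p_bg`
#'   for a well-posed benchmark, equality is the negative control.
#' @param n_genes background gene count of the DEG table (default 2000).
#' @param n_spiked spiked (truly differential) genes (default 100).
#' @param spike_effect minimum absolute log2 fold-change of spiked genes
#'   (default 2.0); null genes draw log2fc from Normal(0, 0.3).
#' @param spike_p_max upper bound of spiked adjusted p (default 0.009, below
#'   the conventional 0.05 cutoff); null p is Uniform(0, 1).
#' @param seed master RNG seed.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 200, pp_m = 2, pp_power = 1,
                             n_functions = 40, hierarchy_depth = 3,
                             annotation_mean = 2,
                             disease_size = 15, disease_density = 0.30,
                             n_herbs = 20, compounds_per_herb = 5,
                             targets_per_compound = 4,
                             p_in = 0.8, p_bg = 0.05,
                             n_genes = 2000, n_spiked = 100,
                             spike_effect = 2.0, spike_p_max = 0.009,
                             seed = 1L) {
  cfg <- list(n_proteins = n_proteins, pp_m = pp_m, pp_power = pp_power,
              n_functions = n_functions, hierarchy_depth = hierarchy_depth,
              annotation_mean = annotation_mean, disease_size = disease_size,
              disease_density = disease_density, n_herbs = n_herbs,
              compounds_per_herb = compounds_per_herb,
              targets_per_compound = targets_per_compound,
              p_in = p_in, p_bg = p_bg, n_genes = n_genes,
              n_spiked = n_spiked, spike_effect = spike_effect,
              spike_p_max = spike_p_max, seed = as.integer(seed))
  stopifnot(n_proteins >= 1, n_functions >= 0, hierarchy_depth >= 1,
            disease_size >= 1, n_herbs >= 1, compounds_per_herb >= 1,
            targets_per_compound >= 1,
            p_in >= 0, p_in <= 1, p_bg >= 0, p_bg <= 1,
            annotation_mean >= 0)
  structure(cfg, class = "synthetic_config")
}

# named substreams derived from the master seed; spacing keeps streams for
# consecutive master seeds distinct, and everything stays below 2^31
.sub_seed <- function(seed, stream) {
  offset <- c(network = 11L, disease = 23L, catalog = 37L, deg = 53L)[[stream]]
  as.integer((as.numeric(seed) * 64 + offset) %% .Machine$integer.max)
}

.pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2, nchar(n)), "d"), seq_len(n))
}

#' Generate a synthetic multiscale network
#'
#' Protein layer: connected scale-free graph by preferential attachment.
#' Function layer: levels 1 (leaves) to `hierarchy_depth` (roots); each
#' non-root function gets one or two parents at the next level, giving a
#' child-to-parent DAG. Annotations: each protein annotates Poisson-many
#' functions. Deterministic given the config seed.
#'
#' @param config a [synthetic_config()].
#' @return a [msnet()].
#' @export
generate_network <- function(config) {
  withr::with_seed(.sub_seed(config$seed, "network"), {
    g <- igraph::sample_pa(config$n_proteins, power = config$pp_power,
                           m = config$pp_m, directed = FALSE)
    prot <- .pad_ids("P", config$n_proteins)
    el <- igraph::as_edgelist(g)
    pp <- data.frame(from = prot[as.integer(el[, 1])],
                     to = prot[as.integer(el[, 2])],
                     stringsAsFactors = FALSE)
    fn <- .pad_ids("F", config$n_functions)
    ff <- NULL
    level <- integer(0)
    if (config$n_functions > 0) {
      level <- sort(rep_len(seq_len(config$hierarchy_depth),
                            config$n_functions))
      if (config$hierarchy_depth > 1) {
        ff_rows <- list()
        for (l in seq_len(config$hierarchy_depth - 1)) {
          kids <- fn[level == l]
          parents <- fn[level == l + 1]
          if (length(parents) == 0) next
          for (kid in kids) {
            np <- 1 + stats::rbinom(1, 1, 0.3)
            ff_rows[[kid]] <- data.frame(
              child = kid,
              parent = sample(parents, min(np, length(parents))),
              stringsAsFactors = FALSE)
          }
        }
        if (length(ff_rows)) ff <- do.call(rbind, ff_rows)
      }
    }
    pf <- NULL
    if (config$n_functions > 0 && config$annotation_mean > 0) {
      pf_rows <- lapply(prot, function(p) {
        na <- min(stats::rpois(1, config$annotation_mean),
                  config$n_functions)
        if (na == 0) return(NULL)
        data.frame(protein = p, fn = sample(fn, na), stringsAsFactors = FALSE)
      })
      pf <- do.call(rbind, pf_rows)
    }
    net <- msnet(pp = pp, pf = pf, ff = ff, proteins = prot, functions = fn)
    attr(net, "function_levels") <- setNames(level, fn)
    net
  })
}

#' Plant a densified disease module in the protein layer
#'
#' Grows a connected protein subset of the configured size by random
#' neighborhood expansion, then adds internal pp edges until the module's
#' internal density reaches `disease_density`. Because densification adds
#' edges, the (new) network is returned together with the gene set.
#'
#' @param network a [msnet()].
#' @param config a [synthetic_config()].
#' @param seed optional override of the disease substream seed.
#' @return list with `network` (updated [msnet()]) and `disease`
#'   (a `disease_gene_set` labeled "synthetic-disease").
#' @export
plant_disease <- function(network, config, seed = NULL) {
  if (is.null(seed)) seed <- .sub_seed(config$seed, "disease")
  withr::with_seed(seed, {
    m <- min(config$disease_size, length(network$proteins))
    module <- sample(network$proteins, 1)
    while (length(module) < m) {
      frontier <- setdiff(
        unique(unlist(lapply(module, function(x)
          node_neighbors(network, x)$protein))),
        module)
      if (length(frontier) == 0) {
        frontier <- setdiff(network$proteins, module)
      }
      module <- c(module, sample(frontier, 1))
    }
    module <- sort(module)
    # densify internal wiring
    have <- network$pp[network$pp$from %in% module &
                         network$pp$to %in% module, , drop = FALSE]
    want <- ceiling(config$disease_density * m * (m - 1) / 2)
    add_n <- want - nrow(have)
    pp <- network$pp
    if (add_n > 0) {
      all_pairs <- t(utils::combn(module, 2))
      key <- paste(all_pairs[, 1], all_pairs[, 2])
      missing <- all_pairs[!key %in% paste(have$from, have$to), ,
                           drop = FALSE]
      pick <- missing[sample(nrow(missing), min(add_n, nrow(missing))), ,
                      drop = FALSE]
      pp <- rbind(pp, data.frame(from = pick[, 1], to = pick[, 2],
                                 stringsAsFactors = FALSE))
    }
    net2 <- msnet(pp = pp, pf = network$pf, ff = network$ff,
                  proteins = network$proteins, functions = network$functions)
    attr(net2, "function_levels") <- attr(network, "function_levels")
    list(network = net2,
         disease = disease_gene_set(module, disease = "synthetic-disease"))
  })
}

#' Generate a herb catalog with one planted effective herb
#'
#' Every herb gets `compounds_per_herb` compounds with
#' `targets_per_compound` targets each. With probability `p_in` (planted
#' herb) or `p_bg` (decoys) a target is drawn proximal to the disease: a
#' uniformly chosen disease-module gene, kept as-is or replaced by one of its
#' direct pp interactors with equal chance, so proximal draws concentrate on
#' the module core and its first shell. All other draws are uniform over the
#' proteins. Setting `p_in = p_bg` yields the negative-control catalog in
#' which the planted label is statistically meaningless.
#'
#' @param network a [msnet()] (after [plant_disease()]).
#' @param disease the planted `disease_gene_set`.
#' @param config a [synthetic_config()].
#' @param seed optional override of the catalog substream seed.
#' @return list with `catalog` (a [herb_catalog()]) and `planted` (the
#'   effective herb's id).
#' @export
generate_catalog <- function(network, disease, config, seed = NULL) {
  if (is.null(seed)) seed <- .sub_seed(config$seed, "catalog")
  withr::with_seed(seed, {
    module <- intersect(disease$records$gene, network$proteins)
    nbrs_of <- lapply(setNames(module, module), function(x)
      node_neighbors(network, x)$protein)
    # an in-draw lands on a disease gene, or steps to one of its direct
    # interactors: "inside or adjacent", weighted toward the module core
    draw_proximal <- function(n) {
      vapply(seq_len(n), function(i) {
        g <- sample(module, 1)
        if (stats::runif(1) < 0.5 || length(nbrs_of[[g]]) == 0) g
        else sample(nbrs_of[[g]], 1)
      }, character(1))
    }
    herbs <- .pad_ids("H", config$n_herbs)
    planted <- sample(herbs, 1)
    compounds_of <- list()
    targets_of <- list()
    ci <- 0L
    for (h in herbs) {
      p_hit <- if (h == planted) config$p_in else config$p_bg
      comp_ids <- character(config$compounds_per_herb)
      for (j in seq_len(config$compounds_per_herb)) {
        ci <- ci + 1L
        cid <- sprintf("C%04d", ci)
        comp_ids[j] <- cid
        n_t <- config$targets_per_compound
        inside <- stats::runif(n_t) < p_hit
        tg <- character(n_t)
        if (any(inside)) {
          tg[inside] <- draw_proximal(sum(inside))
        }
        if (any(!inside)) {
          tg[!inside] <- sample(network$proteins, sum(!inside),
                                replace = TRUE)
        }
        targets_of[[cid]] <- unique(tg)
      }
      compounds_of[[h]] <- comp_ids
    }
    list(catalog = herb_catalog(compounds_of, targets_of), planted = planted)
  })
}

#' Generate a DEG table with spiked genes
#'
#' Background genes draw log2 fold-changes from Normal(0, 0.3) and adjusted
#' p from Uniform(0, 1); spiked genes get `|log2fc| >= spike_effect` (random
#' sign) and adjusted p below `spike_p_max`. The spiked ids are recorded as
#' ground truth in `attr(, "spiked")`.
#'
#' @param config a [synthetic_config()].
#' @param seed optional override of the deg substream seed.
#' @return a [deg_table()] with attribute `spiked`.
#' @export
generate_deg_table <- function(config, seed = NULL) {
  if (is.null(seed)) seed <- .sub_seed(config$seed, "deg")
  withr::with_seed(seed, {
    genes <- .pad_ids("G", config$n_genes)
    lfc <- stats::rnorm(config$n_genes, 0, 0.3)
    p <- stats::runif(config$n_genes)
    spiked <- sort(sample(genes, min(config$n_spiked, config$n_genes)))
    si <- match(spiked, genes)
    sign <- sample(c(-1, 1), length(si), replace = TRUE)
    lfc[si] <- sign * (config$spike_effect +
                         abs(stats::rnorm(length(si), 0, 0.25)))
    p[si] <- stats::runif(length(si), 0, config$spike_p_max)
    tab <- deg_table(genes, lfc, p)
    attr(tab, "spiked") <- spiked
    tab
  })
}

#' Materialize a complete synthetic fixture directory
#'
#' Writes the exact TSV/GMT dialects the loaders read: the three network
#' layers, herb-compound and compound-target tables, the disease gene list, a
#' gene-set library derived from the network's annotations, and the DEG
#' table. Returns the in-memory objects too.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated objects and file paths.
#' @export
generate_fixtures <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net0 <- generate_network(config)
  pd <- plant_disease(net0, config)
  net <- pd$network
  gc_ <- generate_catalog(net, pd$disease, config)
  deg <- generate_deg_table(config)

  paths <- list(
    pp = file.path(dir, "pp.tsv"), pf = file.path(dir, "pf.tsv"),
    ff = file.path(dir, "ff.tsv"),
    herb_compound = file.path(dir, "herb_compound.tsv"),
    compound_target = file.path(dir, "compound_target.tsv"),
    disease = file.path(dir, "disease_genes.tsv"),
    gmt = file.path(dir, "function_sets.gmt"),
    deg = file.path(dir, "deg.tsv"))
  write_network_tsv(net, paths$pp, paths$pf, paths$ff)
  hc <- do.call(rbind, lapply(gc_$catalog$herbs, function(h)
    data.frame(herb = h, compound = gc_$catalog$compounds_of[[h]],
               stringsAsFactors = FALSE)))
  .write_tsv(hc, paths$herb_compound)
  ct <- do.call(rbind, lapply(names(gc_$catalog$targets_of), function(co)
    data.frame(compound = co, target = gc_$catalog$targets_of[[co]],
               stringsAsFactors = FALSE)))
  .write_tsv(ct, paths$compound_target)
  .write_tsv(data.frame(gene = pd$disease$records$gene,
                        source = "synthetic", association_type = "genetic",
                        stringsAsFactors = FALSE), paths$disease)
  ann <- split(net$pf$protein, net$pf$fn)
  ann <- ann[lengths(ann) > 0]
  if (length(ann)) write_gmt(geneset_library(ann, "synthetic-functions"),
                             paths$gmt)
  .write_tsv(data.frame(gene = deg$gene, log2fc = deg$log2fc,
                        padj = deg$padj, stringsAsFactors = FALSE),
             paths$deg)
  writeLines(jsonlite::toJSON(list(planted_herb = gc_$planted,
                                   seed = config$seed),
                              auto_unbox = TRUE),
             file.path(dir, "ground_truth.json"))
  invisible(list(network = net, disease = pd$disease,
                 catalog = gc_$catalog, planted = gc_$planted,
                 deg = deg, paths = paths))
}

#' Run the planted-herb benchmark end to end
#'
#' Generates a network, disease module, and catalog from the config, runs the
#' full prioritization, extracts the planted herb's mechanism subnetwork, and
#' reports how well the pipeline recovered the construction.
#'
#' @param config a [synthetic_config()].
#' @param params an [rwr_params()].
#' @param k mechanism top-k (default 20).
#' @return list: `planted`, `rank` (of the planted herb), `records` (the
#'   prioritization table), `mechanism_has_disease_protein`, `runtime_sec`.
#' @export
benchmark_run <- function(config, params = rwr_params(), k = 20) {
  t0 <- proc.time()[["elapsed"]]
  net0 <- generate_network(config)
  pd <- plant_disease(net0, config)
  net <- pd$network
  gc_ <- generate_catalog(net, pd$disease, config)
  catalog <- filter_herbs(gc_$catalog, min_components = 3)
  records <- prioritize(catalog, pd$disease, net, params)
  rank <- records$rank[records$entity == gc_$planted]
  if (length(rank) == 0) rank <- NA_integer_  # planted herb filtered out

  mech_has_disease <- NA
  if (!is.na(rank)) {
    tr <- build_transition(net, params)
    hprof <- diffusion_profile(net, herb_seed(catalog, gc_$planted, net),
                               params, transition = tr)
    dprof <- attr(records, "disease_profile")
    mech <- extract_mechanism(hprof, dprof, net,
                              compound_targets = hprof$seeds,
                              disease_genes = pd$disease$records$gene, k = k)
    module_nodes <- intersect(mech$nodes$id, pd$disease$records$gene)
    mech_has_disease <- length(module_nodes) >= 1
  }
  list(planted = gc_$planted, rank = rank, records = records,
       mechanism_has_disease_protein = mech_has_disease,
       runtime_sec = proc.time()[["elapsed"]] - t0)
}
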