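#' Herb catalog: herbs, their compounds, and compound targets
#'
#' A `herb_catalog` holds the herb -> compound -> target mapping used to build
#' diffusion seeds. Compounds referenced by a herb but absent from the
#' compound-target table are kept and flagged untargeted; compounds with
#' targets but no herb are kept and flagged orphan.
#'
#' @param compounds_of named list: herb id -> character vector of compound ids.
#' @param targets_of named list: compound id -> character vector of gene ids.
#' @return object of class `herb_catalog` with elements `herbs`,
#'   `compounds_of`, `targets_of`, `untargeted` (compounds with no known
#'   target), and `orphans` (targeted compounds not referenced by any herb).
#' @export
herb_catalog <- function(compounds_of, targets_of) {
  if (length(compounds_of) == 0) stop("no associations", call. = FALSE)
  herbs <- names(compounds_of)
  if (is.null(herbs) || any(is.na(herbs)) || any(herbs == "")) {
    stop("empty herb identifier", call. = FALSE)
  }
  compounds_of <- lapply(compounds_of, function(x) sort(unique(x)))
  targets_of <- lapply(targets_of, function(x) sort(unique(x)))
  referenced <- sort(unique(unlist(compounds_of, use.names = FALSE)))
  untargeted <- setdiff(referenced, names(targets_of))
  orphans <- setdiff(names(targets_of), referenced)
  structure(
    list(herbs = sort(herbs),
         compounds_of = compounds_of[sort(herbs)],
         targets_of = targets_of,
         untargeted = untargeted,
         orphans = orphans),
    class = "herb_catalog"
  )
}

#' @export
print.herb_catalog <- function(x, ...) {
  n_assoc <- sum(lengths(x$compounds_of))
  cat("herb_catalog:", length(x$herbs), "herbs,",
      length(unique(unlist(x$compounds_of))), "compounds,",
      n_assoc, "herb-compound associations\n")
  cat("  targeted compounds:", length(x$targets_of),
      "| untargeted:", length(x$untargeted),
      "| orphans:", length(x$orphans), "\n")
  invisible(x)
}

#' Load a herb-compound association table
#'
#' Reads a two-or-more-column TSV (herb, compound). Duplicate rows collapse to
#' one association; rows with empty fields are rejected with their row numbers.
#'
#' @param path TSV file path.
#' @return named list herb -> character vector of compound ids.
#' @export
load_herb_compound <- function(path) {
  df <- read_tsv_dialect(path, min_cols = 2)
  if (nrow(df) == 0) stop("no associations in ", path, call. = FALSE)
  .check_nonempty(df, 1:2, path)
  pairs <- unique(data.frame(herb = df[[1]], compound = df[[2]],
                             stringsAsFactors = FALSE))
  message(nrow(pairs), " unique herb-compound pairs from ", path)
  split(pairs$compound, pairs$herb)
}

#' Load a compound-target association table
#'
#' Reads a two-or-more-column TSV (compound, gene). Target sets are
#' deduplicated and whitespace around identifiers is trimmed.
#'
#' @param path TSV file path.
#' @return named list compound -> character vector of gene ids.
#' @export
load_compound_target <- function(path) {
  df <- read_tsv_dialect(path, min_cols = 2)
  if (nrow(df) == 0) stop("no associations in ", path, call. = FALSE)
  .check_nonempty(df, 1:2, path)
  pairs <- unique(data.frame(compound = df[[1]], gene = df[[2]],
                             stringsAsFactors = FALSE))
  split(pairs$gene, pairs$compound)
}

#' Apply a two-column identifier mapping to a compound-target map
#'
#' Stand-in for upstream gene-identifier harmonization: a TSV (old id, new id)
#' applied to target gene ids before catalog construction. Unmapped ids pass
#' through unchanged.
#'
#' @param targets_of named list compound -> gene ids.
#' @param path mapping TSV path.
#' @return remapped `targets_of`.
#' @export
apply_gene_map <- function(targets_of, path) {
  df <- read_tsv_dialect(path, min_cols = 2)
  map <- setNames(df[[2]], df[[1]])
  lapply(targets_of, function(g) {
    hit <- g %in% names(map)
    g[hit] <- unname(map[g[hit]])
    sort(unique(g))
  })
}

#' Load herb-compound and compound-target tables into a catalog
#'
#' @param herb_compound_path,compound_target_path TSV paths.
#' @param gene_map_path optional identifier mapping TSV applied to targets.
#' @return a [herb_catalog()].
#' @export
load_catalog <- function(herb_compound_path, compound_target_path,
                         gene_map_path = NULL) {
  hc <- load_herb_compound(herb_compound_path)
  ct <- load_compound_target(compound_target_path)
  if (!is.null(gene_map_path)) ct <- apply_gene_map(ct, gene_map_path)
  herb_catalog(hc, ct)
}

# compounds of a herb that have at least one known target
.targeted_compounds <- function(catalog, herb) {
  intersect(catalog$compounds_of[[herb]], names(catalog$targets_of))
}

#' Drop herbs with too few target-linked compounds
#'
#' Retains exactly the herbs whose number of compounds with at least one known
#' target is `min_components` or more (default 3, the robustness threshold for
#' herbs likely to exert substantive multi-component effects). Untargeted
#' compounds do not count. Idempotent.
#'
#' @param catalog a [herb_catalog()].
#' @param min_components minimum number of target-linked compounds (>= 1).
#' @return filtered catalog; removed herb ids in `attr(, "removed")`.
#' @export
filter_herbs <- function(catalog, min_components = 3) {
  stopifnot(inherits(catalog, "herb_catalog"), min_components >= 1)
  n_linked <- vapply(catalog$herbs,
                     function(h) length(.targeted_compounds(catalog, h)),
                     integer(1))
  keep <- catalog$herbs[n_linked >= min_components]
  removed <- setdiff(catalog$herbs, keep)
  if (length(removed)) {
    message("filter_herbs: removed ", length(removed), " herbs (",
            paste(removed, collapse = ", "), ")")
  }
  if (length(keep) == 0) stop("no herbs retained", call. = FALSE)
  out <- herb_catalog(catalog$compounds_of[keep], catalog$targets_of)
  attr(out, "removed") <- removed
  out
}

#' Per-target pathway count for a herb
#'
#' For each target gene of the herb, the number of the herb's compounds that
#' hit it -- the simple pathway count accommodating multiple components acting
#' on a single target.
#'
#' @param catalog a [herb_catalog()].
#' @param herb herb id present in the catalog.
#' @return named integer vector gene -> count (all values >= 1).
#' @export
pathway_count <- function(catalog, herb) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!herb %in% catalog$herbs) stop("unknown herb: ", herb, call. = FALSE)
  comps <- .targeted_compounds(catalog, herb)
  genes <- unlist(lapply(comps, function(co) unique(catalog$targets_of[[co]])),
                  use.names = FALSE)
  if (length(genes) == 0) return(setNames(integer(0), character(0)))
  tab <- table(genes)
  setNames(as.integer(tab), names(tab))
}

#' Top targets by pathway count
#'
#' Genes sorted by count descending then gene id ascending; at most `n`
#' returned. The ranking is prefix-stable: increasing `n` never reorders
#' earlier entries.
#'
#' @param counts named integer vector from [pathway_count()].
#' @param n number of targets to keep (default 50).
#' @return character vector of gene ids, length `min(n, length(counts))`.
#' @export
top_targets <- function(counts, n = 50) {
  stopifnot(n >= 1)
  ord <- order(-counts, names(counts))
  head(names(counts)[ord], n)
}

#' Seed set over network nodes
#'
#' @param entity label for the seeded entity.
#' @param genes gene ids (nonempty, deduplicated, kept in sorted order).
#' @param weights optional nonnegative restart weights; normalized to sum 1.
#' @return object of class `seed_set`.
#' @export
seed_set <- function(entity, genes, weights = NULL) {
  genes <- sort(unique(genes))
  if (length(genes) == 0) stop("empty seed set for ", entity, call. = FALSE)
  if (is.null(weights)) {
    weights <- rep(1 / length(genes), length(genes))
  } else {
    if (length(weights) != length(genes) || any(weights < 0)) {
      stop("invalid seed weights", call. = FALSE)
    }
    weights <- weights / sum(weights)
  }
  structure(list(entity = entity, genes = genes,
                 weights = setNames(weights, genes)),
            class = "seed_set")
}

#' Herb seed set on a network
#'
#' Union of the herb's compound targets intersected with the network's protein
#' nodes, with uniform restart weights. Off-network targets are dropped with a
#' message.
#'
#' @param catalog a [herb_catalog()].
#' @param herb herb id.
#' @param network a [msnet()].
#' @return a [seed_set()].
#' @export
herb_seed <- function(catalog, herb, network) {
  genes <- names(pathway_count(catalog, herb))
  on_net <- intersect(genes, network$proteins)
  dropped <- setdiff(genes, on_net)
  if (length(dropped)) {
    message("herb_seed(", herb, "): dropped ", length(dropped),
            " off-network targets")
  }
  if (length(on_net) == 0) {
    stop("herb has no on-network targets: ", herb, call. = FALSE)
  }
  seed_set(herb, on_net)
}

#' Compound seed set on a network
#'
#' @inheritParams herb_seed
#' @param compound compound id with known targets.
#' @return a [seed_set()], or `NULL` (with a warning) if no target is on the
#'   network.
#' @export
compound_seed <- function(catalog, compound, network) {
  genes <- catalog$targets_of[[compound]]
  if (is.null(genes)) stop("unknown compound: ", compound, call. = FALSE)
  on_net <- intersect(genes, network$proteins)
  if (length(on_net) == 0) {
    warning("compound has no on-network targets: ", compound, call. = FALSE)
    return(NULL)
  }
  seed_set(compound, on_net)
}

#' Load and curate a disease gene set
#'
#' Reads a TSV whose first column is the gene id, with optional `source` and
#' `association_type` columns. Records whose tags match any excluded value are
#' dropped, e.g. associations inferred from animal-model homology, derived
#' solely from literature mining, or classified as therapeutic rather than
#' causal.
#'
#' @param path TSV path.
#' @param disease disease label.
#' @param excluded_association_types,excluded_evidence character vectors of
#'   tag values to drop (matched case-insensitively).
#' @return object of class `disease_gene_set` with `disease` and a `records`
#'   data frame (gene, source, association_type).
#' @export
load_disease_genes <- function(path, disease = "disease",
                               excluded_association_types = character(),
                               excluded_evidence = character()) {
  df <- read_tsv_dialect(path, min_cols = 1)
  if (nrow(df) == 0) stop("no disease genes in ", path, call. = FALSE)
  headered <- !all(grepl("^V[0-9]+$", names(df)))
  src <- if (headered) {
    if ("source" %in% names(df)) df[["source"]] else ""
  } else if (ncol(df) >= 2) df[[2]] else ""
  atype <- if (headered) {
    if ("association_type" %in% names(df)) df[["association_type"]] else ""
  } else if (ncol(df) >= 3) df[[3]] else ""
  rec <- data.frame(gene = df[[1]], source = src, association_type = atype,
                    stringsAsFactors = FALSE)
  n0 <- nrow(rec)
  keep <- !(tolower(rec$association_type) %in%
              tolower(excluded_association_types)) &
          !(tolower(rec$source) %in% tolower(excluded_evidence))
  rec <- rec[keep, , drop = FALSE]
  rec <- rec[!duplicated(rec$gene), , drop = FALSE]
  rownames(rec) <- NULL
  message("disease gene records: ", n0, " -> ", nrow(rec), " after curation")
  if (nrow(rec) == 0) warning("all disease gene records excluded",
                              call. = FALSE)
  structure(list(disease = disease, records = rec),
            class = "disease_gene_set")
}

#' Construct a disease gene set from a vector of gene ids
#'
#' @param genes gene ids.
#' @param disease disease label.
#' @return a `disease_gene_set`.
#' @export
disease_gene_set <- function(genes, disease = "disease") {
  genes <- sort(unique(genes))
  structure(list(disease = disease,
                 records = data.frame(gene = genes, source = "",
                                      association_type = "",
                                      stringsAsFactors = FALSE)),
            class = "disease_gene_set")
}

#' Disease seed set on a network
#'
#' @param disease a `disease_gene_set`.
#' @param network a [msnet()].
#' @return a [seed_set()].
#' @export
disease_seed <- function(disease, network) {
  on_net <- intersect(disease$records$gene, network$proteins)
  if (length(on_net) == 0) {
    stop("disease has no on-network genes", call. = FALSE)
  }
  seed_set(disease$disease, on_net)
}

#' Herb-target co-targeting summary
#'
#' Deduplicated herb-target edge table (a herb targets a gene if any of its
#' compounds does) and, per target, the number of distinct herbs hitting it --
#' the computation behind co-target network figures where proteins co-targeted
#' by several herbs are highlighted.
#'
#' @param catalog a [herb_catalog()].
#' @param herbs herbs to include (default all).
#' @param min_herbs report only targets hit by at least this many herbs in the
#'   `key_targets` element (the full count table is always returned).
#' @return list with `edges` (herb, target), `target_counts` (target,
#'   n_herbs), and `key_targets` (targets meeting `min_herbs`).
#' @export
cotarget_summary <- function(catalog, herbs = NULL, min_herbs = 1) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (is.null(herbs)) herbs <- catalog$herbs
  if (length(herbs) == 0) stop("need at least one herb", call. = FALSE)
  stopifnot(all(herbs %in% catalog$herbs))
  edges <- do.call(rbind, lapply(herbs, function(h) {
    g <- names(pathway_count(catalog, h))
    if (length(g) == 0) return(NULL)
    data.frame(herb = h, target = g, stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) edges <- data.frame(herb = character(),
                                          target = character())
  edges <- unique(edges)
  edges <- edges[order(edges$herb, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  tab <- table(edges$target)
  counts <- data.frame(target = names(tab), n_herbs = as.integer(tab),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_herbs, counts$target), , drop = FALSE]
  rownames(counts) <- NULL
  list(edges = edges, target_counts = counts,
       key_targets = counts$target[counts$n_herbs >= min_herbs])
}

#' Write a catalog snapshot as JSON
#'
#' @param catalog a [herb_catalog()].
#' @param path output path.
#' @export
write_catalog_json <- function(catalog, path) {
  jsonlite::write_json(
    list(herbs = catalog$herbs,
         compounds_of = catalog$compounds_of,
         targets_of = catalog$targets_of,
         untargeted = catalog$untargeted,
         orphans = catalog$orphans),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}
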