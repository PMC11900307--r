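#' Top-k most visited nodes of a diffusion profile
#'
#' The k highest-probability nodes, ties broken by node id ascending. By
#' default the profile's own seeds are excluded so the list names influenced
#' nodes rather than inputs.
#'
#' @param profile a `diffusion_profile`.
#' @param k number of nodes (>= 1); default 20, large enough to capture the
#'   high-visitation fringe of a profile.
#' @param exclude node ids to exclude (default: the profile's seeds).
#' @return character vector of node ids, length `min(k, available)`.
#' @export
top_k_nodes <- function(profile, k = 20, exclude = NULL) {
  stopifnot(k >= 1)
  if (is.null(exclude)) exclude <- profile$seeds
  p <- profile$p[!names(profile$p) %in% exclude]
  ord <- order(-p, names(p))
  head(names(p)[ord], k)
}

#' Extract the mechanism subnetwork linking a compound to a disease
#'
#' Candidate nodes are the top-k nodes of the compound profile, the top-k of
#' the disease profile, the compound's targets, and the disease genes present
#' in the network. Edges are the induced multiscale edges plus anchor edges
#' from the compound to each retained target and from the disease to each
#' disease gene. Compound targets with no link to the disease side (disease
#' genes, either top-k set) are removed iteratively to a fixpoint; "linked"
#' means direct multiscale adjacency by default, or within `link_hops` hops.
#' A target that is itself a disease gene always counts as linked. The
#' highest-ranking node of each profile is flagged critical.
#'
#' @param compound_profile,disease_profile `diffusion_profile` objects on the
#'   same network.
#' @param network a [msnet()].
#' @param compound_targets the compound's (or herb's) target gene ids.
#' @param disease_genes disease gene ids.
#' @param k top-k size per profile (default 20).
#' @param link_hops adjacency radius defining "linked" (default 1).
#' @param exclude_seeds drop each profile's seeds from its own top-k list
#'   (default TRUE).
#' @return object of class `mechanism_subnetwork`: `nodes` (id, class, role,
#'   rank, critical) and `edges` (from, to, layer) data frames plus the two
#'   anchor labels.
#' @export
extract_mechanism <- function(compound_profile, disease_profile, network,
                              compound_targets, disease_genes, k = 20,
                              link_hops = 1, exclude_seeds = TRUE) {
  stopifnot(identical(sort(names(compound_profile$p)),
                      sort(names(disease_profile$p))))
  nodes_all <- msnet_nodes(network)
  targets <- intersect(unique(compound_targets), nodes_all)
  dgenes <- intersect(unique(disease_genes), nodes_all)
  excl_c <- if (exclude_seeds) compound_profile$seeds else character()
  excl_d <- if (exclude_seeds) disease_profile$seeds else character()
  top_c <- top_k_nodes(compound_profile, k, exclude = excl_c)
  top_d <- top_k_nodes(disease_profile, k, exclude = excl_d)

  candidates <- unique(c(top_c, top_d, targets, dgenes))
  if (length(candidates) == 0) {
    stop("mechanism candidate set is empty on this network", call. = FALSE)
  }

  # adjacency within the multiscale layers, over candidate support
  g <- msnet_to_igraph(network)
  linked_to <- function(from_set, to_set, hops) {
    if (length(from_set) == 0 || length(to_set) == 0) {
      return(setNames(logical(length(from_set)), from_set))
    }
    d <- igraph::distances(g, v = from_set, to = to_set)
    apply(d, 1, function(row) any(row >= 1 & row <= hops))
  }

  # iterated exclusion of unlinked compound targets; the linkage set never
  # shrinks when a target leaves, so this reaches its fixpoint, but iterate
  # anyway to make the contract explicit
  keep_targets <- targets
  repeat {
    disease_side <- unique(c(top_d, dgenes, top_c))
    ok <- keep_targets %in% dgenes |
      linked_to(keep_targets, setdiff(disease_side, NA), link_hops)
    if (all(ok)) break
    keep_targets <- keep_targets[ok]
    if (length(keep_targets) == 0) break
  }

  retained <- unique(c(top_c, top_d, keep_targets, dgenes))
  sub <- subnetwork(network, retained)
  cls <- node_classes(network)

  role_of <- function(id) {
    if (id %in% keep_targets) "compound-target"
    else if (id %in% dgenes) "disease-protein"
    else if (cls[[id]] == "protein") "intermediate-protein"
    else "biological-function"
  }
  rank_c <- match(retained, top_c)
  rank_d <- match(retained, top_d)
  crit <- retained %in% c(top_c[1], top_d[1])
  nodes <- data.frame(
    id = retained,
    class = unname(cls[retained]),
    role = vapply(retained, role_of, character(1)),
    rank_compound = rank_c, rank_disease = rank_d,
    critical = crit, stringsAsFactors = FALSE)

  canon_layer <- function(df, nm, layer) {
    if (nrow(df) == 0) {
      return(data.frame(from = character(), to = character(),
                        layer = character(), stringsAsFactors = FALSE))
    }
    data.frame(from = df[[1]], to = df[[2]], layer = layer,
               stringsAsFactors = FALSE)
  }
  edges <- rbind(
    canon_layer(sub$pp, c("from", "to"), "pp"),
    canon_layer(sub$pf, c("protein", "fn"), "pf"),
    canon_layer(sub$ff, c("child", "parent"), "ff"))

  c_label <- paste0("compound:", compound_profile$entity)
  d_label <- paste0("disease:", disease_profile$entity)
  anchors <- data.frame(
    id = c(c_label, d_label), class = c("anchor", "anchor"),
    role = c("compound", "disease"),
    rank_compound = NA_integer_, rank_disease = NA_integer_,
    critical = FALSE, stringsAsFactors = FALSE)
  anchor_edges <- rbind(
    if (length(keep_targets))
      data.frame(from = c_label, to = keep_targets,
                 layer = "compound-target", stringsAsFactors = FALSE),
    if (length(dgenes))
      data.frame(from = d_label, to = dgenes, layer = "disease-protein",
                 stringsAsFactors = FALSE))

  nodes <- rbind(anchors, nodes)
  edges <- rbind(anchor_edges, edges)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$layer, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 compound = c_label, disease = d_label),
            class = "mechanism_subnetwork")
}

#' @export
print.mechanism_subnetwork <- function(x, ...) {
  cat("mechanism_subnetwork:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges (", x$compound, "vs", x$disease, ")\n")
  invisible(x)
}

# directed so that anchor and hierarchy edge orientations survive GraphML
.mech_to_igraph <- function(sn) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(
    g, nrow(sn$nodes), name = sn$nodes$id, class = sn$nodes$class,
    role = sn$nodes$role,
    rank_compound = ifelse(is.na(sn$nodes$rank_compound), -1L,
                           sn$nodes$rank_compound),
    rank_disease = ifelse(is.na(sn$nodes$rank_disease), -1L,
                          sn$nodes$rank_disease),
    critical = sn$nodes$critical)
  if (nrow(sn$edges)) {
    g <- igraph::add_edges(g, t(as.matrix(sn$edges[, c("from", "to")])),
                           layer = sn$edges$layer)
  }
  g
}

#' Export a mechanism subnetwork
#'
#' GraphML and Cytoscape JSON carry role/layer tags as node and edge
#' attributes; the TSV edge list has columns source, target, layer,
#' role_source, role_target. The GraphML writer round-trips: reading the file
#' back with [read_mechanism_graphml()] restores an equal subnetwork.
#'
#' @param sn a `mechanism_subnetwork`.
#' @param path output path.
#' @param format one of `"graphml"`, `"cytoscape-json"`, `"tsv"`.
#' @export
export_subnetwork <- function(sn, path,
                              format = c("graphml", "cytoscape-json", "tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(.mech_to_igraph(sn), path, format = "graphml")
  } else if (format == "cytoscape-json") {
    roles <- setNames(sn$nodes$role, sn$nodes$id)
    cy <- list(
      format_version = "1.0",
      elements = list(
        nodes = lapply(seq_len(nrow(sn$nodes)), function(i) {
          list(data = list(id = sn$nodes$id[i], class = sn$nodes$class[i],
                           role = sn$nodes$role[i],
                           critical = sn$nodes$critical[i]))
        }),
        edges = lapply(seq_len(nrow(sn$edges)), function(i) {
          list(data = list(source = sn$edges$from[i],
                           target = sn$edges$to[i],
                           layer = sn$edges$layer[i]))
        })))
    jsonlite::write_json(cy, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    roles <- setNames(sn$nodes$role, sn$nodes$id)
    df <- data.frame(source = sn$edges$from, target = sn$edges$to,
                     layer = sn$edges$layer,
                     role_source = unname(roles[sn$edges$from]),
                     role_target = unname(roles[sn$edges$to]),
                     stringsAsFactors = FALSE)
    .write_tsv(df, path)
  }
  invisible(path)
}

#' Read a mechanism subnetwork from GraphML
#'
#' Inverse of [export_subnetwork()]'s graphml format.
#'
#' @param path GraphML path.
#' @return a `mechanism_subnetwork`.
#' @export
read_mechanism_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::vertex_attr(g)
  nodes <- data.frame(
    id = v$name, class = v$class, role = v$role,
    rank_compound = ifelse(v$rank_compound < 0, NA_integer_,
                           as.integer(v$rank_compound)),
    rank_disease = ifelse(v$rank_disease < 0, NA_integer_,
                          as.integer(v$rank_disease)),
    critical = as.logical(v$critical), stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      layer = igraph::edge_attr(g, "layer"),
                      stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  edges <- edges[order(edges$layer, edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 compound = nodes$id[nodes$role == "compound"][1],
                 disease = nodes$id[nodes$role == "disease"][1]),
            class = "mechanism_subnetwork")
}
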