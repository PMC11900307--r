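#' Multiscale network: proteins, biological functions, three edge layers
#'
#' The heterogeneous graph on which diffusion profiles are computed. Three
#' layers: undirected protein-protein interactions (`pp`), undirected
#' protein-function annotations (`pf`), and a directed child-to-parent
#' function hierarchy (`ff`). Node classes are disjoint; self-loops are
#' rejected; edges are deduplicated and stored in canonical sorted order so
#' construction is insensitive to input row order.
#'
#' @param pp two-column data frame or matrix of protein-protein edges.
#' @param pf two-column data frame (protein, function).
#' @param ff two-column data frame (child function, parent function).
#' @param proteins,functions optional extra node ids (isolated nodes are
#'   allowed; functions appearing only in `ff` are valid).
#' @return object of class `msnet` with sorted node vectors `proteins`,
#'   `functions` and canonical edge data frames `pp`, `pf`, `ff`.
#' @export
msnet <- function(pp = NULL, pf = NULL, ff = NULL,
                  proteins = character(), functions = character()) {
  as_edges <- function(x, nm) {
    if (is.null(x) || NROW(x) == 0) {
      return(setNames(data.frame(a = character(), b = character(),
                                 stringsAsFactors = FALSE), nm))
    }
    df <- data.frame(a = as.character(x[[1]]), b = as.character(x[[2]]),
                     stringsAsFactors = FALSE)
    names(df) <- nm
    df
  }
  pp <- as_edges(pp, c("from", "to"))
  pf <- as_edges(pf, c("protein", "fn"))
  ff <- as_edges(ff, c("child", "parent"))

  # self-loops are meaningless in pp/pf and ill-formed in a hierarchy
  loop <- pp$from == pp$to
  if (any(loop)) {
    warning(sum(loop), " pp self-loops rejected", call. = FALSE)
    pp <- pp[!loop, , drop = FALSE]
  }
  if (any(ff$child == ff$parent)) {
    warning("ff self-loops rejected", call. = FALSE)
    ff <- ff[ff$child != ff$parent, , drop = FALSE]
  }

  # canonicalize undirected layers, deduplicate everything
  canon <- function(a, b) data.frame(from = pmin(a, b), to = pmax(a, b),
                                     stringsAsFactors = FALSE)
  pp <- unique(canon(pp$from, pp$to))
  pp <- pp[order(pp$from, pp$to), , drop = FALSE]
  pf <- unique(pf)
  pf <- pf[order(pf$protein, pf$fn), , drop = FALSE]
  ff <- unique(ff)
  ff <- ff[order(ff$child, ff$parent), , drop = FALSE]
  # reciprocal hierarchy edges contradict a child->parent reading; collapse
  # (sorted first, so the lexicographically smaller child wins regardless of
  # input row order)
  key <- paste(pmin(ff$child, ff$parent), pmax(ff$child, ff$parent))
  if (anyDuplicated(key)) {
    warning("reciprocal ff edges collapsed to a single child->parent edge",
            call. = FALSE)
    ff <- ff[!duplicated(key), , drop = FALSE]
  }

  prot <- sort(unique(c(proteins, pp$from, pp$to, pf$protein)))
  fn <- sort(unique(c(functions, pf$fn, ff$child, ff$parent)))
  clash <- intersect(prot, fn)
  if (length(clash)) {
    stop("class conflict: node(s) appear as both protein and function: ",
         paste(head(clash, 10), collapse = ", "), call. = FALSE)
  }
  rownames(pp) <- rownames(pf) <- rownames(ff) <- NULL
  structure(list(proteins = prot, functions = fn, pp = pp, pf = pf, ff = ff),
            class = "msnet")
}

#' @export
print.msnet <- function(x, ...) {
  cat("msnet:", length(x$proteins), "proteins,", length(x$functions),
      "functions |", nrow(x$pp), "pp,", nrow(x$pf), "pf,", nrow(x$ff),
      "ff edges\n")
  invisible(x)
}

#' All node ids of a network (proteins then functions, each sorted)
#' @param network a [msnet()].
#' @return character vector.
#' @export
msnet_nodes <- function(network) c(network$proteins, network$functions)

#' Node class lookup
#' @param network a [msnet()].
#' @return named character vector, values `"protein"` or `"function"`.
#' @export
node_classes <- function(network) {
  setNames(c(rep("protein", length(network$proteins)),
             rep("function", length(network$functions))),
           msnet_nodes(network))
}

#' Load the three network layers from TSV files
#'
#' Each file needs two node-id columns (extra columns ignored). Edges are
#' deduplicated; pp/pf self-loops and reciprocal ff pairs are handled with
#' warnings; a node appearing both as a protein and as a function endpoint is
#' a class-conflict error.
#'
#' @param pp_path,pf_path,ff_path TSV paths for the protein-protein,
#'   protein-function, and function-hierarchy layers.
#' @return a [msnet()]; a per-layer summary is logged.
#' @export
load_network <- function(pp_path, pf_path, ff_path) {
  rd <- function(p) {
    df <- read_tsv_dialect(p, min_cols = 2)
    df[, 1:2, drop = FALSE]
  }
  net <- msnet(pp = rd(pp_path), pf = rd(pf_path), ff = rd(ff_path))
  message("loaded network: ", length(net$proteins), " proteins, ",
          length(net$functions), " functions; ", nrow(net$pp), " pp, ",
          nrow(net$pf), " pf, ", nrow(net$ff), " ff edges")
  net
}

#' Neighbor lists of a node, partitioned by class transition
#'
#' For a protein: `protein` (pp) and `fn` (pf) neighbors. For a function:
#' `protein` (pf), `fn_up` (parents), `fn_down` (children).
#'
#' @param network a [msnet()].
#' @param node node id.
#' @return named list of character vectors.
#' @export
node_neighbors <- function(network, node) {
  if (node %in% network$proteins) {
    list(protein = sort(c(network$pp$to[network$pp$from == node],
                          network$pp$from[network$pp$to == node])),
         fn = sort(network$pf$fn[network$pf$protein == node]))
  } else if (node %in% network$functions) {
    list(protein = sort(network$pf$protein[network$pf$fn == node]),
         fn_up = sort(network$ff$parent[network$ff$child == node]),
         fn_down = sort(network$ff$child[network$ff$parent == node]))
  } else {
    stop("unknown node: ", node, call. = FALSE)
  }
}

#' Validation report for a multiscale network
#'
#' Never mutates its input.
#'
#' @param network a [msnet()].
#' @return list with per-layer counts, isolated nodes, and a class-consistency
#'   verdict.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "msnet"))
  nodes <- msnet_nodes(network)
  touched <- unique(c(network$pp$from, network$pp$to, network$pf$protein,
                      network$pf$fn, network$ff$child, network$ff$parent))
  list(
    n_proteins = length(network$proteins),
    n_functions = length(network$functions),
    n_pp = nrow(network$pp), n_pf = nrow(network$pf), n_ff = nrow(network$ff),
    isolated = setdiff(nodes, touched),
    class_consistent = length(intersect(network$proteins,
                                        network$functions)) == 0 &&
      all(network$pf$fn %in% network$functions) &&
      all(network$ff$child %in% network$functions) &&
      all(network$ff$parent %in% network$functions)
  )
}

#' Induced subnetwork on a node subset
#'
#' Keeps every edge whose two endpoints are in `nodes`, preserving layer
#' labels and node classes.
#'
#' @param network a [msnet()].
#' @param nodes node ids to retain.
#' @return a [msnet()].
#' @export
subnetwork <- function(network, nodes) {
  stopifnot(inherits(network, "msnet"))
  nodes <- unique(nodes)
  pp <- network$pp[network$pp$from %in% nodes & network$pp$to %in% nodes, ]
  pf <- network$pf[network$pf$protein %in% nodes & network$pf$fn %in% nodes, ]
  ff <- network$ff[network$ff$child %in% nodes & network$ff$parent %in% nodes, ]
  msnet(pp = pp, pf = pf, ff = ff,
        proteins = intersect(network$proteins, nodes),
        functions = intersect(network$functions, nodes))
}

#' Convert a multiscale network to an igraph object
#'
#' Node attribute `class` (protein/function) and edge attribute `layer`
#' (pp/pf/ff); ff edges are the only directed ones conceptually but the graph
#' is built undirected with the hierarchy direction stored in `child`/`parent`
#' attributes when `directed_ff = FALSE` is too lossy for the caller.
#'
#' @param network a [msnet()].
#' @return an undirected [igraph::igraph] with a `layer` edge attribute; ff
#'   edges keep their child->parent orientation in edge order.
#' @export
msnet_to_igraph <- function(network) {
  nodes <- msnet_nodes(network)
  edges <- rbind(
    if (nrow(network$pp)) cbind(network$pp$from, network$pp$to),
    if (nrow(network$pf)) cbind(network$pf$protein, network$pf$fn),
    if (nrow(network$ff)) cbind(network$ff$child, network$ff$parent)
  )
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes,
                            class = unname(node_classes(network)))
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(edges),
                           layer = c(rep("pp", nrow(network$pp)),
                                     rep("pf", nrow(network$pf)),
                                     rep("ff", nrow(network$ff))))
  }
  g
}

#' Export a multiscale network as GraphML
#'
#' @param network a [msnet()].
#' @param path output path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(msnet_to_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write the three network layers as TSV files
#'
#' @param network a [msnet()].
#' @param pp_path,pf_path,ff_path output paths.
#' @export
write_network_tsv <- function(network, pp_path, pf_path, ff_path) {
  .write_tsv(setNames(network$pp, c("node1", "node2")), pp_path)
  .write_tsv(setNames(network$pf, c("protein", "function")), pf_path)
  .write_tsv(setNames(network$ff, c("child", "parent")), ff_path)
  invisible(c(pp_path, pf_path, ff_path))
}
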