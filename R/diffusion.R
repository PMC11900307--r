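#' Parameters of the biased random walk with restart
#'
#' The walker restarts to the seed distribution with probability `r` each
#' step; otherwise it moves to a neighbor with probability proportional to a
#' weight that depends only on the class transition: protein->protein
#' (`w_pp`), protein->function (`w_pf`), function->protein (`w_fp`), and
#' hierarchy moves child->parent (`w_f_up`) and parent->child (`w_f_down`).
#' Neutral defaults (`r = 0.5`, all weights 1) make the walk an unbiased RWR;
#' all five weights are the bias knobs.
#'
#' @param r restart probability in (0, 1].
#' @param w_pp,w_pf,w_fp,w_f_up,w_f_down nonnegative class-transition weights;
#'   at least one must be positive.
#' @param tol L1 convergence threshold for power iteration (> 0).
#' @param max_iter maximum number of power iterations (>= 1).
#' @return object of class `rwr_params`.
#' @export
rwr_params <- function(r = 0.5, w_pp = 1, w_pf = 1, w_fp = 1,
                       w_f_up = 1, w_f_down = 1,
                       tol = 1e-6, max_iter = 500L) {
  w <- c(w_pp, w_pf, w_fp, w_f_up, w_f_down)
  if (!(r > 0 && r <= 1)) stop("r must be in (0, 1]", call. = FALSE)
  if (any(w < 0) || all(w == 0)) {
    stop("edge-type weights must be nonnegative with at least one positive",
         call. = FALSE)
  }
  if (tol <= 0 || max_iter < 1) stop("invalid tol/max_iter", call. = FALSE)
  structure(list(r = r, w_pp = w_pp, w_pf = w_pf, w_fp = w_fp,
                 w_f_up = w_f_up, w_f_down = w_f_down,
                 tol = tol, max_iter = as.integer(max_iter)),
            class = "rwr_params")
}

# Column-stochastic transition operator for the biased walk.
# M[v, u] = P(move u -> v); dangling nodes have a zero column and are listed
# so the iteration can route their mass back to the restart distribution.
build_transition <- function(network, params) {
  nodes <- msnet_nodes(network)
  idx <- setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  add <- function(u, v, wt) {
    if (length(u) && wt > 0) {
      from <<- c(from, u); to <<- c(to, v); w <<- c(w, rep(wt, length(u)))
    }
  }
  pp_a <- idx[network$pp$from]; pp_b <- idx[network$pp$to]
  add(pp_a, pp_b, params$w_pp); add(pp_b, pp_a, params$w_pp)
  pf_p <- idx[network$pf$protein]; pf_f <- idx[network$pf$fn]
  add(pf_p, pf_f, params$w_pf); add(pf_f, pf_p, params$w_fp)
  ff_c <- idx[network$ff$child]; ff_p <- idx[network$ff$parent]
  add(ff_c, ff_p, params$w_f_up); add(ff_p, ff_c, params$w_f_down)

  W <- Matrix::sparseMatrix(i = to, j = from, x = w, dims = c(n, n))
  out_w <- Matrix::colSums(W)
  # degree per node irrespective of weights, to detect trapped walkers
  deg <- Matrix::colSums(Matrix::sparseMatrix(i = to, j = from, x = 1,
                                              dims = c(n, n)) != 0)
  trapped <- deg > 0 & out_w == 0
  if (any(trapped)) {
    stop("walker trapped: node(s) with neighbors but all applicable weights ",
         "zero: ", paste(head(nodes[trapped], 5), collapse = ", "),
         call. = FALSE)
  }
  dangling <- out_w == 0
  scale <- ifelse(dangling, 0, 1 / pmax(out_w, .Machine$double.xmin))
  M <- W %*% Matrix::Diagonal(n, scale)
  list(M = M, dangling = which(dangling), nodes = nodes, idx = idx)
}

#' Transition distribution from a node
#'
#' The one-step move distribution of the biased walker at `node`:
#' P(v | u) proportional to the class-transition weight of u -> v. An
#' isolated node returns an empty map (the walker restarts there); a node
#' whose neighbors all carry zero weight is an error.
#'
#' @param network a [msnet()].
#' @param node node id.
#' @param params an [rwr_params()].
#' @return named numeric vector over neighbors (sums to 1), possibly empty.
#' @export
transition_distribution <- function(network, node, params = rwr_params()) {
  if (!node %in% msnet_nodes(network)) {
    stop("unknown node: ", node, call. = FALSE)
  }
  nb <- node_neighbors(network, node)
  if (node %in% network$proteins) {
    w <- c(rep(params$w_pp, length(nb$protein)),
           rep(params$w_pf, length(nb$fn)))
    v <- c(nb$protein, nb$fn)
  } else {
    w <- c(rep(params$w_fp, length(nb$protein)),
           rep(params$w_f_up, length(nb$fn_up)),
           rep(params$w_f_down, length(nb$fn_down)))
    v <- c(nb$protein, nb$fn_up, nb$fn_down)
  }
  keep <- w > 0
  if (length(v) == 0) return(setNames(numeric(0), character(0)))
  if (!any(keep)) {
    stop("walker trapped: all applicable weights zero at ", node,
         call. = FALSE)
  }
  setNames(w[keep] / sum(w[keep]), v[keep])
}

# restart distribution s over the node index
.seed_vector <- function(seeds, nodes) {
  if (!all(seeds$genes %in% nodes)) {
    stop("seed genes not on network: ",
         paste(setdiff(seeds$genes, nodes), collapse = ", "), call. = FALSE)
  }
  s <- numeric(length(nodes))
  s[match(seeds$genes, nodes)] <- seeds$weights
  s
}

#' Diffusion profile of a seed set
#'
#' Fixed point of `p <- r*s + (1-r) * (M p + mass_on_dangling(p) * s)` where
#' `s` is the restart distribution over the seeds and `M` the column-
#' stochastic biased transition operator; dangling nodes hand their mass back
#' to the restart distribution so the result is a proper probability vector.
#' Solved by power iteration to an L1 tolerance.
#'
#' @param network a [msnet()].
#' @param seeds a [seed_set()] whose genes are network nodes.
#' @param params an [rwr_params()].
#' @param transition optional precomputed operator from an internal build,
#'   reused across profiles on the same network and parameters.
#' @return object of class `diffusion_profile`: `entity`, named probability
#'   vector `p` over all nodes (values below 1e-12 clamped to 0 after
#'   normalization), `seeds`, `params`, `iterations`, `residual`.
#' @export
diffusion_profile <- function(network, seeds, params = rwr_params(),
                              transition = NULL) {
  stopifnot(inherits(seeds, "seed_set"))
  if (is.null(transition)) transition <- build_transition(network, params)
  nodes <- transition$nodes
  s <- .seed_vector(seeds, nodes)
  r <- params$r
  if (r == 1) {
    p <- s
    iters <- 0L
    resid <- 0
  } else {
    p <- s
    iters <- 0L
    repeat {
      dang_mass <- if (length(transition$dangling))
        sum(p[transition$dangling]) else 0
      p_new <- r * s + (1 - r) *
        (as.numeric(transition$M %*% p) + dang_mass * s)
      resid <- sum(abs(p_new - p))
      p <- p_new
      iters <- iters + 1L
      if (resid < params$tol) break
      if (iters >= params$max_iter) {
        stop("diffusion did not converge in ", params$max_iter,
             " iterations (last L1 residual ", signif(resid, 3), ")",
             call. = FALSE)
      }
    }
  }
  p <- p / sum(p)
  p[p < 1e-12] <- 0
  structure(list(entity = seeds$entity, p = setNames(p, nodes),
                 seeds = seeds$genes, params = params,
                 iterations = iters, residual = resid),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat("diffusion_profile[", x$entity, "]: ", length(x$p), " nodes, r = ",
      x$params$r, ", ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Diffusion profiles for a list of seed sets
#'
#' Builds the transition operator once and maps [diffusion_profile()] over the
#' seed sets, preserving order.
#'
#' @param network a [msnet()].
#' @param seed_list list of [seed_set()] objects.
#' @param params an [rwr_params()].
#' @return list of `diffusion_profile` objects, same order as `seed_list`.
#' @export
batch_profiles <- function(network, seed_list, params = rwr_params()) {
  tr <- build_transition(network, params)
  lapply(seed_list, function(s)
    diffusion_profile(network, s, params, transition = tr))
}

#' Monte-Carlo visitation frequencies (simulation oracle)
#'
#' Simulates the walk literally: restart with probability `r`, otherwise move
#' by [transition_distribution()]; a dangling position restarts. Visit counts
#' over `n_steps` steps, normalized to frequencies, estimate the stationary
#' distribution that [diffusion_profile()] computes by power iteration.
#' Reproducible given `rng_seed`.
#'
#' @param network a [msnet()].
#' @param seeds a [seed_set()].
#' @param params an [rwr_params()].
#' @param n_steps number of simulated steps (>= 1).
#' @param rng_seed integer RNG seed.
#' @return named numeric frequency vector over all nodes (sums to 1).
#' @export
mc_profile <- function(network, seeds, params = rwr_params(),
                       n_steps = 1e6, rng_seed = 1L) {
  stopifnot(n_steps >= 1)
  tr <- build_transition(network, params)
  n <- length(tr$nodes)
  # CSR of the column-stochastic M: per source node, neighbor ids and
  # within-node cumulative probabilities
  Mt <- Matrix::t(tr$M)  # row u = distribution from u
  Mt <- as(Mt, "RsparseMatrix")
  ptr <- Mt@p
  nbr <- Mt@j
  prob <- Mt@x
  cum <- prob
  for (u in seq_len(n)) {
    a <- ptr[u] + 1L; b <- ptr[u + 1L]
    if (b >= a) cum[a:b] <- cumsum(prob[a:b])
  }
  s <- .seed_vector(seeds, tr$nodes)
  seed_idx <- which(s > 0)
  seed_cum <- cumsum(s[seed_idx] / sum(s[seed_idx]))
  counts <- withr::with_seed(rng_seed, {
    mc_walk_counts(ptr, nbr, cum, seed_idx - 1L, seed_cum,
                   params$r, as.integer(n_steps))
  })
  setNames(counts / sum(counts), tr$nodes)
}

#' Write a diffusion profile as TSV
#'
#' Columns (node, class, probability), sorted by probability descending then
#' node id; probabilities at full precision so the file round-trips exactly.
#'
#' @param profile a `diffusion_profile`.
#' @param network the network it was computed on (for node classes).
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, network, path) {
  cls <- node_classes(network)
  ord <- order(-profile$p, names(profile$p))
  df <- data.frame(node = names(profile$p)[ord],
                   class = unname(cls[names(profile$p)[ord]]),
                   probability = sprintf("%.17g", unname(profile$p[ord])),
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a diffusion profile TSV written by [write_profile_tsv()]
#'
#' @param path TSV path.
#' @param entity label for the restored profile.
#' @return named numeric probability vector.
#' @export
read_profile_tsv <- function(path, entity = "profile") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.numeric(df$probability), df$node)
}
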