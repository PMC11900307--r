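#' Correlation between two diffusion profiles
#'
#' Correlation over the full node vector (proteins and functions) of two
#' profiles on the same network; high values mean the two entities influence
#' similar network regions.
#'
#' @param profile_a,profile_b `diffusion_profile` objects or named numeric
#'   vectors over the same node index.
#' @param method `"pearson"` or `"spearman"`.
#' @return correlation in \[-1, 1\].
#' @export
correlation_score <- function(profile_a, profile_b, method = "pearson") {
  method <- match.arg(method, c("pearson", "spearman"))
  pa <- if (inherits(profile_a, "diffusion_profile")) profile_a$p else profile_a
  pb <- if (inherits(profile_b, "diffusion_profile")) profile_b$p else profile_b
  if (length(pa) != length(pb) || !setequal(names(pa), names(pb))) {
    stop("profiles are not over the same node index", call. = FALSE)
  }
  pb <- pb[names(pa)]
  if (stats::sd(pa) == 0 || stats::sd(pb) == 0) {
    stop("degenerate profile: zero variance", call. = FALSE)
  }
  stats::cor(pa, pb, method = method)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least `k`
#' marked genes when drawing `n` without replacement from a universe of `N`
#' containing `K` marked. Evaluated through the survival function in log
#' space, so tiny tails keep precision.
#'
#' @param k observed overlap (0 <= k <= min(n, K)).
#' @param n draw size.
#' @param K number of marked genes in the universe.
#' @param N universe size.
#' @param log.p return the natural-log probability.
#' @return upper-tail probability in (0, 1\] (or its log).
#' @export
hypergeom_upper <- function(k, n, K, N, log.p = FALSE) {
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("inconsistent hypergeometric counts (k=", k, ", n=", n,
         ", K=", K, ", N=", N, ")", call. = FALSE)
  }
  if (k <= 0) return(if (log.p) 0 else 1)
  stats::phyper(k - 1, m = K, n = N - K, k = n,
                lower.tail = FALSE, log.p = log.p)
}

#' Fold enrichment of an overlap
#'
#' `(k/n) / (K/N)`: observed overlap fraction over the fraction expected under
#' random draws from the universe. 1 means no enrichment.
#'
#' @inheritParams hypergeom_upper
#' @return nonnegative real; 0 when `k = 0`.
#' @export
fold_enrichment <- function(k, n, K, N) {
  stopifnot(n > 0, K > 0)
  (k / n) * (N / K)
}

#' Rank herbs against a disease by diffusion-profile correlation
#'
#' Computes the disease diffusion profile and one profile per retained herb
#' (seeded at the union of its compound targets on the network), then scores
#' each herb by profile correlation, target-set overlap with the on-network
#' disease genes (hypergeometric upper tail and fold enrichment), and sorts
#' by correlation descending with deterministic ties by herb id. Herbs whose
#' overlap p-value fails `alpha` are flagged, not dropped.
#'
#' @param catalog a [herb_catalog()] (already filtered as desired).
#' @param disease a `disease_gene_set`.
#' @param network a [msnet()].
#' @param params an [rwr_params()].
#' @param method correlation method, `"pearson"` (default) or `"spearman"`.
#' @param universe_N overlap universe size; defaults to the number of network
#'   proteins.
#' @param alpha significance threshold for the overlap flag.
#' @param overlap_from_top_n if set, the overlap denominator is the herb's
#'   top-`n` targets by pathway count instead of its full on-network target
#'   set (the capped variant of the overlap statistic).
#' @return data frame of class `prioritization`: entity, correlation_score,
#'   overlap_k, overlap_n, p_value, enrichment, significant, rank.
#' @export
prioritize <- function(catalog, disease, network, params = rwr_params(),
                       method = "pearson", universe_N = NULL, alpha = 0.05,
                       overlap_from_top_n = NULL) {
  stopifnot(inherits(catalog, "herb_catalog"),
            inherits(disease, "disease_gene_set"))
  if (is.null(universe_N)) universe_N <- length(network$proteins)
  dseed <- disease_seed(disease, network)
  tr <- build_transition(network, params)
  dprof <- diffusion_profile(network, dseed, params, transition = tr)
  K <- length(dseed$genes)

  rows <- lapply(catalog$herbs, function(h) {
    hseed <- herb_seed(catalog, h, network)
    hprof <- diffusion_profile(network, hseed, params, transition = tr)
    targ <- if (is.null(overlap_from_top_n)) {
      hseed$genes
    } else {
      intersect(top_targets(pathway_count(catalog, h), overlap_from_top_n),
                network$proteins)
    }
    k <- length(intersect(targ, dseed$genes))
    n <- length(targ)
    data.frame(
      entity = h,
      correlation_score = correlation_score(hprof, dprof, method),
      overlap_k = k, overlap_n = n,
      p_value = hypergeom_upper(k, n, K, universe_N),
      enrichment = fold_enrichment(k, n, K, universe_N),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # alpha >= 1 disables the overlap filter (nothing flagged)
  out$significant <- if (alpha >= 1) TRUE else out$p_value < alpha
  out <- out[order(-out$correlation_score, out$entity), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prioritization", class(out))
  attr(out, "disease_profile") <- dprof
  attr(out, "universe_N") <- universe_N
  attr(out, "K") <- K
  out
}

#' Rank a herb's compounds against the disease
#'
#' Each targeted compound of the herb is seeded at its own on-network targets;
#' compounds with no on-network target are skipped with a warning. Scores and
#' overlap statistics as in [prioritize()]; the top `top_m` compounds by
#' correlation (ties by compound id) are returned.
#'
#' @inheritParams prioritize
#' @param herb herb id in the catalog.
#' @param top_m maximum number of compounds returned (default 5).
#' @return `prioritization` data frame over compounds.
#' @export
prioritize_compounds <- function(catalog, herb, disease, network,
                                 params = rwr_params(), method = "pearson",
                                 universe_N = NULL, alpha = 0.05, top_m = 5) {
  stopifnot(inherits(catalog, "herb_catalog"))
  if (!herb %in% catalog$herbs) stop("unknown herb: ", herb, call. = FALSE)
  if (is.null(universe_N)) universe_N <- length(network$proteins)
  dseed <- disease_seed(disease, network)
  tr <- build_transition(network, params)
  dprof <- diffusion_profile(network, dseed, params, transition = tr)
  K <- length(dseed$genes)

  comps <- .targeted_compounds(catalog, herb)
  rows <- list()
  for (co in comps) {
    cseed <- compound_seed(catalog, co, network)
    if (is.null(cseed)) next
    cprof <- diffusion_profile(network, cseed, params, transition = tr)
    k <- length(intersect(cseed$genes, dseed$genes))
    n <- length(cseed$genes)
    rows[[co]] <- data.frame(
      entity = co,
      correlation_score = correlation_score(cprof, dprof, method),
      overlap_k = k, overlap_n = n,
      p_value = hypergeom_upper(k, n, K, universe_N),
      enrichment = fold_enrichment(k, n, K, universe_N),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no scorable compounds for ", herb,
                              call. = FALSE)
  out <- do.call(rbind, rows)
  out$significant <- if (alpha >= 1) TRUE else out$p_value < alpha
  out <- out[order(-out$correlation_score, out$entity), , drop = FALSE]
  out <- head(out, top_m)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("prioritization", class(out))
  attr(out, "disease_profile") <- dprof
  out
}

#' Write a prioritization table as display TSV (plus optional full JSON)
#'
#' TSV columns mirror a ranked candidate table: entity, correlation score (4
#' significant digits), overlap as `k/n`, p-value, enrichment. The JSON keeps
#' full precision.
#'
#' @param records a `prioritization` data frame.
#' @param path TSV path.
#' @param json_path optional JSON path.
#' @export
write_prioritization <- function(records, path, json_path = NULL) {
  df <- data.frame(
    entity = records$entity,
    correlation_score = .fmt_num(records$correlation_score),
    overlap = paste0(records$overlap_k, "/", records$overlap_n),
    p_value = .fmt_num(records$p_value),
    enrichment = .fmt_num(records$enrichment),
    significant = records$significant,
    stringsAsFactors = FALSE)
  .write_tsv(df, path)
  if (!is.null(json_path)) {
    jsonlite::write_json(records[, c("entity", "correlation_score",
                                     "overlap_k", "overlap_n", "p_value",
                                     "enrichment", "significant", "rank")],
                         json_path, dataframe = "rows", digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
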