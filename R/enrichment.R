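#' Read a GMT gene-set library
#'
#' Standard GMT: one term per line, tab-separated as term, description, then
#' member genes. Duplicate genes within a term are collapsed; lines with no
#' genes are rejected with a warning.
#'
#' @param path GMT file path.
#' @param name library name (defaults to the file name).
#' @return object of class `geneset_library`: `name` and `terms`, a named
#'   list term id -> list(description, genes).
#' @export
read_gmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  terms <- list()
  for (ln in lines) {
    parts <- trimws(strsplit(ln, "\t", fixed = TRUE)[[1]])
    genes <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    if (length(parts) < 3 || length(genes) == 0) {
      warning("GMT line with no genes skipped: ",
              substr(ln, 1, 40), call. = FALSE)
      next
    }
    terms[[parts[1]]] <- list(description = parts[2], genes = sort(genes))
  }
  if (length(terms) == 0) stop("no usable terms in ", path, call. = FALSE)
  structure(list(name = name, terms = terms), class = "geneset_library")
}

#' Build a gene-set library in code
#'
#' @param terms named list term -> character vector of genes (or
#'   list(description, genes)).
#' @param name library name.
#' @return a `geneset_library`.
#' @export
geneset_library <- function(terms, name = "library") {
  terms <- lapply(terms, function(t) {
    if (is.character(t)) t <- list(description = "", genes = t)
    t$genes <- sort(unique(t$genes))
    if (length(t$genes) == 0) stop("empty term", call. = FALSE)
    t
  })
  structure(list(name = name, terms = terms), class = "geneset_library")
}

#' Write a gene-set library as GMT
#' @param library a `geneset_library`.
#' @param path output path.
#' @export
write_gmt <- function(library, path) {
  lines <- vapply(names(library$terms), function(id) {
    t <- library$terms[[id]]
    paste(c(id, if (nzchar(t$description)) t$description else id, t$genes),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order. Thin, named wrapper
#' so the adjustment used across the package is a single switchable point.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values, each in `[p, 1]`.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Combined enrichment score
#'
#' `-ln(p) * z`: the product of the log-transformed p-value and the z-score
#' of the overlap's deviation from its null expectation. Positive z means
#' over-representation.
#'
#' @param p p-value in (0, 1\].
#' @param z overlap z-score.
#' @return the combined score (0 when `p = 1` or `z = 0`).
#' @export
combined_score <- function(p, z) {
  -log(p) * z
}

# exact hypergeometric z-score of the observed overlap
.hyper_z <- function(k, n, K, N) {
  mu <- n * K / N
  v <- n * (K / N) * (1 - K / N) * (N - n) / (N - 1)
  if (!is.finite(v) || v <= 0) return(0)
  (k - mu) / sqrt(v)
}

#' Over-representation analysis against a gene-set library
#'
#' Per term: raw p = hypergeometric upper tail of the query/term overlap in
#' the universe; BH adjustment across the library's tested terms; z-score of
#' the overlap under the exact hypergeometric null (mean `nK/N`); combined
#' score `-ln(p_raw) * z` (switchable to the adjusted p). Query genes outside
#' the universe are dropped with a warning. Sorted by combined score
#' descending.
#'
#' @param query character vector of gene ids.
#' @param library a `geneset_library`.
#' @param universe character vector of background gene ids.
#' @param alpha significance threshold applied to adjusted p for the
#'   `significant` flag.
#' @param combine_on `"raw"` (default) or `"adjusted"`: which p-value feeds
#'   the combined score.
#' @param term_blocklist optional character vector of regular expressions; a
#'   term whose id or description matches any of them is excluded before
#'   testing (e.g. to drop sets explicitly tied to named diseases).
#' @return data frame of class `enrichment`: term, description, overlap_k,
#'   term_size, p_raw, p_adjusted, z_score, combined_score, significant,
#'   genes (';'-joined overlap).
#' @export
ora <- function(query, library, universe, alpha = 0.05,
                combine_on = c("raw", "adjusted"),
                term_blocklist = NULL) {
  combine_on <- match.arg(combine_on)
  stopifnot(inherits(library, "geneset_library"))
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (length(query) == 0) stop("empty query", call. = FALSE)
  off <- setdiff(query, universe)
  if (length(off)) {
    warning(length(off), " query genes outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
    if (length(query) == 0) stop("empty query after universe intersection",
                                 call. = FALSE)
  }
  terms <- library$terms
  if (!is.null(term_blocklist)) {
    hit <- vapply(names(terms), function(id) {
      any(vapply(term_blocklist, function(rx) {
        grepl(rx, id, ignore.case = TRUE) ||
          grepl(rx, terms[[id]]$description, ignore.case = TRUE)
      }, logical(1)))
    }, logical(1))
    terms <- terms[!hit]
  }
  if (length(terms) == 0) stop("no terms to test", call. = FALSE)

  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(terms), function(id) {
    tg <- intersect(terms[[id]]$genes, universe)
    ov <- intersect(query, tg)
    k <- length(ov)
    K <- length(tg)
    p <- if (K == 0) 1 else hypergeom_upper(k, n, K, N)
    data.frame(term = id, description = terms[[id]]$description,
               overlap_k = k, term_size = K, p_raw = p,
               z_score = if (K == 0) 0 else .hyper_z(k, n, K, N),
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p_raw)
  pc <- if (combine_on == "raw") out$p_raw else out$p_adjusted
  out$combined_score <- combined_score(pc, out$z_score)
  out$significant <- out$p_adjusted < alpha
  out <- out[order(-out$combined_score, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out <- out[, c("term", "description", "overlap_k", "term_size", "p_raw",
                 "p_adjusted", "z_score", "combined_score", "significant",
                 "genes")]
  class(out) <- c("enrichment", class(out))
  out
}

#' Write an enrichment table as display TSV
#'
#' Shaped like a published enrichment table: Term, Overlap `k/n`, adjusted p,
#' combined score, ';'-joined overlapping targets.
#'
#' @param records an `enrichment` data frame.
#' @param path output path.
#' @export
write_enrichment <- function(records, path) {
  df <- data.frame(
    term = records$term,
    overlap = paste0(records$overlap_k, "/", records$term_size),
    adjusted_p = .fmt_num(records$p_adjusted),
    combined_score = .fmt_num(records$combined_score),
    targets = records$genes,
    stringsAsFactors = FALSE)
  .write_tsv(df, path)
}
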