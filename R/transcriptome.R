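#' Differential-expression table
#'
#' One row per gene with its log2 fold-change and adjusted p-value.
#'
#' @param gene,log2fc,padj equal-length vectors.
#' @return data frame of class `deg_table`.
#' @export
deg_table <- function(gene, log2fc, padj) {
  if (anyDuplicated(gene)) stop("duplicate genes in DEG table", call. = FALSE)
  if (any(padj < 0 | padj > 1, na.rm = TRUE)) {
    stop("adjusted p outside [0, 1]", call. = FALSE)
  }
  structure(data.frame(gene = as.character(gene),
                       log2fc = as.numeric(log2fc),
                       padj = as.numeric(padj), stringsAsFactors = FALSE),
            class = c("deg_table", "data.frame"))
}

#' Read a DEG table from TSV (gene, log2fc, padj)
#' @param path TSV path.
#' @return a [deg_table()].
#' @export
load_deg_table <- function(path) {
  df <- read_tsv_dialect(path, min_cols = 3)
  if (nrow(df) == 0) stop("empty DEG table: ", path, call. = FALSE)
  deg_table(df[[1]], as.numeric(df[[2]]), as.numeric(df[[3]]))
}

#' Split a DEG table into significant up- and downregulated genes
#'
#' Boundary semantics follow the conventional printed thresholds exactly:
#' fold-change inclusive (`|log2fc| >= lfc_min`), adjusted p strict
#' (`padj < alpha`). The two lists are disjoint and the filter is idempotent
#' and monotone in both thresholds.
#'
#' @param table a [deg_table()].
#' @param lfc_min minimum absolute log2 fold-change (default 1.0).
#' @param alpha adjusted-p threshold, exclusive (default 0.05).
#' @return list with character vectors `up` and `down`.
#' @export
deg_filter <- function(table, lfc_min = 1.0, alpha = 0.05) {
  sig <- !is.na(table$padj) & table$padj < alpha
  list(up = sort(table$gene[sig & table$log2fc >= lfc_min]),
       down = sort(table$gene[sig & table$log2fc <= -lfc_min]))
}

#' Filter compounds by external signature-similarity score
#'
#' Retains records whose summary score meets the cutoff (inclusive), sorted
#' by score descending. The scores themselves come from an external
#' connectivity-map style resource and are consumed, not computed, here.
#'
#' @param records data frame with columns `compound` and `score`.
#' @param cutoff minimum score retained (default 80, inclusive).
#' @return filtered records sorted by score descending then compound id.
#' @export
similarity_filter <- function(records, cutoff = 80) {
  stopifnot(all(c("compound", "score") %in% names(records)))
  out <- records[records$score >= cutoff, , drop = FALSE]
  out <- out[order(-out$score, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a compound similarity-score table from TSV (compound, score)
#' @param path TSV path.
#' @return data frame with `compound`, `score`.
#' @export
load_similarity <- function(path) {
  df <- read_tsv_dialect(path, min_cols = 2)
  data.frame(compound = df[[1]], score = as.numeric(df[[2]]),
             stringsAsFactors = FALSE)
}

#' Enrich significant DEGs against a gene-set library
#'
#' Delegates to [ora()]. By default up- and downregulated genes are pooled;
#' `mode = "split"` tests them separately.
#'
#' @param degs output of [deg_filter()].
#' @param library a `geneset_library`.
#' @param universe background gene ids.
#' @param mode `"joint"` (default) or `"split"`.
#' @param ... passed to [ora()].
#' @return an `enrichment` data frame (`joint`), or a named list of two
#'   (`split`).
#' @export
deg_enrich <- function(degs, library, universe, mode = c("joint", "split"),
                       ...) {
  mode <- match.arg(mode)
  if (mode == "joint") {
    ora(c(degs$up, degs$down), library, universe, ...)
  } else {
    list(up = ora(degs$up, library, universe, ...),
         down = ora(degs$down, library, universe, ...))
  }
}
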