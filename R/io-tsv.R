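# Shared TSV dialect: tab-delimited, '#'-prefixed comment lines skipped,
# first row treated as a header iff every cell matches a known header name.

.default_header_names <- c(
  "herb", "compound", "component", "target", "gene", "protein", "function",
  "node1", "node2", "from", "to", "child", "parent", "source",
  "association_type", "evidence", "cid", "entrez", "symbol", "score",
  "summary_score", "log2fc", "lfc", "padj", "adj_p", "p", "pvalue",
  "class", "probability", "node", "term", "description", "level", "mapped"
)

#' Read a tab-separated table in the package's dialect
#'
#' Tab-delimited, `#` comment lines skipped, no quoting. The first row is
#' treated as a header row iff all of its cells (lowercased) appear in
#' `header_names`; otherwise it is data.
#'
#' @param path file path.
#' @param min_cols minimum number of columns required.
#' @param header_names character vector of recognized header tokens.
#' @return data frame of character columns (no header names preserved beyond
#'   positional `V1`, `V2`, ...).
#' @keywords internal
read_tsv_dialect <- function(path, min_cols = 2,
                             header_names = .default_header_names) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- tryCatch(
    read.delim(path, header = FALSE, sep = "\t", quote = "",
               comment.char = "#", colClasses = "character",
               blank.lines.skip = TRUE, stringsAsFactors = FALSE),
    error = function(e) data.frame()
  )
  if (nrow(df) == 0) {
    return(df)
  }
  if (ncol(df) < min_cols) {
    stop("expected at least ", min_cols, " tab-separated columns in ", path,
         call. = FALSE)
  }
  first <- tolower(trimws(as.character(df[1, ])))
  if (all(first %in% tolower(header_names))) {
    names(df) <- first
    df <- df[-1, , drop = FALSE]
    rownames(df) <- NULL
  }
  for (j in seq_along(df)) df[[j]] <- trimws(df[[j]])
  df
}

# Reject rows with empty fields in the given columns; reports 1-based data-row
# line numbers (comment/blank lines are not counted, matching what a user sees
# after stripping comments).
.check_nonempty <- function(df, cols, path) {
  bad <- rep(FALSE, nrow(df))
  for (j in cols) bad <- bad | is.na(df[[j]]) | df[[j]] == ""
  if (any(bad)) {
    stop("rows with empty fields in ", path, " (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  }
  invisible(df)
}

# Fixed-format numeric for TSV output: 4 significant digits, matching the
# display precision of the ranked tables; JSON carries full precision.
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.4g", x))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}
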