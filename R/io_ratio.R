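## RatioTable: per-protein quantification across condition x time x
## replicate, the entry point of the pipeline. Stored as a numeric matrix
## (proteins x sample columns) plus a layout table mapping each sample column
## to its (condition, time, replicate) cell.

RT_CONDITIONS <- c("treated", "vehicle")

#' Construct a ratio table
#'
#' @param protein_id character vector of unique protein symbols (normalized
#'   to uppercase).
#' @param unique_peptides nonnegative integer per protein.
#' @param values numeric matrix, one row per protein, one column per sample;
#'   `NA` marks a missing quantification, all present values must be finite
#'   and positive (intensity/ratio scale).
#' @param layout data.frame with columns `column`, `condition`
#'   (`treated`/`vehicle`), `time` (minutes), `replicate`, one row per value
#'   column.
#' @return an object of class `ratio_table`.
#' @export
ratio_table <- function(protein_id, unique_peptides, values, layout) {
  protein_id <- normalize_symbol(protein_id)
  dup <- unique(protein_id[duplicated(protein_id)])
  if (length(dup))
    at_stop("ingestion_error", "duplicate protein_id: %s",
            paste(dup, collapse = ", "))
  values <- as.matrix(values)
  if (nrow(values) != length(protein_id))
    at_stop("ingestion_error", "values has %d rows for %d proteins",
            nrow(values), length(protein_id))
  need <- c("column", "condition", "time", "replicate")
  if (!all(need %in% names(layout)))
    at_stop("format_error", "layout must have columns %s",
            paste(need, collapse = ", "))
  if (!all(layout$condition %in% RT_CONDITIONS))
    at_stop("format_error", "conditions must be one of: %s",
            paste(RT_CONDITIONS, collapse = ", "))
  if (nrow(layout) != ncol(values))
    at_stop("ingestion_error", "layout describes %d columns, values has %d",
            nrow(layout), ncol(values))
  bad <- is.finite(values) & values <= 0
  if (any(bad, na.rm = TRUE))
    at_stop("ingestion_error", "non-positive values present (%d cells)",
            sum(bad, na.rm = TRUE))
  ## order columns by (condition, time, replicate), times ascending
  ord <- order(layout$condition, layout$time, layout$replicate)
  layout <- layout[ord, , drop = FALSE]
  values <- values[, ord, drop = FALSE]
  rownames(values) <- protein_id
  colnames(values) <- layout$column
  structure(list(protein_id = protein_id,
                 unique_peptides = as.integer(unique_peptides),
                 values = values,
                 layout = layout),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat(sprintf(
    "ratio_table: %d proteins, %d samples (%d conditions x %d time points x %d replicates)\n",
    length(x$protein_id), nrow(x$layout),
    length(unique(x$layout$condition)), length(rt_times(x)),
    length(unique(x$layout$replicate))))
  na <- sum(is.na(x$values))
  if (na) cat(sprintf("  %d missing entries\n", na))
  invisible(x)
}

#' Time points of a ratio table (ascending)
#' @param rt a `ratio_table`.
#' @export
rt_times <- function(rt) sort(unique(rt$layout$time))

#' Subset a ratio table by protein
#' @param rt a `ratio_table`.
#' @param keep logical or character index of proteins to retain.
#' @export
rt_subset <- function(rt, keep) {
  if (is.character(keep)) keep <- rt$protein_id %in% normalize_symbol(keep)
  ratio_table(rt$protein_id[keep], rt$unique_peptides[keep],
              rt$values[keep, , drop = FALSE], rt$layout)
}

## Default column-name convention: <condition>_t<time>_r<replicate>.
parse_default_layout <- function(cols) {
  pat <- "^(treated|vehicle)_t([0-9]+)_r([0-9]+)$"
  ok <- grepl(pat, cols)
  if (!all(ok)) return(NULL)
  data.frame(column = cols,
             condition = sub(pat, "\\1", cols),
             time = as.numeric(sub(pat, "\\2", cols)),
             replicate = as.integer(sub(pat, "\\3", cols)),
             stringsAsFactors = FALSE)
}

#' Read a ratio table from TSV
#'
#' The file must contain `protein_id` and `unique_peptides` columns followed
#' by one column per sample. Sample columns are mapped to (condition, time,
#' replicate) either by an explicit `layout` data.frame or, by default, by
#' parsing names of the form `treated_t5_r1`. Rows containing non-positive or
#' unparsable values are dropped with a logged count; missing entries (`NA`)
#' are kept and flagged.
#'
#' @param path TSV file.
#' @param layout optional data.frame with columns `column`, `condition`,
#'   `time`, `replicate`.
#' @return a [ratio_table()].
#' @export
read_ratio_table <- function(path, layout = NULL) {
  df <- read_tsv(path)
  need <- c("protein_id", "unique_peptides")
  if (!all(need %in% names(df)))
    at_stop("format_error", "missing required columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  vcols <- setdiff(names(df), need)
  if (is.null(layout)) {
    layout <- parse_default_layout(vcols)
    if (is.null(layout))
      at_stop("format_error",
              "cannot parse sample columns; supply an explicit layout")
  } else {
    miss <- setdiff(layout$column, vcols)
    if (length(miss))
      at_stop("format_error", "layout names absent from file: %s",
              paste(miss, collapse = ", "))
    vcols <- layout$column
  }
  ids <- normalize_symbol(df$protein_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    at_stop("ingestion_error", "duplicate protein_id: %s",
            paste(dup, collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[vcols], function(col) as.numeric(col), numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(ids, vcols))
  bad_row <- apply(vals, 1, function(r) any(is.finite(r) & r <= 0))
  ## a cell that was text in the file parses to NA; treat rows where the raw
  ## field was non-empty but the parse gave NA as unparsable
  raw_na <- vapply(df[vcols], function(col)
    is.na(suppressWarnings(as.numeric(col))) & !(is.na(col) | col == "" | col == "NA"),
    logical(nrow(df)))
  raw_na <- matrix(raw_na, nrow = nrow(df))
  bad_row <- bad_row | apply(raw_na, 1, any)
  if (any(bad_row)) {
    at_log("read_ratio_table: dropping %d row(s) with non-positive or unparsable values",
           sum(bad_row))
    vals <- vals[!bad_row, , drop = FALSE]
    df <- df[!bad_row, , drop = FALSE]
    ids <- ids[!bad_row]
  }
  if (anyNA(vals))
    at_log("read_ratio_table: %d missing entries flagged", sum(is.na(vals)))
  ratio_table(ids, df$unique_peptides, vals, layout)
}

#' Write a ratio table to TSV
#'
#' Inverse of [read_ratio_table()]: `read_ratio_table(write_ratio_table(x))`
#' reproduces `x` up to column order.
#'
#' @param rt a `ratio_table`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ratio_table <- function(rt, path) {
  df <- data.frame(protein_id = rt$protein_id,
                   unique_peptides = rt$unique_peptides,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(rt$values, check.names = FALSE))
  write_tsv(df, path)
}
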