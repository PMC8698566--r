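#' @keywords internal
"_PACKAGE"

## Shared internal helpers: logging, seed handling, tiny hashing, symbol
## normalization. Kept deliberately dependency-free.

at_log <- function(fmt, ...) {
  message(sprintf(paste0("[androtime] ", fmt), ...))
}

at_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "androtime_error")))
}

at_warn <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

#' Normalize protein identifiers to uppercase gene symbols
#'
#' All joins across quantification, annotation, interaction and marker tables
#' are case-insensitive on gene symbols; this is the single normalization
#' point.
#'
#' @param x character vector of identifiers.
#' @return uppercase, whitespace-trimmed character vector.
#' @export
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

## Evaluate an expression under a local RNG state seeded with `seed`,
## restoring the caller's RNG afterwards so generators are pure functions of
## (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    at_stop("parameter_error", "seed must be a single integer, got %s",
            deparse(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and a stage offset, kept within
## 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

## FNV-1a 32-bit hash of a character vector; used for the run-manifest config
## fingerprint. Arithmetic in double precision, multiplication split into
## 16-bit halves to stay exact under 2^53.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## Write a data.frame as TSV (no quoting surprises, no row names).
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}
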