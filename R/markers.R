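## Consensus differential-expression marker calling across independent
## expression datasets, paired tumor/normal testing, and intersection of
## the markers with the temporal clusters.

#' Construct an expression dataset
#'
#' @param exprs numeric genes x samples matrix (positive raw scale or
#'   already log scale; see [normalize_dataset()]).
#' @param group factor/character of length `ncol(exprs)` with two levels
#'   (e.g. naive/refractory or normal/tumor; the second level is the case
#'   group).
#' @param pair_id optional pair identifiers for paired designs.
#' @param dataset_id label used in marker reports.
#' @return an object of class `expression_dataset`.
#' @export
expression_dataset <- function(exprs, group, pair_id = NULL,
                               dataset_id = "dataset") {
  exprs <- as.matrix(exprs)
  group <- as.factor(group)
  if (length(group) != ncol(exprs))
    at_stop("ingestion_error", "group length != number of samples")
  if (nlevels(group) != 2)
    at_stop("ingestion_error", "group must have exactly 2 levels")
  if (any(table(group) < 2))
    at_stop("ingestion_error", "need >= 2 samples per group")
  if (any(!is.finite(exprs)))
    at_stop("ingestion_error", "non-finite expression values")
  rownames(exprs) <- normalize_symbol(rownames(exprs))
  structure(list(exprs = exprs, group = group, pair_id = pair_id,
                 dataset_id = dataset_id),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset %s: %d genes x %d samples (%s)%s\n",
              x$dataset_id, nrow(x$exprs), ncol(x$exprs),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", "),
              if (!is.null(x$pair_id)) ", paired" else ""))
  invisible(x)
}

#' Normalize an expression dataset
#'
#' Log-transforms (log2; values <= 0 are shifted by a logged offset
#' first), median-centers each array, and scales each array to unit
#' standard deviation. Constant arrays are dropped with a warning. With
#' `log = FALSE` the values are taken as already log scale.
#'
#' @param ds an [expression_dataset()].
#' @param log apply the log2 transform.
#' @return the normalized `expression_dataset` (per-array median 0, sd 1).
#' @export
normalize_dataset <- function(ds, log = TRUE) {
  x <- ds$exprs
  if (log) {
    if (any(x <= 0)) {
      offset <- 1 - min(x)
      at_log("normalize_dataset[%s]: shifting by %.4g before log",
             ds$dataset_id, offset)
      x <- x + offset
    }
    x <- log2(x)
  }
  sds <- apply(x, 2, stats::sd)
  const <- sds < 1e-12
  if (any(const)) {
    at_warn("normalize_dataset[%s]: dropping %d constant array(s)",
            ds$dataset_id, sum(const))
    x <- x[, !const, drop = FALSE]
    ds$group <- droplevels(ds$group[!const])
    if (!is.null(ds$pair_id)) ds$pair_id <- ds$pair_id[!const]
    sds <- sds[!const]
  }
  x <- sweep(x, 2, apply(x, 2, stats::median), "-")
  x <- sweep(x, 2, apply(x, 2, stats::sd), "/")
  ds$exprs <- x
  ds
}

## t.test refuses essentially-constant data; map that degenerate case to
## the evidence it carries: no mean difference -> t = 0, p = 1; an exactly
## constant nonzero difference -> unbounded t, p = 0.
safe_t <- function(expr, mean_diff) {
  out <- tryCatch(expr, error = function(e) NULL)
  if (!is.null(out) && is.finite(out$p.value))
    return(c(out$statistic, out$p.value))
  if (abs(mean_diff) < 1e-12) c(0, 1) else c(sign(mean_diff) * Inf, 0)
}

#' Per-gene two-group differential expression
#'
#' Two-sample t-test per gene (equal-variance by default, Welch optional);
#' direction is the sign of case mean minus control mean (the second group
#' level is the case).
#'
#' @param ds a normalized [expression_dataset()].
#' @param alpha per-dataset significance cutoff (default 0.05).
#' @param var_equal pooled-variance t-test (classic microarray practice);
#'   `FALSE` for Welch.
#' @return data.frame: gene, t, p, mean_diff, direction (up/down),
#'   significant.
#' @export
dataset_de <- function(ds, alpha = 0.05, var_equal = TRUE) {
  ctrl <- levels(ds$group)[1]
  case <- levels(ds$group)[2]
  xc <- ds$exprs[, ds$group == ctrl, drop = FALSE]
  xt <- ds$exprs[, ds$group == case, drop = FALSE]
  res <- t(vapply(seq_len(nrow(ds$exprs)), function(i) {
    md <- mean(xt[i, ]) - mean(xc[i, ])
    c(safe_t(stats::t.test(xt[i, ], xc[i, ], var.equal = var_equal), md),
      md)
  }, numeric(3)))
  out <- data.frame(gene = rownames(ds$exprs),
                    dataset_id = ds$dataset_id,
                    t = res[, 1], p = res[, 2], mean_diff = res[, 3],
                    direction = ifelse(res[, 3] >= 0, "up", "down"),
                    significant = res[, 2] < alpha,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Consensus marker calling across independent datasets
#'
#' A gene is a consensus marker when it is significantly changed in the
#' same direction in at least `min_support` (default 2) independent
#' datasets. Genes significant in opposite directions in different
#' datasets, without reaching consensus, are reported separately as
#' conflicts.
#'
#' @param de_list list of [dataset_de()] tables (one per dataset).
#' @param min_support minimum number of same-direction supporting
#'   datasets.
#' @return list of class `marker_calls`: `markers` (gene, direction,
#'   n_support, supporting dataset ids), `conflicts`, and `per_dataset`
#'   (the significant calls underlying both).
#' @export
consensus_markers <- function(de_list, min_support = 2) {
  calls <- do.call(rbind, de_list)
  sig <- calls[calls$significant, , drop = FALSE]
  markers <- NULL
  conflicts <- character(0)
  for (g in sort(unique(sig$gene))) {
    sg <- sig[sig$gene == g, , drop = FALSE]
    nup <- sum(sg$direction == "up")
    ndn <- sum(sg$direction == "down")
    dir <- if (nup >= min_support && nup >= ndn) "up"
    else if (ndn >= min_support) "down" else NA_character_
    if (!is.na(dir)) {
      sup <- sg$dataset_id[sg$direction == dir]
      markers <- rbind(markers, data.frame(
        gene = g, direction = dir, n_support = length(sup),
        datasets = paste(sort(sup), collapse = ","),
        stringsAsFactors = FALSE))
    } else if (nup > 0 && ndn > 0) {
      conflicts <- c(conflicts, g)
    }
  }
  if (is.null(markers))
    markers <- data.frame(gene = character(0), direction = character(0),
                          n_support = integer(0), datasets = character(0),
                          stringsAsFactors = FALSE)
  structure(list(markers = markers, conflicts = conflicts,
                 per_dataset = sig, min_support = min_support),
            class = "marker_calls")
}

#' @export
print.marker_calls <- function(x, ...) {
  cat(sprintf(
    "marker_calls: %d consensus markers (%d up, %d down), %d conflicting gene(s)\n",
    nrow(x$markers), sum(x$markers$direction == "up"),
    sum(x$markers$direction == "down"), length(x$conflicts)))
  invisible(x)
}

#' Paired tumor/normal differential expression
#'
#' Per-gene test of tumor versus matched normal samples. With pair
#' identifiers the statistically proper paired t-test is the default; the
#' published analysis used an unpaired two-sample test, available as
#' `paired = FALSE`. Also emits the per-gene z-score matrix used for
#' heatmaps.
#'
#' @param ds a normalized [expression_dataset()] with `pair_id` set (for
#'   the paired mode).
#' @param alpha significance cutoff (default 0.01).
#' @param paired use the paired test.
#' @param var_equal pooled variance in the unpaired mode.
#' @return list: `results` (gene, t, p, mean_diff, direction,
#'   significant), `zscores` (genes x samples).
#' @export
paired_de <- function(ds, alpha = 0.01, paired = TRUE, var_equal = TRUE) {
  ctrl <- levels(ds$group)[1]
  case <- levels(ds$group)[2]
  if (paired) {
    if (is.null(ds$pair_id))
      at_stop("parameter_error", "paired test requires pair_id")
    po <- order(ds$pair_id)
    idx_c <- po[ds$group[po] == ctrl]
    idx_t <- po[ds$group[po] == case]
    if (!identical(ds$pair_id[idx_c], ds$pair_id[idx_t]))
      at_stop("ingestion_error", "pair ids do not match across groups")
  }
  xc <- ds$exprs[, if (paired) idx_c else ds$group == ctrl, drop = FALSE]
  xt <- ds$exprs[, if (paired) idx_t else ds$group == case, drop = FALSE]
  res <- t(vapply(seq_len(nrow(ds$exprs)), function(i) {
    md <- mean(xt[i, ]) - mean(xc[i, ])
    tt <- if (paired) quote(stats::t.test(xt[i, ], xc[i, ], paired = TRUE))
    else quote(stats::t.test(xt[i, ], xc[i, ], var.equal = var_equal))
    c(safe_t(eval(tt), md), md)
  }, numeric(3)))
  results <- data.frame(gene = rownames(ds$exprs),
                        t = res[, 1], p = res[, 2], mean_diff = res[, 3],
                        direction = ifelse(res[, 3] >= 0, "up", "down"),
                        significant = res[, 2] < alpha,
                        stringsAsFactors = FALSE)
  z <- t(scale(t(ds$exprs)))
  list(results = results, zscores = z)
}

#' Intersect consensus markers with the temporal clusters
#'
#' Joins markers to the cluster assignment on gene symbol and tabulates
#' up/down markers per cluster, plus a long (gene, cluster, dataset,
#' direction) table for heatmap-style layouts.
#'
#' @param markers a `marker_calls` object.
#' @param assignment a labeled `cluster_assignment`.
#' @return list: `table` (gene, cluster, direction, n_support, datasets),
#'   `per_cluster` (cluster x direction counts), `long` (one row per
#'   supporting dataset).
#' @export
intersect_with_clusters <- function(markers, assignment) {
  lab <- stats::setNames(assignment$assigned$cluster,
                         assignment$assigned$protein_id)
  mk <- markers$markers
  mk$cluster <- unname(lab[mk$gene])
  mk <- mk[!is.na(mk$cluster), , drop = FALSE]
  if (!nrow(mk))
    at_warn("intersect_with_clusters: no marker maps to a clustered protein")
  per_cluster <- table(factor(mk$cluster,
                              levels = sort(unique(unname(lab)))),
                       factor(mk$direction, levels = c("up", "down")))
  long <- if (nrow(mk)) {
    do.call(rbind, lapply(seq_len(nrow(mk)), function(i)
      data.frame(gene = mk$gene[i], cluster = mk$cluster[i],
                 dataset = strsplit(mk$datasets[i], ",")[[1]],
                 direction = mk$direction[i], stringsAsFactors = FALSE)))
  } else data.frame(gene = character(0), cluster = character(0),
                    dataset = character(0), direction = character(0))
  list(table = mk, per_cluster = unclass(per_cluster), long = long)
}

#' Write an expression dataset to TSV (two header rows)
#'
#' First header row: sample group; second: pair id (or `NA`); then one row
#' per gene.
#'
#' @param ds an [expression_dataset()].
#' @param path output file.
#' @export
write_expression_dataset <- function(ds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("group", as.character(ds$group)), collapse = "\t"),
             con)
  pid <- if (is.null(ds$pair_id)) rep(NA, ncol(ds$exprs)) else ds$pair_id
  writeLines(paste(c("pair_id", pid), collapse = "\t"), con)
  utils::write.table(
    data.frame(gene = rownames(ds$exprs), ds$exprs, check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression dataset written by [write_expression_dataset()]
#' @param path TSV file.
#' @param dataset_id label for the dataset.
#' @return an [expression_dataset()].
#' @export
read_expression_dataset <- function(path, dataset_id = basename(path)) {
  lines <- readLines(path, n = 2)
  group <- strsplit(lines[1], "\t")[[1]][-1]
  pid <- strsplit(lines[2], "\t")[[1]][-1]
  df <- utils::read.delim(path, skip = 2, check.names = FALSE,
                          stringsAsFactors = FALSE)
  exprs <- as.matrix(df[, -1, drop = FALSE])
  rownames(exprs) <- df[[1]]
  pid <- suppressWarnings(as.integer(pid))
  expression_dataset(exprs, group,
                     pair_id = if (all(is.na(pid))) NULL else pid,
                     dataset_id = dataset_id)
}
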