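## Hypergeometric over-representation of annotation categories within the
## temporal clusters, plus the per-cluster composition profiles behind the
## strip charts.

## Upper-tail hypergeometric over-representation p-value:
## P[X >= x] with X ~ Hypergeometric(M items, K of them in the category,
## n drawn).
hyper_upper_p <- function(x, n, K, M) {
  stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of annotation categories per cluster
#'
#' For every (cluster, category) pair tests whether the cluster contains
#' more proteins of the category than expected under sampling without
#' replacement from the universe. The universe is the set of labeled
#' proteins carrying an annotation of the requested kind; proteins
#' annotated `other/unknown` are excluded from both universe and category
#' counts. One-sided (enrichment only), no multiple-testing correction (as
#' in the published thresholds), with a Benjamini-Hochberg column added for
#' transparency.
#'
#' @param assignment a labeled `cluster_assignment`.
#' @param annotations an [annotation_table()].
#' @param kind `"compartment"` or `"molecular_type"`.
#' @param alpha significance cutoff for the `significant` flag (default
#'   0.001 for compartments, 0.05 for molecular types — pass explicitly).
#' @return data.frame of class `enrichment_result`, sorted by p-value, with
#'   counts (`x` in-cluster-in-category, `n` cluster size, `K` category
#'   size, `M` universe size), `p`, `fold` enrichment `(x/n)/(K/M)`,
#'   `p_adj` (BH) and `significant`.
#' @export
hypergeom_enrich <- function(assignment, annotations,
                             kind = c("compartment", "molecular_type"),
                             alpha = 0.05) {
  kind <- match.arg(kind)
  ann <- as.data.frame(annotations)
  df <- merge(assignment$assigned, ann, by = "protein_id")
  df$category <- df[[kind]]
  df <- df[df$category != "other/unknown", , drop = FALSE]
  if (!nrow(df))
    at_stop("pipeline_error", "empty enrichment universe for kind '%s'",
            kind)
  M <- nrow(df)
  res <- do.call(rbind, lapply(sort(unique(df$cluster)), function(cl) {
    incl <- df$cluster == cl
    n <- sum(incl)
    do.call(rbind, lapply(sort(unique(df$category)), function(cat) {
      K <- sum(df$category == cat)
      x <- sum(incl & df$category == cat)
      data.frame(cluster = cl, category = cat, kind = kind,
                 x = x, n = n, K = K, M = M,
                 p = hyper_upper_p(x, n, K, M),
                 fold = (x / n) / (K / M),
                 stringsAsFactors = FALSE)
    }))
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p < alpha
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Per-cluster annotation composition (percentages)
#'
#' Percentage of each category among the annotated members of each
#' cluster; rows (clusters) sum to 100. Also returned in long format for
#' strip-chart plotting.
#'
#' @inheritParams hypergeom_enrich
#' @return list with `percent` (clusters x categories matrix) and `long`
#'   (cluster, category, count, percent).
#' @export
composition_profile <- function(assignment, annotations,
                                kind = c("compartment", "molecular_type")) {
  kind <- match.arg(kind)
  ann <- as.data.frame(annotations)
  df <- merge(assignment$assigned, ann, by = "protein_id")
  df$category <- df[[kind]]
  tab <- table(df$cluster, df$category)
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(long) <- c("cluster", "category", "count")
  long$percent <- as.data.frame(pct)$Freq
  list(percent = unclass(pct), long = long)
}
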