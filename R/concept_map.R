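## Fisher's-exact association of protein clusters with molecular concepts
## (gene sets), and the concept-map network built from the retained
## associations.

#' Fisher association between clusters and gene-set concepts
#'
#' For each (cluster, concept) pair forms the 2x2 table over the universe
#' (a: in cluster and in concept, b: in cluster only, c: in concept only,
#' d: neither) and computes the sample odds ratio `ad/bc` and the
#' one-sided (enrichment) Fisher p-value. An association is retained when
#' `p < alpha` and `OR > or_floor` (published rule: p < 0.001, OR > 2).
#' Concepts disjoint from the universe are skipped with a warning. When a
#' zero cell occurs the odds ratio uses the Haldane-Anscombe 0.5 correction
#' and is flagged; the raw cells are always reported.
#'
#' @param assignment a labeled `cluster_assignment` (the universe is its
#'   labeled protein set unless `universe` is supplied).
#' @param concepts named list of gene sets (e.g. from [read_gmt()] or
#'   [generate_concepts()]).
#' @param universe optional character vector overriding the universe (e.g.
#'   all quantified proteins).
#' @param alpha retention p cutoff.
#' @param or_floor retention odds-ratio floor (strict).
#' @return data.frame of class `concept_association`: cluster, concept,
#'   cells a-d, odds ratio, p, `or_corrected` flag, `retained`.
#' @export
fisher_associate <- function(assignment, concepts, universe = NULL,
                             alpha = 0.001, or_floor = 2) {
  if (is.null(universe)) universe <- assignment$assigned$protein_id
  universe <- unique(normalize_symbol(universe))
  lab <- stats::setNames(assignment$assigned$cluster,
                         assignment$assigned$protein_id)
  res <- NULL
  for (cn in names(concepts)) {
    set <- intersect(normalize_symbol(concepts[[cn]]), universe)
    if (!length(set)) {
      at_warn("fisher_associate: concept %s is disjoint from the universe, skipped",
              cn)
      next
    }
    for (cl in sort(unique(unname(lab[universe])))) {
      incl <- universe[!is.na(lab[universe]) & lab[universe] == cl]
      a <- length(intersect(incl, set))
      b <- length(incl) - a
      cc <- length(set) - a
      d <- length(universe) - a - b - cc
      corrected <- a == 0 || b == 0 || cc == 0 || d == 0
      or <- if (corrected)
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
      else (a * d) / (b * cc)
      p <- hyper_upper_p(a, a + b, a + cc, a + b + cc + d)
      res <- rbind(res, data.frame(
        cluster = cl, concept = cn, a = a, b = b, c = cc, d = d,
        odds_ratio = or, p = p, or_corrected = corrected,
        retained = p < alpha & or > or_floor,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(res))
    res <- data.frame(cluster = character(0), concept = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), or_corrected = logical(0),
                      retained = logical(0))
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  class(res) <- c("concept_association", "data.frame")
  res
}

#' Build the concept-map network from retained associations
#'
#' Bipartite graph over cluster nodes and the concepts retained by
#' [fisher_associate()]; concept node size is the gene count, edge
#' thickness is `-log10(p)`.
#'
#' @param associations a `concept_association` table.
#' @param concepts the gene-set list (for node sizes).
#' @return an `igraph` with node attributes `kind` (cluster/concept) and
#'   `size`, and edge attribute `thickness`; exportable via
#'   [write_network()].
#' @export
build_concept_map <- function(associations, concepts) {
  kept <- associations[associations$retained, , drop = FALSE]
  clusters <- sort(unique(associations$cluster))
  vertices <- rbind(
    data.frame(name = clusters, kind = "cluster", size = NA_real_,
               stringsAsFactors = FALSE),
    if (nrow(kept))
      data.frame(name = unique(kept$concept), kind = "concept",
                 size = lengths(concepts[unique(kept$concept)]),
                 stringsAsFactors = FALSE))
  edges <- if (nrow(kept))
    data.frame(from = kept$cluster, to = kept$concept,
               thickness = -log10(kept$p), stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0),
                  thickness = numeric(0))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}
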