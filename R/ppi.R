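## PPI-network integration: restriction to the labeled proteome, hub
## ranking, the AR neighborhood, cluster-pair interaction statistics, the
## molecular-type interaction map, and enumeration of C->D->E signaling
## cascades with their nine-region compartment layout.

#' Restrict a PPI network to the labeled proteome
#'
#' Induced subgraph on the proteins carrying a cluster label; cluster (and,
#' when annotations are given, compartment and molecular type) become node
#' attributes.
#'
#' @param network an undirected `igraph` over gene symbols.
#' @param assignment a labeled `cluster_assignment`.
#' @param annotations optional [annotation_table()].
#' @return the induced `igraph`.
#' @export
restrict_network <- function(network, assignment, annotations = NULL) {
  ids <- assignment$assigned$protein_id
  common <- intersect(igraph::V(network)$name, ids)
  if (!length(common))
    at_warn("restrict_network: no labeled protein occurs in the network")
  g <- igraph::induced_subgraph(network, common)
  lab <- stats::setNames(assignment$assigned$cluster, ids)
  igraph::V(g)$cluster <- unname(lab[igraph::V(g)$name])
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    comp <- stats::setNames(ann$compartment, ann$protein_id)
    typ <- stats::setNames(ann$molecular_type, ann$protein_id)
    igraph::V(g)$compartment <- unname(comp[igraph::V(g)$name])
    igraph::V(g)$molecular_type <- unname(typ[igraph::V(g)$name])
  }
  g
}

#' Rank hub proteins by degree
#'
#' @param network an `igraph`.
#' @param top_n rows to return (ties broken by symbol for determinism).
#' @param focus symbols always appended (e.g. `"AR"`), regardless of rank.
#' @return data.frame (symbol, degree, rank).
#' @export
hub_degrees <- function(network, top_n = 15, focus = character(0)) {
  deg <- igraph::degree(network)
  ord <- order(-deg, names(deg))
  out <- data.frame(symbol = names(deg)[ord], degree = unname(deg[ord]),
                    rank = seq_along(deg), stringsAsFactors = FALSE)
  sel <- utils::head(out, top_n)
  focus <- normalize_symbol(focus)
  extra <- out[out$symbol %in% setdiff(focus, sel$symbol), , drop = FALSE]
  rbind(sel, extra)
}

#' Neighborhood subgraph of a focus protein
#'
#' Nodes within `radius` graph steps of the focus (its first and second
#' interaction shells by default), with any node attributes preserved.
#'
#' @param network an `igraph`.
#' @param focus protein symbol (error if absent).
#' @param radius neighborhood order.
#' @return the ego `igraph`, with a `shell` node attribute (graph distance
#'   from the focus).
#' @export
ego_neighborhood <- function(network, focus = "AR", radius = 2) {
  focus <- normalize_symbol(focus)
  if (!focus %in% igraph::V(network)$name)
    at_stop("ingestion_error", "focus protein %s absent from the network",
            focus)
  nodes <- igraph::ego(network, order = radius, nodes = focus)[[1]]
  g <- igraph::induced_subgraph(network, nodes)
  d <- igraph::distances(g, v = focus)[1, ]
  igraph::V(g)$shell <- as.integer(d[igraph::V(g)$name])
  g
}

pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "/"), paste(b, a, sep = "/"))
}

#' Cluster-pair interaction counts and over-representation
#'
#' Counts the network edges joining every unordered pair of clusters
#' (within-cluster pairs included) and expresses them as percentages of all
#' counted edges; percentages are reported both over all pairs and over the
#' inter-cluster pairs only. Each pair is tested for edge
#' over-representation with an upper-tail hypergeometric: among the
#' `M = choose(N,2)` protein pairs of the labeled network, `K` carry an
#' edge; of the `n` pairs spanning the two clusters, `x` carry one.
#' A degree-preserving rewiring null is available as a robustness column.
#'
#' @param network the cluster-annotated `igraph` from
#'   [restrict_network()] (or any graph whose nodes appear in
#'   `assignment`).
#' @param assignment a labeled `cluster_assignment`.
#' @param alpha cutoff for the flagged set.
#' @param rewire_B optional number of degree-preserving rewiring
#'   permutations for an empirical p column (0 disables).
#' @param seed seed for the rewiring null.
#' @return data.frame of class `cluster_pair_stats`: pair, clusters, edge
#'   count, pair universe sizes, percentages, `p`, flag (and `p_rewire`
#'   when requested).
#' @export
cluster_pair_stats <- function(network, assignment, alpha = 0.05,
                               rewire_B = 0, seed = 1L) {
  lab <- stats::setNames(assignment$assigned$cluster,
                         assignment$assigned$protein_id)
  nodes <- intersect(igraph::V(network)$name, names(lab))
  g <- igraph::induced_subgraph(network, nodes)
  clusters <- sort(unique(unname(lab[nodes])))
  if (length(clusters) < 2)
    at_stop("pipeline_error", "need at least 2 clusters with network nodes")
  sizes <- table(factor(unname(lab[nodes]), levels = clusters))
  N <- length(nodes)
  M <- N * (N - 1) / 2
  K <- igraph::ecount(g)
  el <- igraph::as_edgelist(g)
  ekey <- pair_key(unname(lab[el[, 1]]), unname(lab[el[, 2]]))
  count_by <- function(keys) {
    tab <- table(keys)
    function(k) if (k %in% names(tab)) as.integer(tab[[k]]) else 0L
  }
  cnt <- count_by(ekey)
  res <- do.call(rbind, lapply(seq_along(clusters), function(i)
    do.call(rbind, lapply(i:length(clusters), function(j) {
      c1 <- clusters[i]; c2 <- clusters[j]
      npairs <- if (i == j) sizes[[c1]] * (sizes[[c1]] - 1) / 2
      else sizes[[c1]] * sizes[[c2]]
      x <- cnt(pair_key(c1, c2))
      data.frame(pair = pair_key(c1, c2), cluster1 = c1, cluster2 = c2,
                 within = i == j, edges = x, pair_universe = npairs,
                 p = hyper_upper_p(x, npairs, K, M),
                 stringsAsFactors = FALSE)
    }))))
  res$percent <- 100 * res$edges / sum(res$edges)
  inter <- !res$within
  res$percent_inter <- NA_real_
  res$percent_inter[inter] <- 100 * res$edges[inter] / sum(res$edges[inter])
  res$flagged <- res$p < alpha
  if (rewire_B > 0) {
    ge <- sapply(seq_len(rewire_B), function(b) {
      gr <- with_seed(child_seed(seed, b),
                      igraph::rewire(g, igraph::keeping_degseq(
                        niter = max(100, 10 * K))))
      elr <- igraph::as_edgelist(gr)
      kr <- pair_key(unname(lab[elr[, 1]]), unname(lab[elr[, 2]]))
      cntr <- count_by(kr)
      vapply(res$pair, cntr, integer(1))
    })
    ge <- matrix(ge, nrow = nrow(res))
    res$p_rewire <- (rowSums(ge >= res$edges) + 1) / (rewire_B + 1)
  }
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  class(res) <- c("cluster_pair_stats", "data.frame")
  res
}

#' Molecular-type interaction map
#'
#' For every pair of molecular types computes the fraction of interacting
#' member pairs (cross-type edges over the product of type sizes); a map
#' edge is kept when the fraction strictly exceeds `fraction_threshold`
#' (default 1%, with 5% as the summarized-map alternative), and flagged as
#' significant by the same hypergeometric scheme as
#' [cluster_pair_stats()]. Edge direction follows the temporal signal
#' flow: from the type whose members sit in earlier clusters (mean cluster
#' rank, A=1 ... E=5) toward the later one; equal ranks give an undirected
#' edge.
#'
#' @param network cluster-annotated graph from [restrict_network()].
#' @param annotations [annotation_table()].
#' @param assignment labeled `cluster_assignment`.
#' @param fraction_threshold minimum interacting-pair fraction (strict).
#' @param alpha significance cutoff.
#' @return data.frame of class `type_interaction_map`: from, to, fraction,
#'   edges, p, significant, directed.
#' @export
type_interaction_map <- function(network, annotations, assignment,
                                 fraction_threshold = 0.01, alpha = 0.05) {
  ann <- as.data.frame(annotations)
  lab <- stats::setNames(assignment$assigned$cluster,
                         assignment$assigned$protein_id)
  typ <- stats::setNames(ann$molecular_type, ann$protein_id)
  ## members are all labeled, typed proteins: a protein without any
  ## interaction still counts toward its type's size
  members <- intersect(assignment$assigned$protein_id, names(typ))
  members <- members[typ[members] != "other/unknown"]
  nodes <- intersect(igraph::V(network)$name, members)
  g <- igraph::induced_subgraph(network, nodes)
  types <- sort(unique(unname(typ[members])))
  rank <- stats::setNames(seq_along(ARCHETYPES), ARCHETYPES)
  mean_rank <- vapply(types, function(tp) {
    cl <- unname(lab[members[typ[members] == tp]])
    mean(rank[cl], na.rm = TRUE)
  }, numeric(1))
  N <- length(members); M <- N * (N - 1) / 2
  K <- igraph::ecount(g)
  el <- igraph::as_edgelist(g)
  t1 <- unname(typ[el[, 1]]); t2 <- unname(typ[el[, 2]])
  out <- NULL
  for (i in seq_along(types)) for (j in seq_along(types)) {
    if (j <= i) next
    a <- types[i]; b <- types[j]
    na <- sum(typ[members] == a); nb <- sum(typ[members] == b)
    x <- sum((t1 == a & t2 == b) | (t1 == b & t2 == a))
    frac <- x / (na * nb)
    if (frac <= fraction_threshold) next
    p <- hyper_upper_p(x, na * nb, K, M)
    from <- a; to <- b; directed <- TRUE
    if (mean_rank[a] > mean_rank[b]) { from <- b; to <- a }
    else if (mean_rank[a] == mean_rank[b]) directed <- FALSE
    out <- rbind(out, data.frame(
      from = from, to = to, fraction = frac, edges = x,
      p = p, significant = p < alpha, directed = directed,
      stringsAsFactors = FALSE))
  }
  if (is.null(out))
    out <- data.frame(from = character(0), to = character(0),
                      fraction = numeric(0), edges = integer(0),
                      p = numeric(0), significant = logical(0),
                      directed = logical(0))
  attr(out, "mean_rank") <- mean_rank
  class(out) <- c("type_interaction_map", "data.frame")
  out
}
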