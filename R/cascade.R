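## Enumeration of C->D->E signaling cascades (ordered protein triples
## joined by two PPI edges) and their placement on the 3x3
## cluster-by-compartment grid.

#' Enumerate signaling cascades between three clusters
#'
#' Lists every ordered triple (c, d, e) with cluster labels C, D, E (by
#' default) such that edges c-d and d-e exist and c != e: the paths through
#' which a signal can travel from the mediator cluster to the terminal
#' regulators via the late stimulators. When `require_terminal_type` is
#' set (default `"transcription regulator"`, the type carried by every
#' terminal protein of the published cascade table) the terminal protein
#' must carry that molecular type. Output is in deterministic
#' lexicographic order and also grouped by the terminal (d, e) edge with
#' the upstream C members listed, mirroring the published table layout.
#'
#' @param network an `igraph` over labeled proteins.
#' @param assignment a labeled `cluster_assignment`.
#' @param annotations optional [annotation_table()]; required when a
#'   terminal-type filter or the type columns are wanted.
#' @param from_label,via_label,to_label cluster labels of the three stages.
#' @param require_terminal_type molecular type required of the terminal
#'   protein, or `NULL` to disable.
#' @return list of class `cascade_set`: `triples` (data.frame Protein_C,
#'   Protein_D, Protein_E and, with annotations, Type_C/D/E), `grouped`
#'   (per (d, e) edge: the C members), and the two counts `n_triples` and
#'   `n_grouped`.
#' @export
enumerate_cascades <- function(network, assignment, annotations = NULL,
                               from_label = "C", via_label = "D",
                               to_label = "E",
                               require_terminal_type = "transcription regulator") {
  lab <- stats::setNames(assignment$assigned$cluster,
                         assignment$assigned$protein_id)
  for (l in c(from_label, via_label, to_label))
    if (!l %in% lab)
      at_stop("parameter_error", "no protein carries cluster label %s", l)
  typ <- NULL
  if (!is.null(annotations)) {
    ann <- as.data.frame(annotations)
    typ <- stats::setNames(ann$molecular_type, ann$protein_id)
  }
  if (!is.null(require_terminal_type) && is.null(typ))
    at_stop("parameter_error",
            "annotations are required for the terminal-type filter")
  nodes <- intersect(igraph::V(network)$name, names(lab))
  g <- igraph::induced_subgraph(network, nodes)
  gl <- lab[igraph::V(g)$name]
  vias <- igraph::V(g)$name[gl == via_label]
  rows <- NULL
  for (d in vias) {
    nb <- igraph::neighbors(g, d)$name
    cs <- sort(nb[gl[nb] == from_label])
    es <- sort(nb[gl[nb] == to_label])
    if (!is.null(require_terminal_type))
      es <- es[typ[es] == require_terminal_type & !is.na(typ[es])]
    if (!length(cs) || !length(es)) next
    grid <- expand.grid(Protein_C = cs, Protein_E = es,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid <- grid[grid$Protein_C != grid$Protein_E, , drop = FALSE]
    if (!nrow(grid)) next
    rows <- rbind(rows, data.frame(Protein_C = grid$Protein_C,
                                   Protein_D = d,
                                   Protein_E = grid$Protein_E,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(rows))
    rows <- data.frame(Protein_C = character(0), Protein_D = character(0),
                       Protein_E = character(0), stringsAsFactors = FALSE)
  rows <- rows[order(rows$Protein_E, rows$Protein_D, rows$Protein_C), ,
               drop = FALSE]
  rownames(rows) <- NULL
  if (!is.null(typ) && nrow(rows)) {
    rows$Type_C <- unname(typ[rows$Protein_C])
    rows$Type_D <- unname(typ[rows$Protein_D])
    rows$Type_E <- unname(typ[rows$Protein_E])
  }
  grouped <- if (nrow(rows)) {
    agg <- stats::aggregate(Protein_C ~ Protein_D + Protein_E, rows,
                            function(x) paste(sort(unique(x)),
                                              collapse = ","))
    agg[order(agg$Protein_E, agg$Protein_D), , drop = FALSE]
  } else data.frame(Protein_D = character(0), Protein_E = character(0),
                    Protein_C = character(0))
  rownames(grouped) <- NULL
  structure(list(triples = rows, grouped = grouped,
                 n_triples = nrow(rows), n_grouped = nrow(grouped),
                 labels = c(from = from_label, via = via_label,
                            to = to_label)),
            class = "cascade_set")
}

#' @export
print.cascade_set <- function(x, ...) {
  cat(sprintf("cascade_set: %d %s->%s->%s triples over %d terminal edges\n",
              x$n_triples, x$labels["from"], x$labels["via"],
              x$labels["to"], x$n_grouped))
  invisible(x)
}

CASCADE_ROWS <- c("plasma membrane", "cytoplasm", "nucleus")

#' Lay out cascades on the nine-region cluster-by-compartment grid
#'
#' Places every distinct cascade member in one of nine regions: columns are
#' the three cascade stages (C, D, E) and rows the three main compartments
#' (plasma membrane, cytoplasm, nucleus). Compartments outside the grid
#' rows are mapped per configuration (extracellular space to the
#' plasma-membrane row, other/unknown to cytoplasm, logged). Edges run
#' C->D->E.
#'
#' @param cascades a `cascade_set`.
#' @param annotations an [annotation_table()] providing compartments.
#' @param compartment_rows named mapping of off-grid compartments to rows.
#' @return list of class `cascade_layout`: `regions` (3x3 occupancy
#'   counts), `placement` (protein, stage, compartment, row, column),
#'   `edges` (directed stage edges), `graph` (an `igraph` with `region`
#'   attributes, GraphML-exportable via [write_network()]).
#' @export
cascade_layout <- function(cascades, annotations,
                           compartment_rows = c(
                             "extracellular space" = "plasma membrane",
                             "other/unknown" = "cytoplasm")) {
  ann <- as.data.frame(annotations)
  comp <- stats::setNames(ann$compartment, ann$protein_id)
  tri <- cascades$triples
  stages <- c(cascades$labels[["from"]], cascades$labels[["via"]],
              cascades$labels[["to"]])
  members <- unique(data.frame(
    protein = c(tri$Protein_C, tri$Protein_D, tri$Protein_E),
    stage = rep(stages, each = nrow(tri)),
    stringsAsFactors = FALSE))
  cc <- unname(comp[members$protein])
  cc[is.na(cc)] <- "other/unknown"
  remapped <- !cc %in% CASCADE_ROWS
  if (any(remapped))
    at_log("cascade_layout: %d member(s) mapped onto grid rows (%s)",
           sum(remapped),
           paste(unique(sprintf("%s->%s", cc[remapped],
                                compartment_rows[cc[remapped]])),
                 collapse = ", "))
  row <- ifelse(remapped, unname(compartment_rows[cc]), cc)
  if (anyNA(row))
    at_stop("parameter_error", "compartment_rows must map every off-grid compartment")
  placement <- data.frame(protein = members$protein, stage = members$stage,
                          compartment = cc, row = row,
                          column = members$stage,
                          stringsAsFactors = FALSE)
  regions <- table(factor(placement$row, levels = CASCADE_ROWS),
                   factor(placement$column, levels = stages))
  edges <- unique(rbind(
    data.frame(from = tri$Protein_C, to = tri$Protein_D,
               stringsAsFactors = FALSE),
    data.frame(from = tri$Protein_D, to = tri$Protein_E,
               stringsAsFactors = FALSE)))
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(
      name = unique(placement$protein),
      region = vapply(unique(placement$protein), function(p) {
        i <- match(p, placement$protein)
        sprintf("%s|%s", placement$column[i], placement$row[i])
      }, character(1))))
  structure(list(regions = unclass(regions), placement = placement,
                 edges = edges, graph = g),
            class = "cascade_layout")
}
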