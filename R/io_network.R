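## PPI network ingestion (BioGRID TAB 3.0 and MITAB dialects) and
## Cytoscape-compatible exports (GraphML, SIF). Networks are undirected
## simple igraph objects over uppercase gene symbols.

DEFAULT_SYSTEMS <- c("direct interaction", "physical association", "physical")

## Column sets identifying each dialect.
TAB3_SYMBOL_COLS <- c("Official Symbol Interactor A",
                      "Official Symbol Interactor B")
MITAB_ID_COLS <- c("#ID Interactor A", "ID Interactor B")

#' Read a BioGRID interaction file into a PPI network
#'
#' Supports the BioGRID TAB 3.0 export (filtered on the
#' `Experimental System Type` column, plus an organism filter when the
#' organism columns are present) and the MITAB dialect (filtered on the
#' interaction-type term, e.g. `psi-mi:"MI:0915"(physical association)`).
#' Self-loops are removed and duplicate edges collapsed; the retained edge
#' count is logged.
#'
#' @param path tab-delimited interaction file.
#' @param allowed_systems experimental systems to retain. The default keeps
#'   direct interactions and physical associations (`"physical"` covers the
#'   TAB 3.0 system-type spelling).
#' @param taxid organism filter applied when organism columns exist
#'   (default human, 9606); `NA` disables it.
#' @return an undirected simple `igraph` with a `system` edge attribute.
#' @export
read_biogrid <- function(path, allowed_systems = DEFAULT_SYSTEMS,
                         taxid = 9606) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", quote = "")
  cols <- names(df)
  if (all(TAB3_SYMBOL_COLS %in% cols)) {
    a <- df[[TAB3_SYMBOL_COLS[1]]]
    b <- df[[TAB3_SYMBOL_COLS[2]]]
    sys <- if ("Experimental System Type" %in% cols)
      df[["Experimental System Type"]] else df[["Experimental System"]]
    if (!is.na(taxid) &&
        all(c("Organism ID Interactor A", "Organism ID Interactor B") %in% cols)) {
      keep_org <- df[["Organism ID Interactor A"]] == taxid &
        df[["Organism ID Interactor B"]] == taxid
      df <- df[keep_org, , drop = FALSE]
      a <- a[keep_org]; b <- b[keep_org]; sys <- sys[keep_org]
    }
  } else if (all(MITAB_ID_COLS %in% cols)) {
    alias_a <- if ("Alt IDs Interactor A" %in% cols)
      df[["Alt IDs Interactor A"]] else df[[MITAB_ID_COLS[1]]]
    alias_b <- if ("Alt IDs Interactor B" %in% cols)
      df[["Alt IDs Interactor B"]] else df[[MITAB_ID_COLS[2]]]
    a <- mitab_symbol(alias_a)
    b <- mitab_symbol(alias_b)
    it <- df[["Interaction Types"]]
    sys <- sub("^.*\\(([^)]*)\\).*$", "\\1", it)
  } else {
    at_stop("format_error",
            "unknown interaction dialect; columns found: %s",
            paste(cols, collapse = ", "))
  }
  keep <- tolower(sys) %in% tolower(allowed_systems)
  a <- normalize_symbol(a[keep])
  b <- normalize_symbol(b[keep])
  sys <- sys[keep]
  ok <- a != "" & b != "" & a != "-" & b != "-"
  edges <- data.frame(a = a[ok], b = b[ok], system = sys[ok],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(system = function(s)
                          paste(sort(unique(s)), collapse = "|")))
  at_log("read_biogrid: %d edges over %d proteins retained",
         igraph::ecount(g), igraph::vcount(g))
  g
}

## Pull a gene symbol out of a MITAB alias field such as
## "biogrid:12345|entrez gene/locuslink:EGFR" -> EGFR.
mitab_symbol <- function(x) {
  parts <- strsplit(x, "|", fixed = TRUE)
  vapply(parts, function(p) {
    hit <- grep("locuslink:|gene name", p, value = TRUE)
    src <- if (length(hit)) hit[1] else p[length(p)]
    sub("\\(.*$", "", sub("^.*:", "", src))
  }, character(1))
}

#' Read a GMT gene-set collection
#'
#' Lines are tab-separated: set name, description, member symbols. Empty
#' sets are skipped with a warning; duplicate names are an error.
#'
#' @param path GMT file.
#' @return a named list of unique uppercase symbol vectors, with a `source`
#'   attribute carrying the per-set description.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nms <- vapply(fields, `[`, character(1), 1)
  dup <- unique(nms[duplicated(nms)])
  if (length(dup))
    at_stop("ingestion_error", "duplicate gene-set name(s): %s",
            paste(dup, collapse = ", "))
  sets <- lapply(fields, function(f)
    unique(normalize_symbol(f[-(1:2)][nzchar(f[-(1:2)])])))
  src <- vapply(fields, function(f)
    if (length(f) >= 2) f[2] else "", character(1))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    at_warn("read_gmt: skipping %d empty gene set(s): %s", sum(empty),
            paste(nms[empty], collapse = ", "))
    sets <- sets[!empty]; nms <- nms[!empty]; src <- src[!empty]
  }
  names(sets) <- nms
  attr(sets, "source") <- stats::setNames(src, nms)
  sets
}

#' Write a gene-set collection to GMT
#' @param sets named list of symbol vectors (optionally with a `source`
#'   attribute).
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  src <- attr(sets, "source")
  lines <- vapply(names(sets), function(nm) {
    desc <- if (!is.null(src) && nm %in% names(src)) src[[nm]] else "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Export a network for Cytoscape
#'
#' Writes GraphML (round-trippable, attributes preserved) or SIF. When a
#' cluster assignment is supplied its labels are attached as a `cluster`
#' node attribute first.
#'
#' @param network an `igraph`.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @param assignment optional [cluster_assignment] whose labels annotate the
#'   nodes.
#' @export
write_network <- function(network, path, format = c("graphml", "sif"),
                          assignment = NULL) {
  format <- match.arg(format)
  if (!is.null(assignment)) {
    lab <- stats::setNames(assignment$assigned$cluster,
                           assignment$assigned$protein_id)
    igraph::V(network)$cluster <-
      unname(lab[igraph::V(network)$name])
  }
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), path)
  }
  invisible(path)
}

#' Read a GraphML network written by [write_network()]
#' @param path GraphML file.
#' @return an `igraph`.
#' @export
read_network <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
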