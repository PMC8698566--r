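## Shared fixtures and independent oracles. Fixtures are built in code at
## test time; oracles deliberately avoid the package code paths they check.

## --- fixture builders -------------------------------------------------

## Minimal two-condition ratio table: values chosen per protein so each
## (time, replicate) cell is treated = vehicle * 2^logratio.
toy_ratio_table <- function(ids = c("AKT1", "EGFR", "TP53"),
                            logratios = NULL,
                            peptides = rep(5L, length(ids))) {
  times <- c(0, 5, 15, 30, 60)
  lay <- expand.grid(replicate = 1:3, time = times,
                     condition = c("treated", "vehicle"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lay <- lay[, c("condition", "time", "replicate")]
  lay$column <- sprintf("%s_t%d_r%d", lay$condition, lay$time,
                        lay$replicate)
  if (is.null(logratios))
    logratios <- matrix(seq_len(length(ids) * 5), length(ids), 5)
  vals <- matrix(NA_real_, length(ids), nrow(lay))
  for (j in seq_len(nrow(lay))) {
    ti <- match(lay$time[j], times)
    base <- 1000
    vals[, j] <- if (lay$condition[j] == "treated" && lay$time[j] > 0)
      base * 2^logratios[, ti] else base
  }
  ratio_table(ids, peptides, vals, lay)
}

## A cluster_assignment built directly from label vectors (bypassing
## clustering) so downstream stages can be tested in isolation.
make_assignment <- function(ids, clusters, membership = 0.9) {
  structure(list(
    assigned = data.frame(protein_id = normalize_symbol(ids),
                          cluster = clusters,
                          membership = rep_len(membership, length(ids)),
                          stringsAsFactors = FALSE),
    excluded = data.frame(protein_id = character(0),
                          membership = numeric(0)),
    k = length(unique(clusters)), threshold = 0.4),
    class = "cluster_assignment")
}

## BioGRID TAB 3.0 style fixture file.
write_tab3 <- function(path, a, b, system_type,
                       org_a = rep(9606, length(a)),
                       org_b = rep(9606, length(a))) {
  df <- data.frame(a, b, system_type, org_a, org_b,
                   check.names = FALSE)
  names(df) <- c("Official Symbol Interactor A",
                 "Official Symbol Interactor B",
                 "Experimental System Type",
                 "Organism ID Interactor A",
                 "Organism ID Interactor B")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

write_mitab <- function(path, a, b, type) {
  df <- data.frame(
    ida = paste0("biogrid:", seq_along(a)),
    idb = paste0("biogrid:", seq_along(a) + 100),
    alta = paste0("entrez gene/locuslink:", a),
    altb = paste0("entrez gene/locuslink:", b),
    it = sprintf("psi-mi:\"MI:0915\"(%s)", type))
  names(df) <- c("#ID Interactor A", "ID Interactor B",
                 "Alt IDs Interactor A", "Alt IDs Interactor B",
                 "Interaction Types")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

## --- independent oracles ----------------------------------------------

## Exact upper-tail hypergeometric by combinatorial enumeration.
enum_hyper_p <- function(x, n, K, M) {
  js <- max(0, x):min(n, K)
  sum(choose(K, js) * choose(M - K, n - js)) / choose(M, n)
}

## Brute-force O(N^3) cascade scan over an edge list.
brute_cascades <- function(edges, labels, types = NULL,
                           terminal_type = NULL) {
  has_edge <- function(u, v)
    any((edges[, 1] == u & edges[, 2] == v) |
          (edges[, 1] == v & edges[, 2] == u))
  ids <- names(labels)
  out <- NULL
  for (c_ in ids[labels == "C"]) for (d_ in ids[labels == "D"])
    for (e_ in ids[labels == "E"]) {
      if (c_ == e_) next
      if (!is.null(terminal_type) && types[[e_]] != terminal_type) next
      if (has_edge(c_, d_) && has_edge(d_, e_))
        out <- rbind(out, data.frame(Protein_C = c_, Protein_D = d_,
                                     Protein_E = e_,
                                     stringsAsFactors = FALSE))
    }
  if (is.null(out))
    return(data.frame(Protein_C = character(0), Protein_D = character(0),
                      Protein_E = character(0)))
  out <- out[order(out$Protein_E, out$Protein_D, out$Protein_C), ]
  rownames(out) <- NULL
  out
}

## Run the preprocessing chain quietly (helper for clustering tests).
quiet_profiles <- function(tab) {
  suppressMessages(standardize_profiles(compute_ratios(
    filter_quantified(tab))))
}
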