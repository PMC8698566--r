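## End-to-end pipeline driver: executes the eight analysis stages in order
## on supplied (or synthetic) inputs, writes every intermediate table under
## the output directory, and records a run manifest with the seed and a
## configuration fingerprint.

PIPELINE_STAGES <- c("preprocess", "cluster", "enrichment", "network",
                     "cascades", "concept_map", "markers", "report")

#' Run the full analysis pipeline
#'
#' Chains preprocessing, fuzzy clustering (with fuzzifier estimation and,
#' optionally, elbow selection of k), compartment/type enrichment,
#' PPI-network integration, cascade enumeration and layout, the concept
#' map, and marker analysis. Every stage writes its tables into `outdir`;
#' a `manifest.json` lists the completed stages, the seed and a hash of the
#' configuration.
#'
#' @param config an [pipeline_config()] object.
#' @param inputs list with elements `table` (a [ratio_table()]),
#'   `annotations` ([annotation_table()]), `network` (`igraph`),
#'   `concepts` (gene-set list), `marker_datasets` (list of
#'   [expression_dataset()]), `paired_dataset` (optional
#'   [expression_dataset()] with pairs).
#' @param outdir output directory (created if needed).
#' @param k number of clusters; `NULL` selects k by the elbow rule over
#'   `config$k_range`.
#' @return list with every stage result plus the manifest, invisibly.
#' @export
run_pipeline <- function(config, inputs, outdir = "androtime_run",
                         k = 5) {
  stopifnot(inherits(config, "at_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  completed <- character(0)
  out <- list()

  ## 1. preprocess
  filtered <- filter_quantified(inputs$table, config$min_unique_peptides,
                                require_all_replicates = TRUE)
  ratios <- compute_ratios(filtered)
  profiles <- standardize_profiles(ratios)
  qc <- pca_qc(ratios)
  write_profiles(profiles, file.path(outdir, "profiles.tsv"))
  out$profiles <- profiles
  out$qc <- qc
  completed <- c(completed, "preprocess")

  ## 2. cluster
  mhat <- estimate_fuzzifier(nrow(profiles), ncol(profiles))
  at_log("run_pipeline: fuzzifier m = %.4f (%.2f)", mhat$m, mhat$m_rounded)
  if (is.null(k)) {
    sel <- select_k_elbow(profiles, config$k_range, m = mhat$m,
                          seed = config$seed)
    write_tsv(sel$diagnostics, file.path(outdir, "elbow.tsv"))
    k <- sel$k
    partition <- sel$fits[[as.character(k)]]
  } else {
    partition <- fcm(profiles, k, m = mhat$m, seed = config$seed)
  }
  assignment <- filter_membership(partition, config$membership_threshold)
  labels <- label_clusters(partition)
  assignment <- apply_cluster_labels(assignment, labels)
  write_tsv(assignment$assigned, file.path(outdir, "assignment.tsv"))
  write_tsv(data.frame(cluster = unname(labels),
                       partition$centroids, check.names = FALSE),
            file.path(outdir, "centroids.tsv"))
  out$partition <- partition
  out$assignment <- assignment
  out$m <- mhat
  completed <- c(completed, "cluster")

  ## 3. enrichment
  enr_loc <- hypergeom_enrich(assignment, inputs$annotations,
                              "compartment", config$alpha_localization)
  enr_typ <- hypergeom_enrich(assignment, inputs$annotations,
                              "molecular_type", config$alpha_type)
  write_tsv(enr_loc, file.path(outdir, "enrichment_localization.tsv"))
  write_tsv(enr_typ, file.path(outdir, "enrichment_type.tsv"))
  out$enrichment <- list(localization = enr_loc, molecular_type = enr_typ)
  completed <- c(completed, "enrichment")

  ## 4. network
  net <- restrict_network(inputs$network, assignment, inputs$annotations)
  hubs <- hub_degrees(net, focus = "AR")
  pairs <- cluster_pair_stats(net, assignment)
  tmap <- type_interaction_map(net, inputs$annotations, assignment,
                               config$type_edge_fraction,
                               config$alpha_type)
  write_tsv(hubs, file.path(outdir, "hubs.tsv"))
  write_tsv(pairs, file.path(outdir, "cluster_pairs.tsv"))
  write_tsv(as.data.frame(tmap), file.path(outdir, "type_map.tsv"))
  write_network(net, file.path(outdir, "network.graphml"), "graphml")
  out$network <- net
  out$hubs <- hubs
  out$pairs <- pairs
  out$type_map <- tmap
  completed <- c(completed, "network")

  ## 5. cascades
  casc <- enumerate_cascades(net, assignment, inputs$annotations)
  layout <- cascade_layout(casc, inputs$annotations,
                           config$compartment_rows)
  if (nrow(casc$triples))
    write_tsv(casc$triples, file.path(outdir, "cascades.tsv"))
  write_tsv(as.data.frame(layout$placement),
            file.path(outdir, "cascade_layout.tsv"))
  out$cascades <- casc
  out$cascade_layout <- layout
  completed <- c(completed, "cascades")

  ## 6. concept map
  universe <- if (config$universe == "labeled") NULL else
    inputs$table$protein_id
  assoc <- fisher_associate(assignment, inputs$concepts,
                            universe = universe,
                            alpha = config$alpha_concept,
                            or_floor = config$odds_ratio_floor)
  cmap <- build_concept_map(assoc, inputs$concepts)
  write_tsv(assoc, file.path(outdir, "concept_associations.tsv"))
  write_network(cmap, file.path(outdir, "concept_map.graphml"), "graphml")
  out$concept_associations <- assoc
  out$concept_map <- cmap
  completed <- c(completed, "concept_map")

  ## 7. markers
  de_list <- lapply(inputs$marker_datasets, function(ds)
    dataset_de(normalize_dataset(ds), config$alpha_marker))
  markers <- consensus_markers(de_list)
  write_tsv(markers$markers, file.path(outdir, "markers.tsv"))
  if (!is.null(inputs$paired_dataset)) {
    pd <- paired_de(normalize_dataset(inputs$paired_dataset),
                    config$alpha_paired)
    out$paired <- pd
    write_tsv(pd$results, file.path(outdir, "paired_de.tsv"))
  }
  inter <- intersect_with_clusters(markers, assignment)
  write_tsv(inter$table, file.path(outdir, "markers_by_cluster.tsv"))
  out$markers <- markers
  out$marker_clusters <- inter
  completed <- c(completed, "markers")

  ## 8. report (run manifest + summary counts)
  manifest <- list(
    package = "androtime",
    seed = config$seed,
    config_hash = config_hash(config),
    stages = completed <- c(completed, "report"),
    n_proteins_input = length(inputs$table$protein_id),
    n_profiles = nrow(profiles),
    n_labeled = nrow(assignment$assigned),
    k = k,
    m = mhat$m_rounded,
    n_cascades = casc$n_triples,
    n_markers = nrow(markers$markers))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  at_log("run_pipeline: %d stages completed, outputs in %s",
         length(completed), outdir)
  invisible(out)
}
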