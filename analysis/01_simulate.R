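#!/usr/bin/env Rscript
## Stage 1 — generate the synthetic study inputs.
##
## Emulates the study design: ~4500 proteins quantified as DHT/vehicle
## intensities at 0/5/15/30/60 min in triplicate, five planted temporal
## archetypes plus a noise class, archetype-biased annotations, a PPI
## network with excess C/E, D/E and C/D edges plus designated hubs, ten
## gene-set concepts, six two-group marker datasets, and one paired
## tumor/normal cohort. Everything lands under results/data/.

suppressPackageStartupMessages(library(androtime))
seed <- 1L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

sim <- generate_profiles(
  4532, noise_sd = 0.3, seed = seed,
  special = c(AR = "C", EGFR = "A", SRC = "A", SP1 = "D", STAT3 = "E",
              TP53 = "E", FASN = "E", CDC42 = "A", TRIM24 = "B"))
write_ratio_table(sim$table, "results/data/ratio_table.tsv")

ann <- generate_annotations(sim$truth, bias_odds = 8, seed = seed)
write_annotation_table(ann, "results/data/annotations.tsv")

net <- generate_ppi(sim$truth, base_rate = 0.003,
                    pair_excess = c("C/E" = 5, "D/E" = 5, "C/D" = 5),
                    hub_spec = c(EGFR = 97, TP53 = 87), seed = seed)
write_network(net, "results/data/ppi.graphml", "graphml")

concepts <- generate_concepts(sim$truth, n_concepts = 10,
                              overlap_odds = 10, seed = seed)
write_gmt(concepts, "results/data/concepts.gmt")

markers <- generate_marker_datasets(
  n_datasets = 6, n_genes = 2000,
  planted = stats::setNames(rep(c(1, -1), each = 21),
                            c(sprintf("P%05d", 101:120), "FASN",
                              sprintf("P%05d", 201:220), "CDC42")),
  effect = 2, n_per_group = 20, n_support = 3, seed = seed)
for (ds in markers)
  write_expression_dataset(ds, sprintf("results/data/%s.tsv",
                                       ds$dataset_id))
paired <- generate_paired_dataset(
  2000, planted = stats::setNames(c(1, -1), c("FASN", "CDC42")),
  effect = 1.5, n_pairs = 52, seed = seed)
write_expression_dataset(paired, "results/data/TCGA_SYN.tsv")

jsonlite::write_json(
  list(seed = seed,
       n_proteins = nrow(sim$truth$proteins),
       archetype_counts = as.list(table(sim$truth$proteins$archetype)),
       planted_pairs = attr(net, "planted_pairs"),
       designated_concepts = as.list(attr(concepts, "designated")),
       planted_markers = as.list(attr(markers, "planted"))),
  "results/data/truth.json", auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d proteins; archetype mix:\n",
            nrow(sim$truth$proteins)))
print(table(sim$truth$proteins$archetype))
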