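#!/usr/bin/env Rscript
## Stage 7 — consensus marker calling and intersection with the clusters.
##
## Normalizes each two-group expression dataset, tests every gene with a
## two-sample t-test (alpha 0.05), keeps genes significant in the same
## direction in at least two independent datasets, re-tests the markers in
## the paired tumor/normal cohort (paired t-test, alpha 0.01), and joins
## the consensus markers to the temporal clusters.

suppressPackageStartupMessages(library(androtime))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

asg <- local({
  df <- read.delim("results/tables/assignment.tsv",
                   stringsAsFactors = FALSE)
  structure(list(assigned = df,
                 excluded = data.frame(protein_id = character(0),
                                       membership = numeric(0)),
                 k = length(unique(df$cluster)), threshold = 0.4),
            class = "cluster_assignment")
})

files <- list.files("results/data", pattern = "^GEO_SYN[0-9]+\\.tsv$",
                    full.names = TRUE)
de_list <- lapply(files, function(f)
  dataset_de(normalize_dataset(read_expression_dataset(
    f, dataset_id = sub("\\.tsv$", "", basename(f)))), alpha = 0.05))
calls <- consensus_markers(de_list, min_support = 2)
write.table(calls$markers, "results/tables/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("consensus markers: %d (%d up, %d down), %d conflicting\n",
            nrow(calls$markers),
            sum(calls$markers$direction == "up"),
            sum(calls$markers$direction == "down"),
            length(calls$conflicts)))

paired <- read_expression_dataset("results/data/TCGA_SYN.tsv",
                                  dataset_id = "TCGA_SYN")
pde <- paired_de(normalize_dataset(paired), alpha = 0.01)
write.table(pde$results, "results/tables/paired_de.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
confirmed <- intersect(calls$markers$gene,
                       pde$results$gene[pde$results$significant])
cat(sprintf("markers confirmed in the paired cohort (p < 0.01): %d (%s)\n",
            length(confirmed), paste(confirmed, collapse = ", ")))

inter <- intersect_with_clusters(calls, asg)
write.table(inter$table, "results/tables/markers_by_cluster.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("markers per cluster and direction:\n")
print(inter$per_cluster)
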