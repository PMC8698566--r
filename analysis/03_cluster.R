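#!/usr/bin/env Rscript
## Stage 3 — fuzzy c-means clustering of the standardized profiles.
##
## Estimates the fuzzifier from the data dimensions, selects the cluster
## count by the elbow of the objective curve, filters uncertain profiles
## at the 0.4 membership threshold, and labels the five temporal clusters
## A-E (signal initiators ... terminal regulators).

suppressPackageStartupMessages(library(androtime))
seed <- 1L
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

profiles <- local({
  df <- read.delim("results/tables/profiles.tsv", check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$protein_id
  attr(m, "times") <- as.numeric(sub("^t", "", colnames(m)))
  m
})

mhat <- estimate_fuzzifier(nrow(profiles), ncol(profiles))
cat(sprintf("fuzzifier m = %.5f (rounded %.2f) at N=%d, D=%d\n",
            mhat$m, mhat$m_rounded, nrow(profiles), ncol(profiles)))

sel <- select_k_elbow(profiles, 2:10, m = mhat$m, seed = seed)
write.table(sel$diagnostics, "results/tables/elbow.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("elbow selects k = %d\n", sel$k))

partition <- sel$fits[[as.character(sel$k)]]
assignment <- filter_membership(partition, 0.4)
labels <- label_clusters(partition)
assignment <- apply_cluster_labels(assignment, labels)
write.table(assignment$assigned, "results/tables/assignment.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("retained %d of %d profiles at membership > 0.4\n",
            nrow(assignment$assigned), nrow(profiles)))
print(table(assignment$assigned$cluster))

grDevices::png("results/figures/cluster_traces.png", 1600, 420, res = 110)
plot_cluster_traces(profiles, partition, assignment)
grDevices::dev.off()
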