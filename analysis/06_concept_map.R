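#!/usr/bin/env Rscript
## Stage 6 — molecular concept map.
##
## Tests every (cluster, concept) pair with a one-sided Fisher's exact
## test over the labeled proteome and keeps associations with p < 0.001
## and odds ratio > 2; the retained associations form the concept map.

suppressPackageStartupMessages(library(androtime))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
dir.create("results/network", recursive = TRUE, showWarnings = FALSE)

asg <- local({
  df <- read.delim("results/tables/assignment.tsv",
                   stringsAsFactors = FALSE)
  structure(list(assigned = df,
                 excluded = data.frame(protein_id = character(0),
                                       membership = numeric(0)),
                 k = length(unique(df$cluster)), threshold = 0.4),
            class = "cluster_assignment")
})
concepts <- read_gmt("results/data/concepts.gmt")

assoc <- fisher_associate(asg, concepts, alpha = 0.001, or_floor = 2)
write.table(assoc, "results/tables/concept_associations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cmap <- build_concept_map(assoc, concepts)
write_network(cmap, "results/network/concept_map.graphml", "graphml")

kept <- assoc[assoc$retained, ]
cat(sprintf("retained %d of %d associations (p < 0.001, OR > 2):\n",
            nrow(kept), nrow(assoc)))
print(kept[, c("cluster", "concept", "a", "odds_ratio", "p")],
      row.names = FALSE)
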