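#!/usr/bin/env Rscript
## Stage 4 — compartment and molecular-type over-representation.
##
## Hypergeometric enrichment of each cluster for subcellular
## localizations (alpha 0.001) and molecular types (alpha 0.05) over the
## retained labeled proteome, plus the percentage composition profiles.

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
ann <- read_annotation_table("results/data/annotations.tsv")

loc <- hypergeom_enrich(asg, ann, "compartment", alpha = 0.001)
typ <- hypergeom_enrich(asg, ann, "molecular_type", alpha = 0.05)
write.table(loc, "results/tables/enrichment_localization.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(typ, "results/tables/enrichment_type.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

comp <- composition_profile(asg, ann, "compartment")
write.table(comp$long, "results/tables/composition_localization.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("significant localization enrichments (p < 0.001):\n")
print(loc[loc$significant, c("cluster", "category", "x", "n", "p", "fold")],
      row.names = FALSE)
cat("\ntop molecular-type enrichments (p < 0.05):\n")
print(head(typ[typ$significant, c("cluster", "category", "x", "n", "p",
                                  "fold")], 10), row.names = FALSE)
cat("\ncluster compartment composition (%):\n")
print(round(comp$percent, 1))
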