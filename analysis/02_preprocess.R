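#!/usr/bin/env Rscript
## Stage 2 — quantification filters and profile standardization.
##
## Applies the >= 2 unique-peptide and all-replicates filters, forms
## per-replicate DHT/vehicle ratios, median-centers each time profile,
## averages replicates, log2-transforms and z-scores per protein, and
## checks replicate agreement by PCA.

suppressPackageStartupMessages(library(androtime))
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

tab <- read_ratio_table("results/data/ratio_table.tsv")
filtered <- filter_quantified(tab, min_unique_peptides = 2,
                              require_all_replicates = TRUE)
ratios <- compute_ratios(filtered)
profiles <- standardize_profiles(ratios)
write_profiles(profiles, "results/tables/profiles.tsv")

qc <- pca_qc(ratios)
write.table(qc$scores, "results/tables/pca_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("input proteins:        %d\n", length(tab$protein_id)))
cat(sprintf("after filters:         %d\n", length(filtered$protein_id)))
cat(sprintf("standardized profiles: %d x %d\n", nrow(profiles),
            ncol(profiles)))
cat(sprintf("replicate grouping score (mean silhouette): %.3f\n",
            qc$grouping_score))
cat(sprintf("PC1/PC2 explained variance: %.1f%% / %.1f%%\n",
            100 * qc$explained[1], 100 * qc$explained[2]))
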