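# androtime

Temporal clustering and network integration of rapid androgen-response
proteomes.

Androgen stimulation of prostate cancer cells triggers protein-level
changes within minutes — long before the canonical AR-driven
transcriptional program. `androtime` analyzes such rapid-response
experiments: DHT-versus-vehicle protein ratios quantified at 0, 5, 15,
30 and 60 minutes in triplicate. For whom: computational biologists who
have a protein × (condition × time × replicate) quantification table,
protein annotations, a PPI network and expression cohorts, and want the
complete clustering-to-clinical-markers analysis with testable parts.

The core model is fuzzy c-means clustering of standardized time
profiles. Each protein's per-replicate ratio profile is median-centered,
averaged over replicates, log2-transformed and z-scored; FCM then
minimizes

    J = sum_{i,c} u_ic^m || x_i - v_c ||^2,   sum_c u_ic = 1

with the fuzzifier chosen by the data-size-dependent minimum-fuzzifier
estimate

    m = 1 + (1418/N + 22.05) D^-2 + (12.33/N + 0.243) D^(-0.0406 ln N - 0.1134)

(m = 2.01 at N = 4532 profiles, D = 5 time points), the cluster count by
the elbow of J(k), and profiles kept only at maximum membership > 0.4.
The five clusters are labeled A–E along the response — signal
initiators, early stimulators, signal mediators (bimodal), late
stimulators, terminal regulators — and integrated with annotations
(hypergeometric enrichment), a PPI network (hubs, cluster-pair
over-representation, type interaction map, C→D→E cascade enumeration on
a nine-region compartment grid), gene-set concepts (Fisher's exact,
p < 0.001 and OR > 2) and clinical expression datasets (consensus
markers: same-direction significance in ≥ 2 independent datasets; paired
tumor/normal confirmation at p < 0.01).

A synthetic-data generator reproduces the statistical structure of every
input (planted archetypes, annotation bias, interaction-pair excess,
markers), so the full pipeline runs and is tested without any download.

## Worked example

The `analysis/` scripts run the whole workflow on the synthetic study
(seed 1, n = 4532 proteins):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_cluster.R
Rscript analysis/04_enrichment.R
Rscript analysis/05_network_cascades.R
Rscript analysis/06_concept_map.R
Rscript analysis/07_markers.R
```

Selected output of a run, with what it means:

```
filter_quantified: retained 4307 of 4532 proteins (dropped 225)
replicate grouping score (mean silhouette): 0.998
fuzzifier m = 2.01374 (rounded 2.01) at N=4307, D=5
elbow selects k = 5
retained 4135 of 4307 profiles at membership > 0.4
  A   B   C   D   E
841 822 837 813 822
```

The peptide/replicate filters drop 225 of 4532 proteins; replicates of
the same time point sit essentially on top of each other in PCA space
(silhouette ≈ 1); the fuzzifier estimate rounds to 2.01; the objective
curve has its knee at five clusters; and 4135 profiles are confident
enough (membership > 0.4) to be labeled A–E.

```
cluster compartment composition (%):       A: plasma membrane 46.4
significant localization enrichments:      A/plasma membrane, C,D,E/nucleus (p < 0.001)
top type enrichments: E transcription regulator (p = 3e-67, fold 2.3),
                      A transporter (p = 3e-55, fold 2.4)
most over-represented cluster pairs: C/D, C/E, D/E
their share of inter-cluster interactions: 66.0%
top hub proteins: EGFR (degree 86), TP53 (81)
C->D->E cascades ending in transcription regulators: 38881 triples over 3284 terminal edges
consensus markers: 79 (42 up, 37 down), 36 conflicting
markers confirmed in the paired cohort (p < 0.01): 2 (CDC42, FASN)
```

The planted structure is recovered: the signal-initiator cluster A is
membrane/transporter-heavy while the terminal-regulator cluster E is
nuclear and transcription-regulator-heavy; the three planted cluster
pairs dominate inter-cluster signaling; the designated hubs rank first;
and the planted markers (including the synthetic FASN, planted as a
terminal regulator up-regulated in disease) survive both the consensus
rule and the paired cohort.

Programmatic use mirrors the scripts:

```r
library(androtime)
sim  <- generate_profiles(2000, noise_sd = 0.3, seed = 1)
prof <- standardize_profiles(compute_ratios(filter_quantified(sim$table)))
sel  <- select_k_elbow(prof, 2:10, seed = 1)   # -> sel$k == 5
asg  <- apply_cluster_labels(
          filter_membership(sel$fits[[as.character(sel$k)]], 0.4),
          label_clusters(sel$fits[[as.character(sel$k)]]))
```

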