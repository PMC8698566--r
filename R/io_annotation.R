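## Annotation vocabulary: four subcellular localizations plus an
## other/unknown sink, and the thirteen molecular types used for the
## type-interaction map. Vocabularies are closed; anything else is an error.

#' Subcellular compartment vocabulary
#' @export
COMPARTMENTS <- c("extracellular space", "plasma membrane", "cytoplasm",
                  "nucleus", "other/unknown")

#' Molecular-type vocabulary
#' @export
MOLECULAR_TYPES <- c("transcription regulator",
                     "ligand-dependent nuclear receptor",
                     "translation regulator", "phosphatase", "peptidase",
                     "kinase", "enzyme", "transporter", "ion channel",
                     "transmembrane receptor", "G-protein coupled receptor",
                     "growth factor", "cytokine", "other/unknown")

#' Construct an annotation table
#'
#' One compartment and one molecular type per protein, both from closed
#' vocabularies ([COMPARTMENTS], [MOLECULAR_TYPES]).
#'
#' @param protein_id character vector (unique after symbol normalization).
#' @param compartment,molecular_type character vectors aligned with
#'   `protein_id`.
#' @return a data.frame of class `annotation_table`.
#' @export
annotation_table <- function(protein_id, compartment, molecular_type) {
  protein_id <- normalize_symbol(protein_id)
  dup <- unique(protein_id[duplicated(protein_id)])
  if (length(dup))
    at_stop("ingestion_error", "duplicate protein_id in annotations: %s",
            paste(dup, collapse = ", "))
  badc <- setdiff(unique(compartment), COMPARTMENTS)
  if (length(badc))
    at_stop("format_error", "unknown compartment(s): %s",
            paste(badc, collapse = ", "))
  badt <- setdiff(unique(molecular_type), MOLECULAR_TYPES)
  if (length(badt))
    at_stop("format_error", "unknown molecular type(s): %s",
            paste(badt, collapse = ", "))
  if (length(compartment) != length(protein_id) ||
      length(molecular_type) != length(protein_id))
    at_stop("ingestion_error", "annotation columns differ in length")
  structure(data.frame(protein_id = protein_id,
                       compartment = compartment,
                       molecular_type = molecular_type,
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Read an annotation table from TSV
#'
#' Expects columns `protein_id`, `compartment`, `molecular_type`.
#'
#' @param path TSV file.
#' @return an [annotation_table()].
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_id", "compartment", "molecular_type")
  if (!all(need %in% names(df)))
    at_stop("format_error", "missing required columns: %s",
            paste(setdiff(need, names(df)), collapse = ", "))
  annotation_table(df$protein_id, df$compartment, df$molecular_type)
}

#' Write an annotation table to TSV
#' @param ann an `annotation_table`.
#' @param path output file.
#' @export
write_annotation_table <- function(ann, path) {
  write_tsv(as.data.frame(ann), path)
}
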