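#' Pipeline configuration
#'
#' Collects every tunable cutoff of the analysis in one validated object.
#' Defaults follow the published analysis: membership threshold 0.4 for
#' retaining a profile after fuzzy clustering, candidate cluster counts 2-10,
#' molecular-type interaction edges above a 1% interacting-pair fraction
#' (with a 5% alternative used for the summarized type map), hypergeometric
#' alphas of 0.05 (molecular type) and 0.001 (subcellular localization),
#' Fisher concept-map retention at p < 0.001 with odds ratio > 2, per-dataset
#' marker alpha 0.05, and paired tumor/normal alpha 0.01.
#'
#' @param membership_threshold retain a clustered protein only when its
#'   maximum membership exceeds this value (strict inequality), in (0,1).
#' @param k_range integer vector of candidate cluster counts for elbow
#'   selection.
#' @param type_edge_fraction minimum fraction of interacting member pairs for
#'   a molecular-type map edge (strict inequality). Default 0.01; 0.05
#'   reproduces the summarized-map convention.
#' @param alpha_localization,alpha_type hypergeometric enrichment alphas for
#'   subcellular compartments and molecular types.
#' @param alpha_concept Fisher alpha for concept-map retention.
#' @param odds_ratio_floor minimum odds ratio for concept-map retention
#'   (strict inequality).
#' @param alpha_marker per-dataset two-sample t-test alpha for marker calling.
#' @param alpha_paired paired tumor/normal differential-expression alpha.
#' @param min_unique_peptides minimum unique-peptide count for a quantified
#'   protein.
#' @param seed integer seed used for every stochastic stage.
#' @param universe enrichment universe policy: `"labeled"` (proteins retained
#'   after the membership filter, the published convention) or
#'   `"quantified"` (all proteins entering clustering).
#' @param compartment_rows mapping of the non-grid compartments onto the
#'   three cascade-layout rows.
#' @return an object of class `at_config` (a validated list).
#' @export
pipeline_config <- function(membership_threshold = 0.4,
                            k_range = 2:10,
                            type_edge_fraction = 0.01,
                            alpha_localization = 0.001,
                            alpha_type = 0.05,
                            alpha_concept = 0.001,
                            odds_ratio_floor = 2,
                            alpha_marker = 0.05,
                            alpha_paired = 0.01,
                            min_unique_peptides = 2,
                            seed = 1L,
                            universe = c("labeled", "quantified"),
                            compartment_rows = c(
                              "extracellular space" = "plasma membrane",
                              "other/unknown" = "cytoplasm")) {
  universe <- match.arg(universe)
  stopifnot(is.numeric(k_range), length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  for (nm in c("membership_threshold", "type_edge_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v >= 1)
      at_stop("parameter_error", "%s must lie in (0,1), got %s", nm,
              format(v))
  }
  for (nm in c("alpha_localization", "alpha_type", "alpha_concept",
               "alpha_marker", "alpha_paired")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1)
      at_stop("parameter_error", "%s must lie in (0,1)", nm)
  }
  if (any(k_range < 2))
    at_stop("parameter_error", "k_range must start at 2 or above")
  cfg <- list(
    membership_threshold = membership_threshold,
    k_range = k_range,
    type_edge_fraction = type_edge_fraction,
    alpha_localization = alpha_localization,
    alpha_type = alpha_type,
    alpha_concept = alpha_concept,
    odds_ratio_floor = odds_ratio_floor,
    alpha_marker = alpha_marker,
    alpha_paired = alpha_paired,
    min_unique_peptides = min_unique_peptides,
    seed = as.integer(seed),
    universe = universe,
    compartment_rows = compartment_rows)
  class(cfg) <- "at_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos fail loudly. Missing keys take the
#' [pipeline_config()] defaults.
#'
#' @param path YAML file.
#' @return an `at_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    at_stop("format_error", "unknown config keys: %s",
            paste(bad, collapse = ", "))
  if (!is.null(raw$compartment_rows))
    raw$compartment_rows <- unlist(raw$compartment_rows)
  do.call(pipeline_config, raw)
}

#' @export
print.at_config <- function(x, ...) {
  cat("androtime pipeline configuration\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-22s %s\n", nm,
                paste(format(v, trim = TRUE), collapse = " ")))
  }
  invisible(x)
}

config_hash <- function(cfg) {
  fnv1a32(paste(names(cfg), vapply(cfg, function(v)
    paste(format(v), collapse = ","), character(1)), sep = "=",
    collapse = ";"))
}
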