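## Preprocessing: quantification filters, treated/vehicle ratio
## computation, and the standardization chain that produces the
## time-profile matrix consumed by fuzzy clustering.

#' Filter proteins by quantification quality
#'
#' Retains proteins meeting the unique-peptide threshold and, optionally,
#' quantified (no missing value) in every replicate. Retained/dropped
#' counts are logged.
#'
#' @param table a [ratio_table()].
#' @param min_unique_peptides minimum unique peptides (default 2; the
#'   published "more than two unique peptides" is read as >= 2, matching the
#'   abstract-level protein counts).
#' @param require_all_replicates drop proteins missing any value in any
#'   replicate.
#' @return the filtered `ratio_table`.
#' @export
filter_quantified <- function(table, min_unique_peptides = 2,
                              require_all_replicates = TRUE) {
  keep <- table$unique_peptides >= min_unique_peptides
  if (require_all_replicates) {
    complete <- !apply(is.na(table$values), 1, any)
    keep <- keep & complete
  }
  at_log("filter_quantified: retained %d of %d proteins (dropped %d)",
         sum(keep), length(keep), sum(!keep))
  if (!any(keep))
    at_stop("pipeline_error",
            "no protein passes the quantification filters; review min_unique_peptides/require_all_replicates")
  rt_subset(table, keep)
}

#' Compute per-replicate treated/vehicle ratios
#'
#' For every (time, replicate) cell the ratio is treated divided by vehicle.
#' When both conditions at time 0 are the same untreated control the time-0
#' ratio is 1 by construction. Proteins with a zero or missing vehicle
#' value are dropped with a log entry.
#'
#' @param table a [ratio_table()] containing both conditions for each
#'   (time, replicate).
#' @return a `ratio_matrix`: list with `ratios` (proteins x time*replicate),
#'   `layout` (time, replicate per column) and `protein_id`.
#' @export
compute_ratios <- function(table) {
  lay <- table$layout
  cells <- unique(lay[lay$condition == "treated", c("time", "replicate")])
  cells <- cells[order(cells$time, cells$replicate), ]
  for (j in seq_len(nrow(cells))) {
    hasv <- any(lay$condition == "vehicle" & lay$time == cells$time[j] &
                  lay$replicate == cells$replicate[j])
    if (!hasv)
      at_stop("pipeline_error",
              "no vehicle sample matching treated (t=%g, rep=%d)",
              cells$time[j], cells$replicate[j])
  }
  tmat <- vmat <- matrix(NA_real_, nrow(table$values), nrow(cells))
  for (j in seq_len(nrow(cells))) {
    tcol <- which(lay$condition == "treated" & lay$time == cells$time[j] &
                    lay$replicate == cells$replicate[j])[1]
    vcol <- which(lay$condition == "vehicle" & lay$time == cells$time[j] &
                    lay$replicate == cells$replicate[j])[1]
    tmat[, j] <- table$values[, tcol]
    vmat[, j] <- table$values[, vcol]
  }
  bad <- apply(vmat, 1, function(v) any(is.na(v) | v == 0))
  if (any(bad))
    at_log("compute_ratios: dropping %d protein(s) with zero or missing vehicle values",
           sum(bad))
  ratios <- (tmat / vmat)[!bad, , drop = FALSE]
  rownames(ratios) <- table$protein_id[!bad]
  colnames(ratios) <- sprintf("t%g_r%d", cells$time, cells$replicate)
  structure(list(ratios = ratios,
                 layout = cells,
                 protein_id = table$protein_id[!bad]),
            class = "ratio_matrix")
}

#' Standardize ratio profiles into the clustering input
#'
#' Applies, in order: median centering, arithmetic averaging over
#' replicates per (protein, time), log2 transformation, and a per-protein
#' z-score across the time points (sample standard deviation). The default
#' centering divides each per-replicate time profile by its own median
#' ratio; `center = "sample"` instead divides each sample column by its
#' median across proteins, which makes the result invariant to positive
#' per-sample scale factors. Constant (zero-variance) profiles and profiles
#' with missing values are removed and logged.
#'
#' @param ratios a `ratio_matrix` from [compute_ratios()].
#' @param center `"profile"` (per time profile, the default) or
#'   `"sample"` (per sample column).
#' @param average `"arithmetic"` (the default: averaging happens on the
#'   centered ratio scale, before the log) or `"geometric"`.
#' @param sd `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a `time_profile_matrix`: numeric matrix, one standardized row
#'   per protein, one column per time point, with a `times` attribute.
#' @export
standardize_profiles <- function(ratios,
                                 center = c("profile", "sample"),
                                 average = c("arithmetic", "geometric"),
                                 sd = c("sample", "population")) {
  center <- match.arg(center)
  average <- match.arg(average)
  sdmode <- match.arg(sd)
  x <- ratios$ratios
  lay <- ratios$layout
  times <- sort(unique(lay$time))
  if (length(times) < 2)
    at_stop("parameter_error", "need at least 2 time points")
  hasna <- apply(x, 1, anyNA)
  if (any(hasna)) {
    at_log("standardize_profiles: dropping %d profile(s) with missing ratios",
           sum(hasna))
    x <- x[!hasna, , drop = FALSE]
  }
  ## (1) median centering
  if (center == "sample") {
    med <- apply(x, 2, stats::median)
    x <- sweep(x, 2, med, "/")
  } else {
    for (r in unique(lay$replicate)) {
      cols <- which(lay$replicate == r)
      med <- apply(x[, cols, drop = FALSE], 1, stats::median)
      x[, cols] <- x[, cols, drop = FALSE] / med
    }
  }
  if (any(x <= 0))
    at_stop("pipeline_error", "non-positive ratio after centering")
  ## (2) average replicates per (protein, time); (3) log2
  avg <- sapply(times, function(tt) {
    cols <- which(lay$time == tt)
    if (average == "arithmetic")
      rowMeans(x[, cols, drop = FALSE])
    else
      exp(rowMeans(log(x[, cols, drop = FALSE])))
  })
  avg <- matrix(avg, nrow = nrow(x))
  prof <- log2(avg)
  ## (4) per-protein z-score across time points
  mu <- rowMeans(prof)
  dev <- prof - mu
  denom <- if (sdmode == "sample") ncol(prof) - 1 else ncol(prof)
  sds <- sqrt(rowSums(dev^2) / denom)
  zero <- sds < 1e-12
  if (any(zero))
    at_log("standardize_profiles: dropping %d constant profile(s)",
           sum(zero))
  z <- dev[!zero, , drop = FALSE] / sds[!zero]
  rownames(z) <- rownames(x)[!zero]
  colnames(z) <- paste0("t", times)
  structure(z, times = times, class = c("time_profile_matrix", "matrix"))
}

#' Principal-component QC of the per-sample ratio profiles
#'
#' Runs a centered PCA over the per-sample (time x replicate) log2 ratio
#' vectors and scores how tightly replicates of the same time point group on
#' the first two components (mean silhouette width with time points as
#' groups).
#'
#' @param ratios a `ratio_matrix`.
#' @return a `qc_report`: list with `scores` (per-sample PC1/PC2
#'   coordinates, time, replicate), `explained` (variance fractions) and
#'   `grouping_score`; or `NULL` with a warning when fewer than 3 samples
#'   exist.
#' @export
pca_qc <- function(ratios) {
  x <- ratios$ratios
  keep <- !apply(x, 1, anyNA)
  x <- log2(x[keep, , drop = FALSE])
  if (ncol(x) < 3) {
    at_warn("pca_qc: fewer than 3 samples, QC skipped")
    return(NULL)
  }
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  co <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  grp <- factor(ratios$layout$time)
  score <- NA_real_
  if (nlevels(grp) >= 2 && nlevels(grp) < nrow(co)) {
    sil <- cluster::silhouette(as.integer(grp), stats::dist(co))
    score <- mean(sil[, "sil_width"])
  }
  structure(list(
    scores = data.frame(sample = colnames(x),
                        time = ratios$layout$time,
                        replicate = ratios$layout$replicate,
                        PC1 = co[, 1],
                        PC2 = if (ncol(co) > 1) co[, 2] else 0),
    explained = ev,
    grouping_score = score), class = "qc_report")
}

#' Write a time-profile matrix to TSV
#' @param profiles a `time_profile_matrix`.
#' @param path output file.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(protein_id = rownames(profiles),
                   as.data.frame(unclass(profiles), check.names = FALSE))
  write_tsv(df, path)
}
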