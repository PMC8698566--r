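## Synthetic-data generators emulating the study design: two conditions
## (treated = androgen, vehicle) at 0/5/15/30/60 min in three replicates,
## ~4500 proteins drawn from five temporal archetypes plus unstructured
## noise, annotation bias per archetype, cluster-pair interaction excess,
## planted concepts and planted consensus markers. Every generator is a pure
## function of (parameters, seed).

TIME_POINTS <- c(0, 5, 15, 30, 60)
ARCHETYPES <- c("A", "B", "C", "D", "E")

## Fixed piecewise-linear archetype templates on the log2 treated/vehicle
## scale. Time 0 is the shared untreated control, so every raw curve is
## anchored at 0 there. Shapes: A peaks at 5-15 min then declines below
## baseline; B stays elevated through 5-30 min; C is bimodal (up early and
## late, down in between); D rises from 30 min; E rises monotonically to a
## 60-min maximum.
ARCHETYPE_RAW <- rbind(
  A = c(0,  0.90,  0.40, -0.50, -0.65),
  B = c(0,  0.35,  1.20,  1.00,  0.00),
  C = c(0,  1.50, -1.90, -0.20,  0.55),
  D = c(0, -0.35, -0.50,  1.50,  0.35),
  E = c(0,  0.25,  0.35,  0.35,  2.00))
colnames(ARCHETYPE_RAW) <- paste0("t", TIME_POINTS)

#' Archetype template profiles
#'
#' @param standardized return the row-standardized (mean 0, unit sample
#'   variance) templates, the space in which clustering operates; otherwise
#'   the raw log2-ratio templates anchored at 0 for the untreated time 0.
#' @return a 5 x 5 matrix, rows `A`-`E`, columns the five time points.
#' @export
archetype_profiles <- function(standardized = TRUE) {
  if (!standardized) return(ARCHETYPE_RAW)
  t(apply(ARCHETYPE_RAW, 1, function(r) (r - mean(r)) / stats::sd(r)))
}

## Deterministic largest-remainder apportionment of n among proportions.
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(prop))
}

#' Generate a synthetic two-condition ratio table with planted archetypes
#'
#' Builds per-replicate treated and vehicle intensities such that the
#' preprocessing chain (per-profile median centering, replicate averaging,
#' log2, per-protein z-score) recovers, for each protein, the standardized
#' version of its archetype curve plus the planted profile noise. Treated
#' and vehicle channels of a replicate share the per-run loading factor (as
#' in a multiplexed labeling design), and both conditions at time 0 are the
#' same untreated control, so the time-0 ratio is exactly 1.
#'
#' @param n_proteins number of proteins (>= 50).
#' @param archetype_mix named proportions over `A`-`E` and `noise`, summing
#'   to 1. Default: five equal archetypes at 18% plus 10% unstructured
#'   profiles.
#' @param noise_sd standard deviation of the profile-level Gaussian noise
#'   added to the archetype curve (log2-ratio scale) at the four treated
#'   time points.
#' @param seed integer seed; the generator is deterministic given it.
#' @param replicate_sd standard deviation of the per-replicate technical
#'   scatter on the log2-ratio scale (0 gives identical replicates).
#' @param frac_low_peptides fraction of proteins given a single unique
#'   peptide (removed by the quantification filter).
#' @param frac_missing fraction of proteins with one missing quantification
#'   (removed when all replicates are required).
#' @param special optional named character vector `symbol -> archetype`
#'   renaming one member of the archetype to a designated symbol (e.g.
#'   `c(AR = "C", SP1 = "D", STAT3 = "E")`).
#' @return a list with elements `table` (a [ratio_table()]) and `truth` (a
#'   `synthetic_truth` object: per-protein archetype, amplitude, the planted
#'   standardized profiles, and the generation parameters).
#' @export
generate_profiles <- function(n_proteins,
                              archetype_mix = c(A = 0.18, B = 0.18, C = 0.18,
                                                D = 0.18, E = 0.18,
                                                noise = 0.10),
                              noise_sd = 0.3, seed = 1L,
                              replicate_sd = 0.05,
                              frac_low_peptides = 0.03,
                              frac_missing = 0.02,
                              special = NULL) {
  if (n_proteins < 50)
    at_stop("parameter_error", "n_proteins must be >= 50")
  if (noise_sd < 0 || replicate_sd < 0)
    at_stop("parameter_error", "noise_sd and replicate_sd must be >= 0")
  if (abs(sum(archetype_mix) - 1) > 1e-8)
    at_stop("parameter_error", "archetype_mix must sum to 1 (got %.6f)",
            sum(archetype_mix))
  if (!all(names(archetype_mix) %in% c(ARCHETYPES, "noise")))
    at_stop("parameter_error", "archetype_mix names must be A-E or 'noise'")
  nt <- length(TIME_POINTS)
  nrep <- 3L
  with_seed(seed, {
    counts <- apportion(n_proteins, archetype_mix)
    labels <- sample(rep(names(counts), counts))
    ids <- sprintf("P%05d", seq_len(n_proteins))
    if (!is.null(special)) {
      for (sym in names(special)) {
        arch <- special[[sym]]
        idx <- which(labels == arch & !ids %in% names(special))
        if (!length(idx))
          at_stop("parameter_error",
                  "special symbol %s requests archetype %s with no members",
                  sym, arch)
        ids[idx[1]] <- normalize_symbol(sym)
      }
    }
    ## planted log2-ratio curves (time 0 pinned at 0)
    q <- matrix(0, n_proteins, nt)
    is_arch <- labels %in% ARCHETYPES
    q[is_arch, ] <- ARCHETYPE_RAW[labels[is_arch], , drop = FALSE]
    eps <- cbind(0, matrix(stats::rnorm(n_proteins * (nt - 1)),
                           n_proteins, nt - 1))
    q[is_arch, ] <- q[is_arch, ] + noise_sd * eps[is_arch, , drop = FALSE]
    q[!is_arch, ] <- eps[!is_arch, , drop = FALSE]  # white noise, sd 1
    amplitude <- exp(stats::rnorm(n_proteins, 0, 0.2))
    baseline <- 2^stats::rnorm(n_proteins, 20, 1.5)  # protein abundance
    loading <- matrix(2^stats::rnorm(nt * nrep, 0, 0.1), nt, nrep)
    ## per-cell technical scatter on the log2 ratio, split over conditions;
    ## time 0 shares the control aliquot so its scatter cancels exactly
    tau_t <- array(stats::rnorm(n_proteins * nt * nrep, 0,
                                replicate_sd / sqrt(2)),
                   c(n_proteins, nt, nrep))
    tau_v <- array(stats::rnorm(n_proteins * nt * nrep, 0,
                                replicate_sd / sqrt(2)),
                   c(n_proteins, nt, nrep))
    tau_t[, 1, ] <- tau_v[, 1, ]
    vals <- matrix(NA_real_, n_proteins, 2 * nt * nrep)
    layout <- expand.grid(replicate = seq_len(nrep), time = TIME_POINTS,
                          condition = RT_CONDITIONS,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
    layout <- layout[, c("condition", "time", "replicate")]
    layout$column <- sprintf("%s_t%d_r%d", layout$condition, layout$time,
                             layout$replicate)
    for (j in seq_len(nrow(layout))) {
      ti <- match(layout$time[j], TIME_POINTS)
      r <- layout$replicate[j]
      logv <- log2(baseline) + log2(loading[ti, r]) + tau_v[, ti, r]
      if (layout$condition[j] == "treated")
        logv <- logv + amplitude * q[, ti] + (tau_t[, ti, r] - tau_v[, ti, r])
      vals[, j] <- 2^logv
    }
    ## designated special proteins are the study's focus; they stay fully
    ## quantified, so the low-peptide/missingness injections skip them
    injectable <- which(!ids %in% normalize_symbol(names(special)))
    peptides <- 2L + stats::rpois(n_proteins, 4)
    n_low <- round(frac_low_peptides * n_proteins)
    if (n_low > 0) peptides[sample(injectable, n_low)] <- 1L
    n_miss <- round(frac_missing * n_proteins)
    if (n_miss > 0) {
      miss_rows <- sample(injectable, n_miss)
      treated_cols <- which(layout$condition == "treated" & layout$time > 0)
      vals[cbind(miss_rows,
                 sample(treated_cols, n_miss, replace = TRUE))] <- NA_real_
    }
    planted <- t(apply(q, 1, function(r) (r - mean(r)) / stats::sd(r)))
    colnames(planted) <- paste0("t", TIME_POINTS)
    rownames(planted) <- ids
    tab <- ratio_table(ids, peptides, vals, layout)
    truth <- structure(list(
      proteins = data.frame(protein_id = ids, archetype = labels,
                            amplitude = amplitude,
                            stringsAsFactors = FALSE),
      planted_profiles = planted,
      archetype_mix = archetype_mix,
      templates = archetype_profiles(TRUE),
      noise_sd = noise_sd, replicate_sd = replicate_sd,
      seed = as.integer(seed)), class = "synthetic_truth")
    list(table = tab, truth = truth)
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d proteins (seed %d, noise sd %.2f)\n",
              nrow(x$proteins), x$seed, x$noise_sd))
  print(table(x$proteins$archetype))
  invisible(x)
}

## Baseline category frequencies. Compartments follow the published
## localization breakdown of the selected proteome (extracellular 3.6%,
## plasma membrane 10.2%, cytoplasm 56.6%, nucleus 29.5%); molecular types
## are a plausible whole-proteome breakdown over the 13 classes plus an
## other/unknown sink.
COMPARTMENT_BASE <- c("extracellular space" = 0.036,
                      "plasma membrane" = 0.102,
                      "cytoplasm" = 0.566,
                      "nucleus" = 0.295,
                      "other/unknown" = 0.001)
TYPE_BASE <- c("transcription regulator" = 0.090,
               "ligand-dependent nuclear receptor" = 0.005,
               "translation regulator" = 0.020,
               "phosphatase" = 0.025,
               "peptidase" = 0.030,
               "kinase" = 0.055,
               "enzyme" = 0.220,
               "transporter" = 0.060,
               "ion channel" = 0.012,
               "transmembrane receptor" = 0.030,
               "G-protein coupled receptor" = 0.008,
               "growth factor" = 0.008,
               "cytokine" = 0.007,
               "other/unknown" = 0.430)

## archetype -> planted (compartment, molecular types) bias pairs
ANNOTATION_BIAS <- list(
  A = list(compartment = "plasma membrane",
           types = c("transporter", "transmembrane receptor")),
  C = list(compartment = "nucleus", types = character(0)),
  D = list(compartment = "nucleus", types = character(0)),
  E = list(compartment = "nucleus",
           types = c("transcription regulator", "translation regulator")))

#' Generate synthetic annotations with archetype-linked bias
#'
#' Compartments and molecular types are drawn from baseline multinomials;
#' for the planted (archetype, category) pairs - plasma-membrane
#' transporters and transmembrane receptors in A, nuclear transcription and
#' translation regulators in E, nuclear localization in C and D - the
#' baseline odds are multiplied by `bias_odds`. `bias_odds = 1` plants no
#' signal.
#'
#' @param truth a `synthetic_truth` from [generate_profiles()].
#' @param bias_odds odds multiplier, >= 1.
#' @param seed integer seed.
#' @return an [annotation_table()] with a `planted` attribute listing the
#'   biased (archetype, kind, category) triples.
#' @export
generate_annotations <- function(truth, bias_odds = 8, seed = 1L) {
  if (bias_odds < 1)
    at_stop("parameter_error", "bias_odds must be >= 1")
  labels <- truth$proteins$archetype
  n <- length(labels)
  with_seed(seed, {
    comp <- character(n)
    type <- character(n)
    for (a in unique(labels)) {
      cw <- COMPARTMENT_BASE
      tw <- TYPE_BASE
      b <- ANNOTATION_BIAS[[a]]
      if (!is.null(b)) {
        cw[b$compartment] <- cw[b$compartment] * bias_odds
        if (length(b$types)) tw[b$types] <- tw[b$types] * bias_odds
      }
      idx <- which(labels == a)
      comp[idx] <- sample(names(cw), length(idx), replace = TRUE, prob = cw)
      type[idx] <- sample(names(tw), length(idx), replace = TRUE, prob = tw)
    }
    ann <- annotation_table(truth$proteins$protein_id, comp, type)
    planted <- do.call(rbind, lapply(names(ANNOTATION_BIAS), function(a) {
      b <- ANNOTATION_BIAS[[a]]
      rbind(data.frame(archetype = a, kind = "compartment",
                       category = b$compartment),
            if (length(b$types))
              data.frame(archetype = a, kind = "molecular_type",
                         category = b$types))
    }))
    attr(ann, "planted") <- if (bias_odds > 1) planted else planted[0, ]
    ann
  })
}

parse_pair_names <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  vapply(parts, function(p) paste(sort(p), collapse = "/"), character(1))
}

#' Generate a synthetic PPI network with cluster-pair edge excess
#'
#' Edges are sampled independently (Erdos-Renyi style) at `base_rate`,
#' multiplied by `pair_excess` for protein pairs whose archetypes form one
#' of the named cluster pairs. Designated hub proteins are wired to exactly
#' the requested number of partners.
#'
#' @param truth a `synthetic_truth`.
#' @param base_rate baseline edge probability (default 0.003, matching the
#'   density of a physical-interaction network of ~17k edges over ~3.5k
#'   proteins).
#' @param pair_excess named multipliers, names like `"C/E"` (unordered);
#'   default plants a five-fold excess on C/E, D/E and C/D.
#' @param hub_spec named integer vector `symbol -> degree`; each named
#'   protein is rewired to exactly that many partners.
#' @param seed integer seed.
#' @return an undirected simple `igraph` over all proteins, with a
#'   `planted_pairs` attribute.
#' @export
generate_ppi <- function(truth, base_rate = 0.003,
                         pair_excess = c("C/E" = 5, "D/E" = 5, "C/D" = 5),
                         hub_spec = NULL, seed = 1L) {
  ids <- truth$proteins$protein_id
  labels <- truth$proteins$archetype
  if (base_rate <= 0 || base_rate >= 1)
    at_stop("parameter_error", "base_rate must lie in (0,1)")
  names(pair_excess) <- parse_pair_names(names(pair_excess))
  groups <- sort(unique(labels))
  with_seed(seed, {
    edge_a <- integer(0); edge_b <- integer(0)
    idx_by_g <- split(seq_along(ids), labels)
    for (gi in seq_along(groups)) for (gj in gi:length(groups)) {
      g1 <- groups[gi]; g2 <- groups[gj]
      key <- paste(sort(c(g1, g2)), collapse = "/")
      p <- min(1, base_rate * if (key %in% names(pair_excess))
        pair_excess[[key]] else 1)
      i1 <- idx_by_g[[g1]]; i2 <- idx_by_g[[g2]]
      if (g1 == g2) {
        n1 <- length(i1)
        npair <- n1 * (n1 - 1) / 2
        if (npair == 0) next
        m <- stats::rbinom(1, npair, p)
        if (m == 0) next
        sel <- sample.int(npair, m)
        ## decode linear index over the upper triangle
        cum <- cumsum((n1 - 1):1)
        a <- findInterval(sel - 1, c(0, cum), rightmost.closed = FALSE)
        b <- sel - c(0, cum)[a] + a
        edge_a <- c(edge_a, i1[a]); edge_b <- c(edge_b, i1[b])
      } else {
        npair <- length(i1) * length(i2)
        m <- stats::rbinom(1, npair, p)
        if (m == 0) next
        sel <- sample.int(npair, m) - 1L
        edge_a <- c(edge_a, i1[sel %% length(i1) + 1L])
        edge_b <- c(edge_b, i2[sel %/% length(i1) + 1L])
      }
    }
    g <- igraph::graph_from_edgelist(
      cbind(ids[edge_a], ids[edge_b]), directed = FALSE)
    g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                              name = setdiff(ids, igraph::V(g)$name))
    g <- igraph::simplify(g)
    if (!is.null(hub_spec)) {
      for (sym in names(hub_spec)) {
        sym_n <- normalize_symbol(sym)
        if (!sym_n %in% ids)
          at_stop("parameter_error", "hub %s is not a generated protein",
                  sym)
        old <- igraph::incident(g, sym_n)
        g <- igraph::delete_edges(g, old)
        partners <- sample(setdiff(ids, sym_n), hub_spec[[sym]])
        g <- igraph::add_edges(g, rbind(sym_n, partners))
      }
      g <- igraph::simplify(g)
    }
    attr(g, "planted_pairs") <- names(pair_excess)[pair_excess > 1]
    g
  })
}

#' Generate synthetic gene-set concepts linked to archetypes
#'
#' Each concept is assigned a designated archetype (cycling through A-E);
#' membership is sampled at `base_rate`, with odds multiplied by
#' `overlap_odds` for proteins of the designated archetype.
#' `overlap_odds = 1` plants no association.
#'
#' @param truth a `synthetic_truth`.
#' @param n_concepts number of concepts.
#' @param overlap_odds odds multiplier >= 1 for designated-archetype
#'   members.
#' @param base_rate baseline membership probability.
#' @param seed integer seed.
#' @return a named list of gene sets (as from [read_gmt()]) with a
#'   `designated` attribute mapping concept -> archetype.
#' @export
generate_concepts <- function(truth, n_concepts = 10, overlap_odds = 10,
                              base_rate = 0.05, seed = 1L) {
  if (overlap_odds < 1)
    at_stop("parameter_error", "overlap_odds must be >= 1")
  ids <- truth$proteins$protein_id
  labels <- truth$proteins$archetype
  with_seed(seed, {
    designated <- rep(ARCHETYPES, length.out = n_concepts)
    sets <- vector("list", n_concepts)
    names(sets) <- sprintf("CONCEPT_%02d", seq_len(n_concepts))
    for (k in seq_len(n_concepts)) {
      odds <- base_rate / (1 - base_rate) *
        ifelse(labels == designated[k], overlap_odds, 1)
      p <- odds / (1 + odds)
      sets[[k]] <- ids[stats::runif(length(ids)) < p]
    }
    attr(sets, "source") <- stats::setNames(
      rep("synthetic", n_concepts), names(sets))
    attr(sets, "designated") <- stats::setNames(designated, names(sets))
    sets
  })
}

#' Generate independent expression datasets with planted markers
#'
#' Emulates a panel of two-group (naive vs hormone-refractory/metastatic)
#' expression studies: log-normal expression with gene-specific baselines,
#' where each planted gene is shifted by `effect` (on the standardized
#' log2 scale) with its planted sign in `n_support` of the datasets.
#'
#' @param n_datasets number of independent datasets.
#' @param n_genes genes per dataset (shared gene space `G00001...`).
#' @param planted named numeric vector, gene -> direction (+1 up in
#'   refractory, -1 down); names outside the gene space are added to it.
#' @param effect standardized mean difference for planted genes (0 = null).
#' @param n_per_group samples per group in each dataset.
#' @param n_support number of datasets in which each planted gene carries
#'   its shift (>= 2 for a recoverable consensus marker).
#' @param seed integer seed.
#' @return list of `expression_dataset` objects with a `planted` attribute.
#' @export
generate_marker_datasets <- function(n_datasets = 6, n_genes = 1000,
                                     planted = NULL, effect = 2,
                                     n_per_group = 20, n_support = 3,
                                     seed = 1L) {
  if (n_support > n_datasets)
    at_stop("parameter_error", "n_support cannot exceed n_datasets")
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (!is.null(planted)) {
    names(planted) <- normalize_symbol(names(planted))
    genes <- union(genes, names(planted))
  }
  with_seed(seed, {
    support <- lapply(planted, function(d)
      sort(sample.int(n_datasets, n_support)))
    mu <- stats::setNames(stats::rnorm(length(genes), 8, 1), genes)
    out <- vector("list", n_datasets)
    for (d in seq_len(n_datasets)) {
      group <- factor(rep(c("naive", "refractory"), each = n_per_group),
                      levels = c("naive", "refractory"))
      logx <- matrix(stats::rnorm(length(genes) * length(group), 0, 1),
                     length(genes), length(group),
                     dimnames = list(genes, sprintf("DS%d_S%02d", d,
                                                    seq_along(group))))
      logx <- logx + mu
      for (gn in names(planted))
        if (d %in% support[[gn]])
          logx[gn, group == "refractory"] <-
            logx[gn, group == "refractory"] + effect * planted[[gn]]
      out[[d]] <- expression_dataset(2^logx, group,
                                     dataset_id = sprintf("GEO_SYN%d", d))
    }
    attr(out, "planted") <- planted
    attr(out, "support") <- support
    out
  })
}

#' Generate a paired tumor/normal expression dataset with planted markers
#'
#' Emulates a paired-design cohort: a shared per-subject effect plus
#' residual noise, with planted genes shifted by `effect` in the tumor
#' sample of every pair.
#'
#' @param n_genes genes (`G00001...` shared gene space).
#' @param planted named numeric vector gene -> direction (+1/-1).
#' @param effect standardized shift in tumor samples.
#' @param n_pairs number of tumor/normal pairs.
#' @param seed integer seed.
#' @return an `expression_dataset` with `pair_id` set and a `planted`
#'   attribute.
#' @export
generate_paired_dataset <- function(n_genes = 1000, planted = NULL,
                                    effect = 1.5, n_pairs = 52, seed = 1L) {
  genes <- sprintf("G%05d", seq_len(n_genes))
  if (!is.null(planted)) {
    names(planted) <- normalize_symbol(names(planted))
    genes <- union(genes, names(planted))
  }
  with_seed(seed, {
    mu <- stats::rnorm(length(genes), 8, 1)
    subj <- matrix(rep(stats::rnorm(n_pairs, 0, 0.5), each = length(genes)),
                   length(genes), n_pairs)
    mk <- function(tag) matrix(
      stats::rnorm(length(genes) * n_pairs, 0, 1), length(genes), n_pairs,
      dimnames = list(genes, sprintf("%s_%02d", tag, seq_len(n_pairs))))
    normal <- mu + subj + mk("N")
    tumor <- mu + subj + mk("T")
    for (gn in names(planted))
      tumor[gn, ] <- tumor[gn, ] + effect * planted[[gn]]
    exprs <- 2^cbind(tumor, normal)
    group <- factor(rep(c("tumor", "normal"), each = n_pairs),
                    levels = c("normal", "tumor"))
    ds <- expression_dataset(exprs, group,
                             pair_id = rep(seq_len(n_pairs), 2),
                             dataset_id = "TCGA_SYN")
    attr(ds, "planted") <- planted
    ds
  })
}
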