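mk_ds <- function(n_genes = 30, n = 6, shift_gene = NULL, shift = 0,
                  seed = 1, id = "DS1") {
  set.seed(seed)
  x <- matrix(2^stats::rnorm(n_genes * 2 * n, 8, 1), n_genes,
              dimnames = list(sprintf("G%03d", 1:n_genes),
                              sprintf("S%02d", 1:(2 * n))))
  grp <- factor(rep(c("naive", "refractory"), each = n),
                levels = c("naive", "refractory"))
  if (!is.null(shift_gene))
    x[shift_gene, grp == "refractory"] <-
      x[shift_gene, grp == "refractory"] * 2^shift
  expression_dataset(x, grp, dataset_id = id)
}

test_that("normalization yields per-array median 0 and unit sd", {
  ds <- normalize_dataset(mk_ds())
  expect_lt(max(abs(apply(ds$exprs, 2, stats::median))), 1e-9)
  expect_lt(max(abs(apply(ds$exprs, 2, stats::sd) - 1)), 1e-9)
  ## re-applying the centering/scaling changes nothing
  ds2 <- normalize_dataset(ds, log = FALSE)
  expect_equal(ds2$exprs, ds$exprs, tolerance = 1e-12)
  ## non-positive values get a logged offset
  raw <- mk_ds()
  raw$exprs[1, 1] <- -3
  expect_message(normalize_dataset(raw), "shifting")
  ## constant array dropped with warning
  cst <- mk_ds(n = 3)
  cst$exprs[, 2] <- 7
  expect_warning(out <- normalize_dataset(cst), "constant")
  expect_equal(ncol(out$exprs), 5)
})

test_that("differential expression calls direction and nulls correctly", {
  ## case group identical to control -> t = 0, p = 1
  set.seed(2)
  half <- matrix(2^stats::rnorm(20 * 4, 8, 1), 20)
  ds <- expression_dataset(cbind(half, half),
                           rep(c("naive", "refractory"), each = 4))
  rownames(ds$exprs) <- sprintf("G%03d", 1:20)
  de <- dataset_de(normalize_dataset(ds))
  expect_true(all(abs(de$t) < 1e-9))
  expect_true(all(de$p > 0.999))
  expect_false(any(de$significant))
  ## planted 2-sd shift at n=20/20 is called with the right direction
  dsp <- mk_ds(n_genes = 40, n = 20, shift_gene = "G007", shift = 3,
               seed = 3)
  dep <- dataset_de(normalize_dataset(dsp))
  g7 <- dep[dep$gene == "G007", ]
  expect_true(g7$significant)
  expect_equal(g7$direction, "up")
  ## null calibration: called fraction approximately alpha
  calls <- unlist(lapply(1:6, function(s)
    dataset_de(normalize_dataset(mk_ds(n_genes = 150, n = 10,
                                       seed = 100 + s)))$significant))
  rate <- mean(calls)
  se <- sqrt(0.05 * 0.95 / length(calls))
  expect_lt(abs(rate - 0.05), 4 * se)
})

test_that("consensus calling implements the two-dataset same-direction rule", {
  de <- function(gene, dir, sig, id)
    data.frame(gene = gene, dataset_id = id, t = 0, p = ifelse(sig, .01, .5),
               mean_diff = ifelse(dir == "up", 1, -1), direction = dir,
               significant = sig, stringsAsFactors = FALSE)
  lst <- list(de("FASN", "up", TRUE, "D1"),
              de("FASN", "up", TRUE, "D2"),
              de("CDC42", "up", TRUE, "D1"),
              de("CDC42", "down", TRUE, "D2"),
              de("TK1", "down", TRUE, "D1"),
              de("TK1", "down", FALSE, "D2"))
  mc <- consensus_markers(lst)
  expect_equal(mc$markers$gene, "FASN")       # up in 2 -> consensus
  expect_equal(mc$markers$n_support, 2L)
  expect_equal(mc$conflicts, "CDC42")         # opposite directions
  expect_false("TK1" %in% mc$markers$gene)    # significant in only 1
})

test_that("paired testing recovers planted tumor shifts and honors pairing", {
  pd <- generate_paired_dataset(n_genes = 150,
                                planted = stats::setNames(
                                  rep(c(1, -1), each = 10),
                                  sprintf("G%05d", 1:20)),
                                effect = 1.5, n_pairs = 52, seed = 5)
  res <- paired_de(normalize_dataset(pd), alpha = 0.01)
  planted <- sprintf("G%05d", 1:20)
  hits <- res$results[res$results$gene %in% planted, ]
  expect_gte(mean(hits$significant), 0.9)
  up <- hits[hits$gene %in% sprintf("G%05d", 1:10), ]
  expect_true(all(up$direction[up$significant] == "up"))
  ## null genes called at roughly the nominal 1%
  null <- res$results[!res$results$gene %in% planted, ]
  expect_lt(mean(null$significant), 0.06)
  ## tumor == normal -> no calls
  same <- pd
  same$exprs[, same$group == "tumor"] <- same$exprs[, same$group == "normal"]
  res0 <- paired_de(normalize_dataset(same), alpha = 0.01)
  expect_false(any(res0$results$significant))
  ## z-score matrix is row-standardized
  expect_lt(max(abs(rowMeans(res$zscores))), 1e-9)
  nop <- pd; nop$pair_id <- NULL
  expect_error(paired_de(normalize_dataset(nop)),
               class = "parameter_error")
})

test_that("marker-cluster intersection joins on symbol with counts", {
  mc <- structure(list(markers = data.frame(
    gene = c("FASN", "CKAP5", "TK1", "GONE"),
    direction = c("up", "up", "down", "up"),
    n_support = c(3L, 2L, 2L, 2L),
    datasets = c("D1,D2,D3", "D1,D2", "D2,D3", "D1,D5"),
    stringsAsFactors = FALSE), conflicts = character(0)),
    class = "marker_calls")
  asg <- make_assignment(c("FASN", "CKAP5", "TK1", "AR"),
                         c("E", "E", "A", "C"))
  res <- intersect_with_clusters(mc, asg)
  expect_equal(nrow(res$table), 3)           # GONE has no cluster
  expect_equal(res$per_cluster["E", "up"], 2)
  expect_equal(res$per_cluster["A", "down"], 1)
  expect_equal(nrow(res$long), 7)            # one row per supporting dataset
  expect_true(all(res$table$n_support >= 2))
  empty <- structure(list(markers = mc$markers[0, ],
                          conflicts = character(0)),
                     class = "marker_calls")
  expect_warning(intersect_with_clusters(empty, asg), "no marker")
})

test_that("expression datasets round-trip through the two-header TSV", {
  pd <- generate_paired_dataset(n_genes = 20, n_pairs = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_dataset(pd, path)
  back <- read_expression_dataset(path, dataset_id = pd$dataset_id)
  expect_equal(back$exprs, pd$exprs, tolerance = 1e-12)
  expect_equal(as.character(back$group), as.character(pd$group))
  expect_equal(back$pair_id, pd$pair_id)
})
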