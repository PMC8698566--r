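test_that("ratio tables round-trip through TSV", {
  tab <- toy_ratio_table()
  expect_length(tab$protein_id, 3)
  expect_equal(rt_times(tab), c(0, 5, 15, 30, 60))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ratio_table(tab, path)
  back <- read_ratio_table(path)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$values, tab$values)
  expect_equal(back$unique_peptides, tab$unique_peptides)
})

test_that("duplicate protein ids are rejected by name", {
  tab <- toy_ratio_table()
  df <- data.frame(protein_id = c("AR", "AR", "TP53"),
                   unique_peptides = 3L,
                   as.data.frame(tab$values[1:3, ], check.names = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_ratio_table(path), "AR", class = "ingestion_error")
})

test_that("rows with non-positive or unparsable values are dropped with a log", {
  tab <- toy_ratio_table()
  df <- data.frame(protein_id = tab$protein_id,
                   unique_peptides = tab$unique_peptides,
                   as.data.frame(tab$values, check.names = FALSE))
  df[2, 3] <- -5        # non-positive value in one sample
  df[3, 4] <- "oops"    # unparsable text
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_message(back <- read_ratio_table(path), "dropping 2")
  expect_equal(back$protein_id, tab$protein_id[1])
  ## missing required columns is a format error
  expect_error(read_ratio_table(
    withr::local_tempfile(lines = "a\tb\n1\t2", fileext = ".tsv")),
    class = "format_error")
})

test_that("BioGRID TAB3 parsing filters systems, loops and duplicates", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_tab3(path,
             a = c("EGFR", "EGFR", "AR", "TP53"),
             b = c("AR", "AR", "EGFR", "TP53"),
             system_type = rep("physical", 4))
  g <- suppressMessages(read_biogrid(path))
  expect_equal(igraph::ecount(g), 1)  # dup + reversed dup collapsed
  expect_true(igraph::are_adjacent(g, "EGFR", "AR"))
  expect_equal(unname(igraph::degree(g, "TP53")), 0)  # self-loop removed

  write_tab3(path, a = c("A1", "B1"), b = c("B1", "C1"),
             system_type = c("physical", "genetic"))
  g2 <- suppressMessages(read_biogrid(path))
  expect_equal(igraph::ecount(g2), 1)  # genetic row excluded

  ## 10-row fixture, hand count: 6 physical rows among human pairs, one
  ## duplicated and one self-loop -> 4 unique edges
  write_tab3(path,
             a = c("P1", "P2", "P3", "P4", "P5", "P5", "P6", "P7", "P8", "P9"),
             b = c("P2", "P3", "P4", "P5", "P6", "P6", "P6", "P8", "P9", "P9"),
             system_type = c("physical", "physical", "genetic", "physical",
                             "physical", "physical", "physical", "genetic",
                             "physical", "physical"),
             org_a = c(rep(9606, 9), 10090),
             org_b = rep(9606, 10))
  g3 <- suppressMessages(read_biogrid(path))
  ## physical & human & not self-loop & deduplicated:
  ## P1-P2, P2-P3, P4-P5, P5-P6 (dup collapsed), P6-P6 self from row 7? no:
  ## row 7 is P6-P6 -> removed; P8-P9 kept; P9-P9 (mouse) organism-dropped
  expect_equal(igraph::ecount(g3), 5)
})

test_that("MITAB dialect is parsed and unknown dialects fail loudly", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_mitab(path, a = c("EGFR", "SRC"), b = c("AR", "AR"),
              type = c("physical association", "colocalization"))
  g <- suppressMessages(read_biogrid(path))
  expect_equal(igraph::ecount(g), 1)
  expect_setequal(igraph::V(g)$name, c("EGFR", "AR"))
  bad <- withr::local_tempfile(lines = "foo\tbar\n1\t2", fileext = ".txt")
  expect_error(read_biogrid(bad), "dialect", class = "format_error")
})

test_that("GMT collections read, skip empties, and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tAKT1\tEGFR\tTP53",
               "SET_B\tdesc\tAR\tSP1",
               "EMPTY\tdesc"), path)
  expect_warning(sets <- read_gmt(path), "EMPTY")
  expect_length(sets, 2)
  expect_equal(sets$SET_B, c("AR", "SP1"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  again <- read_gmt(out)
  expect_equal(again[], sets[])
  writeLines(c("S\td\tA", "S\td\tB"), path)
  expect_error(read_gmt(path), class = "ingestion_error")
})

test_that("network exports round-trip through GraphML and SIF", {
  g <- igraph::graph_from_edgelist(
    cbind(c("AR", "SP1"), c("SP1", "STAT3")), directed = FALSE)
  asg <- make_assignment(c("AR", "SP1", "STAT3"), c("C", "D", "E"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network(g, path, "graphml", assignment = asg)
  back <- read_network(path)
  expect_true(igraph::isomorphic(g, back))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
  expect_equal(igraph::V(back)$cluster[match("SP1",
                                             igraph::V(back)$name)], "D")
  sif <- withr::local_tempfile(fileext = ".sif")
  write_network(g, sif, "sif")
  expect_equal(length(readLines(sif)), 2)
})

test_that("configuration validates and reads from YAML", {
  cfg <- pipeline_config()
  expect_equal(cfg$membership_threshold, 0.4)
  expect_equal(cfg$k_range, 2:10)
  expect_error(pipeline_config(membership_threshold = 1.2),
               class = "parameter_error")
  expect_error(pipeline_config(type_edge_fraction = 0),
               class = "parameter_error")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("membership_threshold: 0.5", "seed: 42"), path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$membership_threshold, 0.5)
  expect_equal(cfg2$seed, 42L)
  writeLines("not_a_key: 1", path)
  expect_error(read_config(path), "not_a_key", class = "format_error")
})
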