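mk_graph <- function(edges) {
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

test_that("network restriction induces the labeled subgraph", {
  g <- mk_graph(cbind(c("A1", "A1", "B1", "B1", "C1", "D1"),
                      c("B1", "C1", "C1", "D1", "D1", "E9")))
  asg <- make_assignment(c("A1", "B1", "C1", "D1"), c("A", "B", "C", "D"))
  ann <- annotation_table(c("A1", "B1", "C1", "D1"),
                          rep("cytoplasm", 4), rep("kinase", 4))
  net <- restrict_network(g, asg, ann)
  expect_equal(igraph::ecount(net), 5)  # E9 and its edge removed
  expect_setequal(igraph::V(net)$name, c("A1", "B1", "C1", "D1"))
  expect_equal(igraph::V(net)$cluster[igraph::V(net)$name == "C1"], "C")
  ## idempotence
  net2 <- restrict_network(net, asg, ann)
  expect_true(igraph::identical_graphs(
    igraph::delete_vertex_attr(net, "compartment"),
    igraph::delete_vertex_attr(net2, "compartment")))
  expect_warning(restrict_network(g, make_assignment("Z9", "A")),
                 "no labeled protein")
})

test_that("hub ranking is by degree with deterministic symbol ties", {
  star <- mk_graph(cbind(rep("HUB", 9), paste0("S", 1:9)))
  hubs <- hub_degrees(star, top_n = 3)
  expect_equal(hubs$symbol[1], "HUB")
  expect_equal(hubs$degree[1], 9)
  expect_equal(hubs$symbol[2:3], c("S1", "S2"))  # ties: lexicographic
  withAR <- hub_degrees(star, top_n = 2, focus = "S5")
  expect_true("S5" %in% withAR$symbol)
})

test_that("ego neighborhoods honor the radius", {
  path4 <- mk_graph(cbind(c("A", "B", "C"), c("B", "C", "D")))
  g2 <- ego_neighborhood(path4, "A", radius = 2)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
  expect_equal(sort(igraph::V(g2)$shell), c(0L, 1L, 2L))
  g0 <- ego_neighborhood(path4, "A", radius = 0)
  expect_equal(igraph::V(g0)$name, "A")
  expect_error(ego_neighborhood(path4, "NOPE"), "NOPE",
               class = "ingestion_error")
})

test_that("cluster-pair statistics match the exact enumeration example", {
  ## 2 clusters of sizes 2,2; 4 edges total, 3 spanning
  g <- mk_graph(cbind(c("A1", "A1", "A2", "A1"),
                      c("B1", "B2", "B1", "A2")))
  asg <- make_assignment(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"))
  st <- cluster_pair_stats(g, asg)
  ab <- st[st$pair == "A/B", ]
  expect_equal(ab$edges, 3)
  expect_equal(ab$percent, 75)
  ## universe: 6 node pairs, 4 with edges, 4 spanning pairs, 3 observed
  expect_equal(ab$p, enum_hyper_p(3, 4, 4, 6), tolerance = 1e-12)
  expect_equal(sum(st$edges), 4)
  expect_equal(sum(st$percent), 100, tolerance = 1e-9)
  expect_equal(sum(st$percent_inter, na.rm = TRUE), 100, tolerance = 1e-9)
  expect_error(cluster_pair_stats(g, make_assignment(c("A1", "A2"),
                                                     c("A", "A"))),
               class = "pipeline_error")
})

test_that("a complete bipartite planted pair is the most significant", {
  ids <- c(paste0("X", 1:4), paste0("Y", 1:4), paste0("Z", 1:4))
  asg <- make_assignment(ids, rep(c("C", "D", "E"), each = 4))
  el <- rbind(as.matrix(expand.grid(paste0("X", 1:4), paste0("Y", 1:4))),
              c("Z1", "Z2"), c("X1", "Z3"))
  g <- mk_graph(el)
  st <- cluster_pair_stats(g, asg)
  expect_equal(st$pair[which.min(st$p)], "C/D")
  expect_true(st$flagged[st$pair == "C/D"])
  ## removing an edge never increases any pair count
  g2 <- igraph::delete_edges(g, 1)
  st2 <- cluster_pair_stats(g2, asg)
  m <- merge(st[, c("pair", "edges")], st2[, c("pair", "edges")],
             by = "pair")
  expect_true(all(m$edges.y <= m$edges.x))
})

test_that("rewiring null p-values broadly agree with the hypergeometric", {
  sim <- generate_profiles(200, seed = 31)
  g <- generate_ppi(sim$truth, base_rate = 0.02,
                    pair_excess = c("C/E" = 6), seed = 31)
  asg <- make_assignment(sim$truth$proteins$protein_id,
                         sim$truth$proteins$archetype)
  st <- cluster_pair_stats(g, asg, rewire_B = 60, seed = 5)
  expect_true(all(st$p_rewire >= 0 & st$p_rewire <= 1))
  ce <- st[st$pair == "C/E", ]
  expect_true(ce$flagged)
  expect_lt(ce$p_rewire, 0.1)
})

test_that("the type interaction map applies threshold, test and direction", {
  ## two types, complete bipartite -> fraction 1, direction A-ish -> E-ish
  ids <- c("K1", "K2", "T1", "T2")
  asg <- make_assignment(ids, c("A", "A", "E", "E"))
  ann <- annotation_table(ids, rep("cytoplasm", 4),
                          c("kinase", "kinase",
                            "transcription regulator",
                            "transcription regulator"))
  g <- mk_graph(as.matrix(expand.grid(c("K1", "K2"), c("T1", "T2"))))
  tm <- type_interaction_map(g, ann, asg, fraction_threshold = 0.01)
  expect_equal(nrow(tm), 1)
  expect_equal(tm$fraction, 1)
  expect_equal(tm$from, "kinase")
  expect_equal(tm$to, "transcription regulator")
  expect_true(tm$directed)
  ## reversing the cluster ranks reverses the direction (antisymmetry)
  asg_rev <- make_assignment(ids, c("E", "E", "A", "A"))
  tm_rev <- type_interaction_map(g, ann, asg_rev, 0.01)
  expect_equal(tm_rev$from, "transcription regulator")
  expect_equal(tm_rev$to, "kinase")
  ## fraction exactly at the threshold is excluded (strict >)
  tm_edge <- type_interaction_map(g, ann, asg, fraction_threshold = 1)
  expect_equal(nrow(tm_edge), 0)
  ## equal mean ranks give an undirected edge
  asg_eq <- make_assignment(ids, c("A", "E", "A", "E"))
  tm_eq <- type_interaction_map(g, ann, asg_eq, 0.01)
  expect_false(tm_eq$directed)
})

test_that("three-type fixture reproduces the hand-derived map", {
  ids <- c("K1", "K2", "E1", "E2", "E3", "T1")
  asg <- make_assignment(ids, c("A", "B", "C", "C", "D", "E"))
  ann <- annotation_table(ids, rep("nucleus", 6),
                          c("kinase", "kinase", "enzyme", "enzyme",
                            "enzyme", "transcription regulator"))
  g <- mk_graph(cbind(c("K1", "K1", "E1", "E3"),
                      c("E1", "E2", "T1", "T1")))
  tm <- type_interaction_map(g, ann, asg, fraction_threshold = 0.1)
  ## kinase-enzyme: 2 of 6 pairs = 1/3; enzyme-tcreg: 2 of 3;
  ## kinase-tcreg: 0 -> no edge
  expect_equal(nrow(tm), 2)
  ke <- tm[tm$from == "kinase", ]
  expect_equal(ke$fraction, 2 / 6)
  et <- tm[tm$to == "transcription regulator", ]
  expect_equal(et$fraction, 2 / 3)
  expect_equal(et$from, "enzyme")
})

test_that("cascade enumeration matches hand examples", {
  ## C={c1}, D={d1,d2}, E={e1}, edges (c1,d1),(d1,e1),(c1,d2) -> one cascade
  g <- mk_graph(cbind(c("C1", "D1", "C1"), c("D1", "E1", "D2")))
  asg <- make_assignment(c("C1", "D1", "D2", "E1"), c("C", "D", "D", "E"))
  cs <- enumerate_cascades(g, asg, require_terminal_type = NULL)
  expect_equal(cs$n_triples, 1)
  expect_equal(unname(unlist(cs$triples[1, 1:3])), c("C1", "D1", "E1"))
  expect_error(enumerate_cascades(g, asg, from_label = "Q",
                                  require_terminal_type = NULL),
               class = "parameter_error")
  ## c != e is enforced
  g2 <- mk_graph(cbind(c("X1", "D1"), c("D1", "X1")))
  asgx <- make_assignment(c("X1", "D1"), c("C", "D"))
  expect_error(enumerate_cascades(g2, asgx, require_terminal_type = NULL),
               class = "parameter_error")  # no E label at all
})

test_that("the published AR-SP1-STAT3 cascade row is returned verbatim", {
  g <- mk_graph(cbind(c("AR", "SP1"), c("SP1", "STAT3")))
  asg <- make_assignment(c("AR", "SP1", "STAT3"), c("C", "D", "E"))
  ann <- annotation_table(
    c("AR", "SP1", "STAT3"),
    compartment = c("nucleus", "nucleus", "nucleus"),
    molecular_type = c("ligand-dependent nuclear receptor",
                       "transcription regulator",
                       "transcription regulator"))
  cs <- enumerate_cascades(g, asg, ann)
  expect_equal(cs$n_triples, 1)
  expect_equal(unname(unlist(cs$triples[1, ])),
               c("AR", "SP1", "STAT3",
                 "ligand-dependent nuclear receptor",
                 "transcription regulator", "transcription regulator"))
  ## the terminal-type filter removes non-regulator terminals
  ann2 <- annotation_table(c("AR", "SP1", "STAT3"),
                           rep("nucleus", 3),
                           c("ligand-dependent nuclear receptor",
                             "transcription regulator", "kinase"))
  cs2 <- enumerate_cascades(g, asg, ann2)
  expect_equal(cs2$n_triples, 0)
})

test_that("cascade enumeration equals the brute-force scan on random graphs", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(30:60, 1)
    ids <- sprintf("N%03d", 1:n)
    labels <- stats::setNames(
      sample(c("C", "D", "E", "X"), n, replace = TRUE), ids)
    types <- stats::setNames(
      sample(c("transcription regulator", "kinase", "enzyme"), n,
             replace = TRUE), ids)
    m <- sample(40:120, 1)
    edges <- unique(t(apply(
      matrix(sample(ids, 2 * m, replace = TRUE), ncol = 2), 1, sort)))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    g <- mk_graph(edges)
    asg <- make_assignment(names(labels), unname(labels))
    ann <- annotation_table(names(types), rep("cytoplasm", n),
                            unname(types))
    got <- enumerate_cascades(g, asg, ann,
                              require_terminal_type = "transcription regulator")
    want <- brute_cascades(edges, labels, types,
                           terminal_type = "transcription regulator")
    expect_equal(got$triples[, 1:3], want)
    got_all <- enumerate_cascades(g, asg, ann,
                                  require_terminal_type = NULL)
    want_all <- brute_cascades(edges, labels)
    expect_equal(got_all$triples[, 1:3], want_all)
  }
})

test_that("the cascade layout always produces the nine-region grid", {
  g <- mk_graph(cbind(c("AR", "SP1"), c("SP1", "STAT3")))
  asg <- make_assignment(c("AR", "SP1", "STAT3"), c("C", "D", "E"))
  ann <- annotation_table(c("AR", "SP1", "STAT3"),
                          c("extracellular space", "cytoplasm", "nucleus"),
                          c("ligand-dependent nuclear receptor",
                            "transcription regulator",
                            "transcription regulator"))
  cs <- enumerate_cascades(g, asg, ann)
  expect_message(lay <- cascade_layout(cs, ann), "mapped onto grid rows")
  expect_equal(dim(lay$regions), c(3, 3))
  expect_equal(sum(lay$regions), 3)  # three distinct members placed
  ## extracellular space went to the plasma-membrane row
  expect_equal(lay$placement$row[lay$placement$protein == "AR"],
               "plasma membrane")
  ## empty cascade set still yields the 3x3 grid
  cs0 <- enumerate_cascades(g, make_assignment(c("AR", "SP1", "STAT3"),
                                               c("C", "D", "E")),
                            ann, require_terminal_type = "kinase")
  lay0 <- cascade_layout(cs0, ann)
  expect_equal(dim(lay0$regions), c(3, 3))
  expect_equal(sum(lay0$regions), 0)
})
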