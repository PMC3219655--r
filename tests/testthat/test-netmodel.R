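test_that("construction applies the retention cascade", {
  tb <- list(
    mirna_targets = data.frame(
      mirna_id = c("miR-a", "miR-a", "miR-b", "miR-c"),
      target_id = c("G1", "NDG1", "G2", "NDG2")),
    disease_genes = c("G1", "G2", "TFB"),
    tf_hits = data.frame(tf_id = c("TFA", "TFB", "TFC"),
                         mirna_id = c("miR-a", "miR-b", "miR-c")),
    tcof_pairs = data.frame(
      tcof_id = c("COF1", "COF2", "COF3"),
      tf_id = c("TFA", "TFC", "TFA"),
      confidence = c("high", "high", "low")),
    ppi_pairs = data.frame(protein_a = c("G1", "G2", "NDG1"),
                           protein_b = c("TFA", "NDG1", "NDG2")))
  net <- build_network(tb$mirna_targets, tb$disease_genes, tb$tf_hits,
                       tb$tcof_pairs, tb$ppi_pairs, 1000)

  # miR-c targets only a non-disease gene: dropped, along with TFC and COF2
  expect_false("miR-c" %in% net$nodes$id)
  expect_false("TFC" %in% net$nodes$id)
  expect_false("COF2" %in% net$nodes$id)
  # low-confidence TcoF link dropped
  expect_false("COF3" %in% net$nodes$id)
  # PPIs induced on retained proteins only: no NDG partner proteins added
  expect_false(any(grepl("^NDG", net$nodes$id)))
  expect_true(all(c("miR-a", "miR-b", "G1", "G2", "TFA", "TFB",
                    "COF1") %in% net$nodes$id))
  cts <- census(net)
  expect_equal(cts$n_mirnas, 2)
  expect_equal(cts$n_targets, 2)
  expect_equal(cts$n_tfs, 2)
  expect_equal(cts$n_tcofs, 1)
  expect_equal(cts$n_edges_targeting, 2)
  expect_equal(cts$n_edges_regulation, 2)
  # PPI edges: induced G1--TFA plus the COF1--TFA co-factor link
  expect_equal(cts$n_edges_ppi, 2)
  expect_equal(cts$total_edges,
               cts$n_edges_targeting + cts$n_edges_regulation +
                 cts$n_edges_ppi)
})

test_that("a protein in both disease list and TF column gets both roles", {
  net <- build_network(
    mirna_targets = data.frame(mirna_id = c("miR-1", "miR-1"),
                               target_id = c("G1", "TFX")),
    disease_genes = c("G1", "TFX"),
    tf_hits = data.frame(tf_id = "TFX", mirna_id = "miR-1"),
    tcof_pairs = data.frame(tcof_id = character(), tf_id = character()),
    ppi_pairs = data.frame(protein_a = character(), protein_b = character()))
  i <- match("TFX", net$nodes$id)
  expect_equal(net$nodes$roles[i], "TARGET,TF")
  expect_true(net$nodes$disease_associated[i])
  # one node despite two roles
  expect_equal(sum(net$nodes$id == "TFX"), 1)
})

test_that("multiple binding-site hits collapse to one regulation edge", {
  net <- build_network(
    mirna_targets = data.frame(mirna_id = "miR-1", target_id = "G1"),
    disease_genes = "G1",
    tf_hits = data.frame(tf_id = c("TFA", "TFA", "TFA"),
                         mirna_id = rep("miR-1", 3)),
    tcof_pairs = data.frame(tcof_id = character(), tf_id = character()),
    ppi_pairs = data.frame(protein_a = character(), protein_b = character()))
  expect_equal(sum(net$edges$type == "REGULATION"), 1)
})

test_that("construction errors are specific", {
  mt <- data.frame(mirna_id = "miR-1", target_id = "G1")
  empty2 <- data.frame(protein_a = character(), protein_b = character())
  tc0 <- data.frame(tcof_id = character(), tf_id = character())
  # unknown miRNA id referenced by the hit table is named in the error
  expect_error(
    build_network(mt, "G1",
                  data.frame(tf_id = "TFA", mirna_id = "miR-ghost"),
                  tc0, empty2),
    "miR-ghost")
  # nothing retained
  expect_error(
    build_network(mt, "OTHER",
                  data.frame(tf_id = character(), mirna_id = character()),
                  tc0, empty2),
    "nothing to analyse")
  # identifier in both namespaces
  expect_error(
    build_network(data.frame(mirna_id = c("miR-1", "miR-2"),
                             target_id = c("G1", "miR-1")),
                  c("G1", "miR-1"),
                  data.frame(tf_id = character(), mirna_id = character()),
                  tc0, empty2),
    "both miRNA and protein")
})

test_that("census counts toy and degenerate networks", {
  empty <- new_network(
    data.frame(id = character(), roles = character(),
               disease_associated = logical()),
    data.frame(source = character(), target = character(),
               type = character()))
  cts <- census(empty)
  expect_true(all(unlist(cts[setdiff(names(cts), "promoter_window")]) == 0))

  chain <- chain_network()
  cc <- census(chain)
  expect_equal(cc$total_nodes, 3)
  expect_equal(cc$total_edges, 2)
  expect_equal(c(cc$n_edges_targeting, cc$n_edges_regulation,
                 cc$n_edges_ppi), c(1, 1, 0))
})

test_that("census additivity holds on generated networks", {
  for (seed in 1:5) {
    gen <- generate_tables(small_gen_config(seed))
    for (w in c(1000, 5000)) {
      cts <- census(build_from_tables(gen, w))
      expect_equal(cts$total_edges,
                   cts$n_edges_targeting + cts$n_edges_regulation +
                     cts$n_edges_ppi)
    }
  }
})

test_that("regulon, downstream targets and miRNA in-degree", {
  net <- new_network(
    nodes = data.frame(
      id = c("TF1", "TF2", "m1", "m2", "P1", "P2", "P3"),
      roles = c("TF", "TF", "MIRNA", "MIRNA", "TARGET", "TARGET", "TARGET"),
      disease_associated = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)),
    edges = data.frame(
      source = c("TF1", "TF1", "m1", "m1", "m2", "m2"),
      target = c("m1", "m2", "P1", "P2", "P2", "P3"),
      type = c("REGULATION", "REGULATION", rep("TARGETING", 4))))
  expect_equal(tf_regulon(net, "TF1"), c("m1", "m2"))
  expect_equal(tf_regulon(net, "TF2"), character(0))
  expect_equal(tf_downstream_targets(net, "TF1"), c("P1", "P2", "P3"))
  expect_equal(tf_downstream_targets(net, "TF2"), character(0))
  expect_equal(mirna_in_degree(net, "P2"), 2)
  expect_equal(mirna_in_degree(net, "TF1"), 0)
  expect_error(tf_regulon(net, "P1"), "not a TF")
  expect_error(tf_regulon(net, "nope"), "unknown node")
  expect_error(mirna_in_degree(net, "m1"), "not a protein")
})

test_that("adding input rows never removes nodes or edges", {
  gen <- generate_tables(small_gen_config(3))
  base <- build_from_tables(gen, 1000)
  grow <- function(tables) {
    net2 <- build_from_tables(list(tables = tables), 1000)
    expect_true(all(base$nodes$id %in% net2$nodes$id))
    key <- function(e) paste(e$source, e$target, e$type)
    expect_true(all(key(base$edges) %in% key(net2$edges)))
  }
  tb <- gen$tables
  tb1 <- tb
  tb1$mirna_targets <- rbind(tb1$mirna_targets,
                             data.frame(mirna_id = "miR-new",
                                        target_id = "GENE-001"))
  grow(tb1)
  tb2 <- tb
  tb2$ppi_pairs <- rbind(tb2$ppi_pairs,
                         data.frame(protein_a = "GENE-001",
                                    protein_b = "GENE-002"))
  grow(tb2)
  tb3 <- tb
  tb3$tf_hits <- rbind(tb3$tf_hits,
                       data.frame(tf_id = "TF-NEW", mirna_id = "miR-001",
                                  core_score = 0.99, matrix_score = 0.99,
                                  window_nt = 1000L))
  grow(tb3)
})

test_that("promoter-window nesting: NW1000 regulation edges nest in NW5000", {
  for (seed in 1:5) {
    gen <- generate_tables(small_gen_config(seed))
    nw1 <- build_from_tables(gen, 1000)
    nw5 <- build_from_tables(gen, 5000)
    key <- function(net, type) {
      e <- net$edges[net$edges$type == type, ]
      paste(e$source, e$target)
    }
    expect_true(all(key(nw1, "REGULATION") %in% key(nw5, "REGULATION")))
    expect_setequal(key(nw1, "TARGETING"), key(nw5, "TARGETING"))
    expect_true(all(nw1$nodes$id %in% nw5$nodes$id))
  }
})

test_that("no orphan proteins: every node carries a retained role", {
  gen <- generate_tables(small_gen_config(11))
  net <- build_from_tables(gen, 1000)
  expect_true(all(nchar(net$nodes$roles) > 0))
  # PPI endpoints are proteins already required by another relationship
  pp <- net$edges[net$edges$type == "PPI", ]
  role_of <- setNames(net$nodes$roles, net$nodes$id)
  expect_true(all(grepl("TF|TCOF|TARGET", role_of[pp$source])))
  expect_true(all(grepl("TF|TCOF|TARGET", role_of[pp$target])))
})

test_that("validation rejects malformed networks", {
  nodes <- data.frame(id = c("m1", "P1"), roles = c("MIRNA", "TARGET"),
                      disease_associated = c(FALSE, TRUE))
  expect_error(new_network(
    data.frame(id = "x", roles = "MIRNA,TF", disease_associated = FALSE),
    data.frame(source = character(), target = character(),
               type = character())),
    "collision")
  expect_error(new_network(
    data.frame(id = "P1", roles = "TARGET", disease_associated = FALSE),
    data.frame(source = character(), target = character(),
               type = character())),
    "disease-associated")
  expect_error(new_network(
    nodes, data.frame(source = "m1", target = "ghost", type = "TARGETING")),
    "endpoint")
  expect_error(new_network(
    nodes, data.frame(source = "P1", target = "m1", type = "TARGETING")),
    "TARGETING")
})
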