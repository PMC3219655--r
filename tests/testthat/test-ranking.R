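test_that("weight samples obey the hierarchy by construction", {
  set.seed(99)
  ws <- sample_weights(5000)
  expect_true(all(ws$e_t == 1))
  expect_true(all(ws$e_r > ws$e_i & ws$e_i > 0 & ws$e_r < 1))
  expect_true(all(ws$w > 0 & ws$w < 1))
  # one n-draw call consumes the stream like n single draws
  set.seed(7); many <- sample_weights(3)
  set.seed(7); singles <- do.call(rbind, replicate(3, sample_weights(1),
                                                   simplify = FALSE))
  expect_equal(many, singles)
})

test_that("hand-evaluated scores: regulation chain and PPI pair", {
  w <- fixed_weights()  # e_r = 0.5, e_i = 0.25, w = 0.5
  chain <- chain_network()
  # S_A = e_r + w * e_t ; S_B = e_t ; S_C = 0
  expect_equal(node_score(chain, "A", w), 1.0)
  expect_equal(node_score(chain, "B", w), 1.0)
  expect_equal(node_score(chain, "C", w), 0)

  pair <- ppi_pair_network()
  # reciprocal edge counted in the second degree: 0.25 + 0.5 * 0.25
  expect_equal(node_score(pair, "D", w), 0.375)
  expect_equal(node_score(pair, "E", w), 0.375)
  # with back-edges excluded the second-degree term vanishes
  expect_equal(node_score(pair, "D", w, second_degree_reciprocal = FALSE),
               0.25)
})

test_that("isolated nodes score zero and unknown nodes error", {
  net <- new_network(
    data.frame(id = c("m1", "P1"), roles = c("MIRNA", "TARGET"),
               disease_associated = c(FALSE, TRUE)),
    data.frame(source = character(), target = character(),
               type = character()))
  expect_equal(node_score(net, "m1", fixed_weights()), 0)
  expect_error(node_score(net, "zz", fixed_weights()), "unknown node")
  expect_error(node_scores(net, list(e_r = 0.2, e_i = 0.5, w = 0.5)),
               "e_r > e_i")
})

test_that("single-draw ranks use fractional ties", {
  iso <- new_network(
    data.frame(id = c("a", "b", "c"), roles = "MIRNA",
               disease_associated = FALSE),
    data.frame(source = character(), target = character(),
               type = character()))
  expect_equal(unname(rank_once(iso, fixed_weights())), c(2, 2, 2))

  r <- rank_once(chain_network(), fixed_weights())
  expect_equal(r[["A"]], 1.5)
  expect_equal(r[["B"]], 1.5)
  expect_equal(r[["C"]], 3)
})

test_that("scores agree with the brute-force oracle in both modes", {
  for (seed in 1:60) {
    net <- random_network(sample(2:8, 1), seed = seed)
    w <- as.list(sample_weights(1))
    got <- node_scores(net, w)
    got_ex <- node_scores(net, w, second_degree_reciprocal = FALSE)
    for (v in net$nodes$id) {
      expect_equal(got[[v]], oracle_node_score(net, v, w), tolerance = 1e-12)
      expect_equal(got_ex[[v]],
                   oracle_node_score(net, v, w, reciprocal = FALSE),
                   tolerance = 1e-12)
    }
  }
})

test_that("adding a targeting out-edge raises the node, lowers no one", {
  set.seed(42)
  for (seed in 1:10) {
    net <- random_network(7, seed = seed, p_edge = 0.3)
    is_target <- grepl("TARGET", net$nodes$roles)
    is_mirna <- net$nodes$roles == "MIRNA"
    if (!any(is_target) || !any(is_mirna)) next
    m <- net$nodes$id[is_mirna][1]
    existing <- net$edges$target[net$edges$type == "TARGETING" &
                                   net$edges$source == m]
    free <- setdiff(net$nodes$id[is_target], existing)
    if (!length(free)) next
    w <- as.list(sample_weights(1))
    before <- node_scores(net, w)
    net2 <- new_network(net$nodes,
                        rbind(net$edges,
                              data.frame(source = m, target = free[1],
                                         type = "TARGETING")),
                        validate = FALSE)
    after <- node_scores(net2, w)
    expect_gt(after[[m]], before[[m]])
    expect_true(all(after >= before - 1e-12))
  }
})

test_that("retyping an out-edge regulation -> targeting never lowers score", {
  for (seed in 1:10) {
    net <- random_network(7, seed = seed)
    reg_idx <- which(net$edges$type == "REGULATION")
    if (!length(reg_idx)) next
    i <- reg_idx[1]
    n <- net$edges$source[i]
    w <- as.list(sample_weights(1))
    before <- node_score(net, n, w)
    e2 <- net$edges
    e2$type[i] <- "TARGETING"
    net2 <- new_network(net$nodes, e2, validate = FALSE)
    expect_gte(node_score(net2, n, w), before)
  }
})

test_that("ranking is deterministic and equivariant under relabeling", {
  net <- random_network(8, seed = 5)
  r1 <- rank_nodes(net, repetitions = 50, seed = 11)
  r2 <- rank_nodes(net, repetitions = 50, seed = 11)
  expect_identical(r1, r2)
  r3 <- rank_nodes(net, repetitions = 50, seed = 12)
  expect_false(identical(r1$average_rank, r3$average_rank))

  # permute identifiers; average ranks must follow the relabeling
  ids <- net$nodes$id
  set.seed(1)
  relabel <- setNames(sprintf("x%02d", sample(length(ids))), ids)
  nodes2 <- net$nodes
  nodes2$id <- unname(relabel[nodes2$id])
  edges2 <- net$edges
  edges2$source <- unname(relabel[edges2$source])
  edges2$target <- unname(relabel[edges2$target])
  net2 <- new_network(nodes2, edges2)
  r1p <- rank_nodes(net2, repetitions = 50, seed = 11)
  got <- setNames(r1p$average_rank, r1p$node_id)
  want <- setNames(r1$average_rank, unname(relabel[r1$node_id]))
  expect_equal(got[names(want)], want)
})

test_that("rank_nodes validates inputs and leaves the RNG state alone", {
  net <- chain_network()
  expect_error(rank_nodes(net, repetitions = 0), "repetitions")
  empty <- new_network(
    data.frame(id = character(), roles = character(),
               disease_associated = logical()),
    data.frame(source = character(), target = character(),
               type = character()))
  expect_error(rank_nodes(empty), "empty network")
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(rank_nodes(net, repetitions = 10, seed = 99))
  expect_equal(runif(1), before)
})

test_that("final rank positions order by average rank with lexical ties", {
  net <- chain_network()
  rk <- rank_nodes(net, repetitions = 25, seed = 3)
  expect_equal(rk$final_rank_position, seq_len(nrow(rk)))
  expect_false(is.unsorted(rk$average_rank))
  rownames(rk) <- NULL
  tied <- rk[duplicated(rk$average_rank) |
               duplicated(rk$average_rank, fromLast = TRUE), ]
  if (nrow(tied)) {
    expect_false(is.unsorted(tied$node_id))
  }
  p <- tempfile()
  write_ranking(rk, p)
  expect_equal(nrow(read_assoc_table(
    p, c(node_id = "character", average_rank = "numeric",
         final_rank_position = "integer"))), 3)
})
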