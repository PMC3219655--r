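# Independent oracles and fixture builders shared across test files.
# Oracles are deliberately naive (explicit edge-list materialisation,
# exhaustive enumeration) and share no code with the package internals.

# Brute-force influence score: materialise the directed edge list (PPI edges
# expanded to both directions), collect the node's first-degree out-edges and
# each distinct out-neighbour's full out-edge list, and sum type weights.
oracle_node_score <- function(network, node, weights, reciprocal = TRUE) {
  wt <- c(TARGETING = 1, REGULATION = weights$e_r, PPI = weights$e_i)
  e <- network$edges
  ppi <- e[e$type == "PPI" & e$source != e$target, , drop = FALSE]
  dir <- rbind(e, data.frame(source = ppi$target, target = ppi$source,
                             type = rep("PPI", nrow(ppi)),
                             stringsAsFactors = FALSE))
  out_edges <- function(v) dir[dir$source == v, , drop = FALSE]
  fe <- out_edges(node)
  first <- sum(wt[fe$type])
  second <- 0
  for (m in unique(fe$target)) {
    oe <- out_edges(m)
    if (!reciprocal) oe <- oe[oe$target != node, , drop = FALSE]
    second <- second + sum(wt[oe$type])
  }
  first + weights$w * second
}

# Exhaustive O(N^3) feedback-loop enumeration over all ordered node triples.
oracle_feedback_loops <- function(network) {
  ids <- network$nodes$id
  e <- network$edges
  key <- function(a, b) paste(a, b, sep = "\r")
  reg <- key(e$source[e$type == "REGULATION"], e$target[e$type == "REGULATION"])
  tgt <- key(e$source[e$type == "TARGETING"], e$target[e$type == "TARGETING"])
  pp <- e[e$type == "PPI", , drop = FALSE]
  ppi <- c(key(pp$source, pp$target), key(pp$target, pp$source))
  dis <- network$nodes$id[network$nodes$disease_associated]
  tri <- expand.grid(tf = ids, mirna = ids, target = ids,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- key(tri$tf, tri$mirna) %in% reg &
    key(tri$mirna, tri$target) %in% tgt &
    key(tri$target, tri$tf) %in% ppi &
    tri$target != tri$tf &
    tri$target %in% dis
  out <- tri[keep, , drop = FALSE]
  out <- out[order(out$tf, out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_self_loops <- function(network) {
  e <- network$edges
  key <- function(a, b) paste(a, b, sep = "\r")
  reg <- key(e$source[e$type == "REGULATION"], e$target[e$type == "REGULATION"])
  tgt <- key(e$source[e$type == "TARGETING"], e$target[e$type == "TARGETING"])
  grid <- expand.grid(mirna = network$nodes$id, tf = network$nodes$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- key(grid$tf, grid$mirna) %in% reg & key(grid$mirna, grid$tf) %in% tgt
  out <- grid[keep, , drop = FALSE]
  out <- out[order(out$mirna, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact hypergeometric upper tail by enumerating every size-n subset of the
# background and counting those with >= k pathway members.
oracle_hyper_tail <- function(k, n, K, N) {
  subsets <- utils::combn(N, n)
  in_pathway <- subsets <= K  # pathway members are items 1..K
  mean(colSums(in_pathway) >= k)
}

# Random role-consistent network: miRNA and protein namespaces disjoint,
# proteins carry random subsets of {TF, TCOF, TARGET}, edges respect types.
random_network <- function(n_nodes, seed, p_edge = 0.35) {
  set.seed(seed)
  n_mirna <- max(1L, rbinom(1L, n_nodes - 1L, 0.4))
  n_prot <- n_nodes - n_mirna
  mirnas <- sprintf("m%02d", seq_len(n_mirna))
  prots <- sprintf("p%02d", seq_len(n_prot))
  roles <- lapply(seq_len(n_prot), function(i) {
    r <- c(if (runif(1) < 0.5) "TF", if (runif(1) < 0.5) "TARGET",
           if (runif(1) < 0.3) "TCOF")
    if (is.null(r)) "TARGET" else r
  })
  is_target <- vapply(roles, function(r) "TARGET" %in% r, TRUE)
  is_tf <- vapply(roles, function(r) "TF" %in% r, TRUE)
  nodes <- data.frame(
    id = c(mirnas, prots),
    roles = c(rep("MIRNA", n_mirna),
              vapply(roles, function(r) paste(sort(r), collapse = ","), "")),
    disease_associated = c(rep(FALSE, n_mirna),
                           is_target | runif(n_prot) < 0.2),
    stringsAsFactors = FALSE)
  typed <- function(g, type) {
    g <- g[runif(nrow(g)) < p_edge, , drop = FALSE]
    g$type <- rep(type, nrow(g))
    g
  }
  edges <- list()
  if (any(is_target)) {
    edges$t <- typed(expand.grid(source = mirnas, target = prots[is_target],
                                 stringsAsFactors = FALSE), "TARGETING")
  }
  if (any(is_tf)) {
    edges$r <- typed(expand.grid(source = prots[is_tf], target = mirnas,
                                 stringsAsFactors = FALSE), "REGULATION")
  }
  if (n_prot >= 1) {
    g <- expand.grid(source = prots, target = prots, stringsAsFactors = FALSE)
    g <- g[g$source < g$target |
             (g$source == g$target & runif(nrow(g)) < 0.1), , drop = FALSE]
    edges$i <- typed(g, "PPI")
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        type = character(), stringsAsFactors = FALSE)
  }
  new_network(nodes, edges)
}

# Three-node chain: TF A regulates miRNA B, which targets disease protein C.
chain_network <- function() {
  new_network(
    nodes = data.frame(
      id = c("A", "B", "C"),
      roles = c("TF", "MIRNA", "TARGET"),
      disease_associated = c(FALSE, FALSE, TRUE)),
    edges = data.frame(source = c("A", "B"), target = c("B", "C"),
                       type = c("REGULATION", "TARGETING")))
}

# Two proteins joined by a single undirected interaction.
ppi_pair_network <- function() {
  new_network(
    nodes = data.frame(id = c("D", "E"), roles = "TARGET",
                       disease_associated = TRUE),
    edges = data.frame(source = "D", target = "E", type = "PPI"))
}

fixed_weights <- function(e_r = 0.5, e_i = 0.25, w = 0.5) {
  list(e_t = 1, e_r = e_r, e_i = e_i, w = w)
}

small_gen_config <- function(seed, ...) {
  generator_config(n_mirnas = 15L, n_targets = 12L, n_tfs = 10L,
                   n_tcofs = 5L, n_nondisease_genes = 8L,
                   tf_hit_prob = 0.12, tf_hit_prob_5000 = 0.25,
                   ppi_density = 0.03, seed = seed, ...)
}
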