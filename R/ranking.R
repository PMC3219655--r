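# Stochastic edge-weight node ranking.
#
# Influence score of a node n (similar in spirit to a two-step Katz
# centrality, but restricted to the first and second degree):
#
#   S_n = sum(e_n1) + w * sum(e_n2)
#
# where e_n1 are the weights of n's outgoing edges, e_n2 the weights of the
# outgoing edges of n's distinct first-degree out-neighbours, and w a damping
# factor for the second degree. Edge weights depend only on the edge type:
# miRNA->target (e_t, fixed at 1), TF->miRNA (e_r), PPI (e_i), constrained to
# 1 = e_t > e_r > e_i > 0. Because no canonical weighting exists, e_r, e_i
# and w are resampled at every repetition and each node's final value is its
# average rank across repetitions. Undirected PPI edges count as outgoing
# from both endpoints.

#' Draw edge-type weight samples
#'
#' Draws `e_r ~ Uniform(0, 1)`, then `e_i ~ Uniform(0, e_r)`, then
#' `w ~ Uniform(0, 1)`, so the hierarchy `1 = e_t > e_r > e_i > 0` holds by
#' construction. Draw order per sample is (e_r, e_i, w); consuming `n`
#' samples in one call uses the RNG stream exactly as `n` single draws would.
#'
#' @param n number of samples.
#' @return data.frame with `n` rows and columns `e_t` (always 1), `e_r`,
#'   `e_i`, `w`.
#' @export
sample_weights <- function(n = 1L) {
  stopifnot(n >= 1L)
  u <- matrix(runif(3L * n), nrow = 3L)
  data.frame(e_t = 1, e_r = u[1L, ], e_i = u[1L, ] * u[2L, ], w = u[3L, ])
}

as_weight_sample <- function(weights) {
  weights <- as.list(weights)
  stopifnot(all(c("e_r", "e_i", "w") %in% names(weights)))
  if (is.null(weights$e_t)) weights$e_t <- 1
  if (weights$e_t != 1 || !(weights$e_t > weights$e_r) ||
      !(weights$e_r > weights$e_i) || weights$e_i <= 0 ||
      weights$w <= 0 || weights$w >= 1) {
    stop("weights must satisfy 1 = e_t > e_r > e_i > 0 and 0 < w < 1")
  }
  weights
}

# Topology summaries reused across repetitions: per-node outgoing edge counts
# by type (PPI expanded to both directions, self-interactions once), the
# 0/1 adjacency of distinct out-neighbours, its products with the count
# vectors, and the reciprocal-edge count sums used when edges pointing back
# to the scored node are excluded from the second degree.
ranking_components <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  e <- network$edges
  src <- match(e$source, ids)
  tgt <- match(e$target, ids)
  adj <- function(type) {
    sel <- e$type == type
    i <- src[sel]; j <- tgt[sel]
    if (type == "PPI") {
      loops <- i == j
      i2 <- c(i, j[!loops]); j2 <- c(j, i[!loops])
      i <- i2; j <- j2
    }
    Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  }
  A <- lapply(c(TARGETING = "TARGETING", REGULATION = "REGULATION",
                PPI = "PPI"), adj)
  B <- ((A$TARGETING + A$REGULATION + A$PPI) > 0) * 1
  d <- lapply(A, Matrix::rowSums)
  s <- lapply(A, function(a) as.vector(B %*% Matrix::rowSums(a)))
  r <- lapply(A, function(a) Matrix::rowSums(B * Matrix::t(a)))
  list(ids = ids, d = d, s = s, r = r)
}

scores_from_components <- function(comp, weights, reciprocal) {
  wts <- c(TARGETING = weights$e_t, REGULATION = weights$e_r,
           PPI = weights$e_i)
  first <- wts[1] * comp$d$TARGETING + wts[2] * comp$d$REGULATION +
    wts[3] * comp$d$PPI
  second <- wts[1] * comp$s$TARGETING + wts[2] * comp$s$REGULATION +
    wts[3] * comp$s$PPI
  if (!reciprocal) {
    second <- second - (wts[1] * comp$r$TARGETING +
                          wts[2] * comp$r$REGULATION + wts[3] * comp$r$PPI)
  }
  setNames(first + weights$w * second, comp$ids)
}

#' Influence scores of all nodes for one weight sample
#'
#' @param network an `ocm_network`.
#' @param weights one row of [sample_weights()] (or any list with elements
#'   `e_r`, `e_i`, `w`, and optionally `e_t = 1`).
#' @param second_degree_reciprocal should second-degree sums include edges
#'   that point back to the scored node (default `TRUE`)? Exposed for
#'   sensitivity analysis.
#' @return Named numeric vector of scores, one per node.
#' @export
node_scores <- function(network, weights, second_degree_reciprocal = TRUE) {
  stopifnot(inherits(network, "ocm_network"))
  weights <- as_weight_sample(weights)
  scores_from_components(ranking_components(network), weights,
                         second_degree_reciprocal)
}

#' Influence score of a single node
#'
#' @inheritParams node_scores
#' @param node node identifier.
#' @return Non-negative numeric score.
#' @export
node_score <- function(network, node, weights,
                       second_degree_reciprocal = TRUE) {
  s <- node_scores(network, weights, second_degree_reciprocal)
  if (!node %in% names(s)) stop("unknown node id: ", node)
  unname(s[[node]])
}

#' Rank nodes for one weight sample
#'
#' Ranks descend by score (rank 1 = highest score); tied scores receive the
#' fractional (average) rank of the positions they occupy, so ranks always
#' average to (N + 1) / 2.
#'
#' @inheritParams node_scores
#' @return Named numeric vector of ranks.
#' @export
rank_once <- function(network, weights, second_degree_reciprocal = TRUE) {
  if (!nrow(network$nodes)) stop("cannot rank an empty network")
  s <- node_scores(network, weights, second_degree_reciprocal)
  rank(-s, ties.method = "average")
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Average node rank over repeated random weight draws
#'
#' For each repetition one weight sample is drawn (shared by all edges of a
#' given type), all node scores are computed and ranked, and each node's
#' final value is the arithmetic mean of its per-repetition ranks. The whole
#' procedure is deterministic given `seed`.
#'
#' @inheritParams node_scores
#' @param repetitions number of weight draws (the default, 10000, matches the
#'   published procedure).
#' @param seed integer seed for the weight-sampling stream; the caller's RNG
#'   state is left untouched.
#' @return data.frame of class `ocm_ranking` with columns `node_id`, `roles`,
#'   `average_rank`, `final_rank_position` (1..N by ascending average rank,
#'   ties broken lexicographically by id), `repetitions` and `seed`, ordered
#'   by `final_rank_position`.
#' @export
rank_nodes <- function(network, repetitions = 10000L, seed = 1L,
                       second_degree_reciprocal = TRUE) {
  stopifnot(inherits(network, "ocm_network"))
  if (!nrow(network$nodes)) stop("cannot rank an empty network")
  if (repetitions < 1L) stop("repetitions must be >= 1")
  comp <- ranking_components(network)
  ws <- with_seed(seed, sample_weights(repetitions))
  rank_sum <- numeric(length(comp$ids))
  for (i in seq_len(repetitions)) {
    s <- scores_from_components(
      comp, list(e_t = 1, e_r = ws$e_r[i], e_i = ws$e_i[i], w = ws$w[i]),
      second_degree_reciprocal)
    rank_sum <- rank_sum + rank(-s, ties.method = "average")
  }
  avg <- rank_sum / repetitions
  pos <- integer(length(avg))
  pos[order(avg, comp$ids)] <- seq_along(avg)
  out <- data.frame(
    node_id = comp$ids,
    roles = network$nodes$roles,
    average_rank = avg,
    final_rank_position = pos,
    repetitions = as.integer(repetitions),
    seed = as.integer(seed),
    stringsAsFactors = FALSE)
  out <- out[order(out$final_rank_position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ocm_ranking", "data.frame")
  out
}

#' Write a ranking table to TSV
#'
#' @param ranking result of [rank_nodes()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path) {
  write_tsv(as.data.frame(ranking), path)
  invisible(path)
}
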