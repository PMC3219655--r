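# Regulatory network motif census.
#
# Two motif families are enumerated. A self-loop is a miRNA that targets one
# of its own predicted TFs (REGULATION tf -> mirna and TARGETING mirna -> tf).
# A feedback loop is the smallest closed circle through all three layers:
# REGULATION tf -> mirna, TARGETING mirna -> target, and a PPI closing
# target -- tf, with target != tf and the target disease-associated. Loops
# are identified as ordered (tf, mirna, target) triples, so a TF-target pair
# connected through two different miRNAs contributes two loops. Whether the
# TF acts as activator or repressor (hence whether a loop is positive or
# negative feedback) is unknown at this level; only topology is reported.

ppi_keys <- function(network) {
  e <- network$edges[network$edges$type == "PPI", , drop = FALSE]
  c(paste(e$source, e$target, sep = "\r"),
    paste(e$target, e$source, sep = "\r"))
}

#' Find miRNA self-loop motifs
#'
#' All distinct (mirna, tf) pairs where the TF regulates the miRNA and the
#' miRNA targets the TF back.
#'
#' @param network an `ocm_network`.
#' @return data.frame with columns `mirna`, `tf`, sorted lexicographically.
#' @export
find_self_loops <- function(network) {
  stopifnot(inherits(network, "ocm_network"))
  e <- network$edges
  reg <- e[e$type == "REGULATION", c("source", "target")]
  names(reg) <- c("tf", "mirna")
  tgt <- e[e$type == "TARGETING", c("source", "target")]
  names(tgt) <- c("mirna", "tf")
  out <- merge(reg, tgt, by = c("mirna", "tf"))
  out <- unique(out[c("mirna", "tf")])
  out <- out[order(out$mirna, out$tf), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find three-element feedback-loop motifs
#'
#' All distinct ordered (tf, mirna, target) triples with REGULATION
#' tf -> mirna, TARGETING mirna -> target, a PPI edge target -- tf,
#' target != tf, and the target disease-associated. The `target_is_tcof`
#' column flags loops whose target also carries the TCOF role (i.e. the
#' closing interaction may be a co-factor relationship rather than a plain
#' PPI); it does not affect loop identity.
#'
#' @param network an `ocm_network`.
#' @return data.frame with columns `tf`, `mirna`, `target`,
#'   `target_is_tcof` (0/1), sorted lexicographically by (tf, mirna, target).
#' @export
find_feedback_loops <- function(network) {
  stopifnot(inherits(network, "ocm_network"))
  e <- network$edges
  reg <- e[e$type == "REGULATION", c("source", "target")]
  names(reg) <- c("tf", "mirna")
  tgt <- e[e$type == "TARGETING", c("source", "target")]
  names(tgt) <- c("mirna", "target")
  tri <- merge(reg, tgt, by = "mirna")
  tri <- tri[tri$target != tri$tf, , drop = FALSE]
  if (nrow(tri)) {
    keys <- ppi_keys(network)
    tri <- tri[paste(tri$target, tri$tf, sep = "\r") %in% keys, ,
               drop = FALSE]
  }
  if (nrow(tri)) {
    dis <- network$nodes$id[network$nodes$disease_associated]
    tri <- tri[tri$target %in% dis, , drop = FALSE]
  }
  tri <- unique(tri[c("tf", "mirna", "target")])
  tcofs <- network$nodes$id[node_has_role(network, "TCOF")]
  tri$target_is_tcof <- as.integer(tri$target %in% tcofs)
  tri <- tri[order(tri$tf, tri$mirna, tri$target), , drop = FALSE]
  rownames(tri) <- NULL
  tri
}

#' Participation summary of feedback loops
#'
#' @param loops data.frame from [find_feedback_loops()].
#' @return List with `n_tfs`, `n_mirnas`, `n_targets`: counts of distinct
#'   identifiers per loop position.
#' @export
loop_participation <- function(loops) {
  list(
    n_tfs = length(unique(loops$tf)),
    n_mirnas = length(unique(loops$mirna)),
    n_targets = length(unique(loops$target))
  )
}

#' Number of feedback loops a node takes part in
#'
#' Counts loops in which the node appears in any position (TF, miRNA or
#' target).
#'
#' @param loops data.frame from [find_feedback_loops()].
#' @param node node identifier.
#' @return Integer count.
#' @export
node_loop_count <- function(loops, node) {
  if (!nrow(loops)) return(0L)
  sum(loops$tf == node | loops$mirna == node | loops$target == node)
}

#' Write motif tables to TSV
#'
#' @param loops data.frame of motifs (self or feedback loops).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_loops <- function(loops, path) {
  write_tsv(loops, path)
  invisible(path)
}
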